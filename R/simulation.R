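#' Simulation configuration
#'
#' Controls for the Monte Carlo duration engine.
#'
#' @param n_runs number of independent simulation runs, `>= 1`.
#' @param seed integer seed; identical seeds give bit-identical results.
#' @param max_reworks_per_edge cap on the number of rework iterations a
#'   single dependency may trigger in one run.  The default `NULL` resolves
#'   per edge: 1 for rework probabilities `>= 0.999` (a certain rework is
#'   taken to occur once per pass, not to loop forever), otherwise 25.
#' @param rework_trigger `"standard"` (default): a rework iteration occurs
#'   while the uniform draw is *below* the rework probability, so the
#'   uncapped iteration count is geometric with `P(nr = k) = p^k (1 - p)`.
#'   `"literal"`: iteration occurs while the draw *exceeds* the probability
#'   (the inverted convention, kept for fidelity experiments).
#' @param duration_source `"sampled"` (default): first-trial durations drawn
#'   from each activity's triangular distribution; `"mlv_only"`: the most
#'   likely value is used deterministically.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_runs = 1000L, seed = 1L,
                       max_reworks_per_edge = NULL,
                       rework_trigger = c("standard", "literal"),
                       duration_source = c("sampled", "mlv_only")) {
  rework_trigger <- match.arg(rework_trigger)
  duration_source <- match.arg(duration_source)
  stopifnot(is.numeric(n_runs), length(n_runs) == 1L, n_runs >= 1)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!is.null(max_reworks_per_edge)) {
    stopifnot(is.numeric(max_reworks_per_edge),
              length(max_reworks_per_edge) == 1L,
              max_reworks_per_edge >= 1)
    max_reworks_per_edge <- as.integer(max_reworks_per_edge)
  }
  structure(list(n_runs = as.integer(n_runs), seed = as.integer(seed),
                 max_reworks_per_edge = max_reworks_per_edge,
                 rework_trigger = rework_trigger,
                 duration_source = duration_source),
            class = "sim_config")
}

# Per-edge iteration cap: explicit config value if given, otherwise 1 for
# near-certain rework probabilities and 25 elsewhere.
resolve_cap <- function(p, max_reworks_per_edge = NULL) {
  if (!is.null(max_reworks_per_edge))
    return(rep_len(as.integer(max_reworks_per_edge), length(p)))
  ifelse(p >= 0.999, 1L, 25L)
}

#' Draw the number of rework iterations for one dependency
#'
#' Consumes exactly `cap` uniform draws from the current RNG stream and
#' counts the leading run of triggering draws (draw below `p` under the
#' standard convention, above `p` under the literal one).  Uncapped, the
#' standard count is geometric: `P(nr = k) = p^k (1 - p)`; the cap truncates
#' it.  Fixed draw consumption keeps the stream aligned across configurations
#' that differ only in `p`.
#'
#' @param p rework probability in `[0, 1]`.
#' @param cap maximum number of iterations, `>= 1`.
#' @param rework_trigger `"standard"` or `"literal"` (see [sim_config()]).
#' @return Integer iteration count in `0:cap`.
#' @export
sample_rework_count <- function(p, cap,
                                rework_trigger = c("standard", "literal")) {
  rework_trigger <- match.arg(rework_trigger)
  check_probability(p, "p")
  stopifnot(cap >= 1)
  u <- stats::runif(cap)
  hit <- if (rework_trigger == "standard") u < p else u > p
  miss <- which(!hit)
  if (!length(miss)) as.integer(cap) else miss[1] - 1L
}

#' Expected rework-iteration count under the truncated geometric model
#'
#' Closed form for the mean of the capped iteration count drawn by
#' [sample_rework_count()]: `sum_{k=1}^{cap} q^k`, where `q` is the
#' per-iteration trigger probability (`p` under the standard convention,
#' `1 - p` under the literal one).
#'
#' @inheritParams sample_rework_count
#' @return Expected iteration count.
#' @export
expected_rework_count <- function(p, cap,
                                  rework_trigger = c("standard", "literal")) {
  rework_trigger <- match.arg(rework_trigger)
  check_probability(p, "p")
  stopifnot(cap >= 1)
  q <- if (rework_trigger == "standard") p else 1 - p
  sum(q ^ seq_len(cap))
}

#' Duration of a single rework iteration
#'
#' Rework repeats a fraction `ri` (rework impact) of the activity's original
#' duration `d0`, shortened by the improvement-curve multiplier `ic`:
#' `d0 * ri * ic`.
#'
#' @param d0 original (first-trial) duration, minutes, `>= 0`.
#' @param ri rework impact in `[0, 1]`.
#' @param ic improvement-curve multiplier in `(0, 1]`.
#' @return Rework duration in minutes.
#' @export
rework_duration <- function(d0, ri, ic) {
  if (any(!is.finite(d0)) || any(d0 < 0))
    stop("d0 must be finite and >= 0", call. = FALSE)
  check_probability(ri, "ri")
  if (any(!is.finite(ic)) || any(ic <= 0) || any(ic > 1))
    stop("ic must lie in (0, 1]", call. = FALSE)
  d0 * ri * ic
}

# Sum of the first nr improvement-curve multipliers; a curve shorter than nr
# is extended by repeating its last value.
ic_partial_sum <- function(ic, nr) {
  if (nr == 0L) return(0)
  k <- length(ic)
  if (nr <= k) sum(ic[seq_len(nr)]) else sum(ic) + (nr - k) * ic[k]
}

# Engine tables: cyclic loop edges (in loop traversal order) and single
# (non-loop) rework edges in consumer-then-provider order.  Edges joining
# two members of the same loop that are not cyclically consecutive (chords)
# carry no rework machinery and are listed separately.
sim_prep <- function(dsm, part, cfg) {
  ids <- dsm$activities$id
  idx <- function(a) match(a, ids)
  edges <- dsm$edges
  ekey <- paste(edges$from, edges$to, sep = "\r")

  loop_edges <- NULL
  if (length(part$loops)) {
    le <- lapply(seq_along(part$loops), function(li) {
      members <- part$loops[[li]]
      nxt <- c(members[-1], members[1])
      key <- paste(members, nxt, sep = "\r")
      hit <- match(key, ekey)
      if (anyNA(hit))
        stop("rework loop {", paste(members, collapse = ", "),
             "} is missing cyclic edge(s): ",
             paste(sub("\r", "->", key[is.na(hit)]), collapse = ", "),
             call. = FALSE)
      data.frame(from = members, to = nxt, p = edges$p[hit], loop = li,
                 stringsAsFactors = FALSE)
    })
    loop_edges <- do.call(rbind, le)
  } else {
    loop_edges <- data.frame(from = character(), to = character(),
                             p = numeric(), loop = integer())
  }

  loop_of <- integer(length(ids))
  for (li in seq_along(part$loops)) loop_of[idx(part$loops[[li]])] <- li
  lkey <- paste(loop_edges$from, loop_edges$to, sep = "\r")
  in_loop_pair <- loop_of[idx(edges$from)] > 0L &
    loop_of[idx(edges$from)] == loop_of[idx(edges$to)]
  is_cyclic <- ekey %in% lkey
  single <- edges[!is_cyclic & !in_loop_pair, , drop = FALSE]
  chords <- edges[!is_cyclic & in_loop_pair, , drop = FALSE]
  if (nrow(single))
    single <- single[order(idx(single$to), idx(single$from)), , drop = FALSE]

  loop_edges$cap <- resolve_cap(loop_edges$p, cfg$max_reworks_per_edge)
  single$cap <- resolve_cap(single$p, cfg$max_reworks_per_edge)
  list(ids = ids,
       mlv = dsm$activities$mlv,
       bcv = dsm$activities$bcv,
       wcv = dsm$activities$wcv,
       ri = dsm$activities$rework_impact,
       ic = dsm$activities$improvement_curve,
       loop_edges = loop_edges,
       single_edges = single,
       chord_edges = chords,
       n_loops = length(part$loops))
}

#' Simulate the rework duration of one loop
#'
#' Walks the loop's cyclic dependencies in order (for a loop A, B: first the
#' rework of B caused by A, then the rework of A caused by B), draws the
#' iteration count for each from the current RNG stream, and accumulates
#' each member's rework duration `d0 * RI * sum(IC_i, i = 1..nr)`.
#'
#' @param loop character vector of loop member ids (from
#'   [partition_dsm()]); every cyclically consecutive pair must be an edge
#'   of `dsm`.
#' @param dsm a [build_dsm()] object.
#' @param d0 named numeric vector of first-trial durations (minutes) for at
#'   least the loop members.
#' @param cfg a [sim_config()].
#' @return List with `duration` (total loop rework duration `D_rl`, minutes),
#'   `nr` (named iteration counts per directed loop edge) and
#'   `edge_durations` (named per-edge rework durations).
#' @export
simulate_loop <- function(loop, dsm, d0, cfg = sim_config()) {
  stopifnot(inherits(dsm, "dsm"), length(loop) >= 2L)
  ids <- dsm$activities$id
  ekey <- paste(dsm$edges$from, dsm$edges$to, sep = "\r")
  nxt <- c(loop[-1], loop[1])
  key <- paste(loop, nxt, sep = "\r")
  hit <- match(key, ekey)
  if (anyNA(hit))
    stop("rework loop {", paste(loop, collapse = ", "),
         "} is missing cyclic edge(s): ",
         paste(sub("\r", "->", key[is.na(hit)]), collapse = ", "),
         call. = FALSE)
  p <- dsm$edges$p[hit]
  cap <- resolve_cap(p, cfg$max_reworks_per_edge)
  nr <- integer(length(loop))
  dur <- numeric(length(loop))
  for (i in seq_along(loop)) {
    consumer <- nxt[i]
    ci <- match(consumer, ids)
    nr[i] <- sample_rework_count(p[i], cap[i], cfg$rework_trigger)
    dur[i] <- d0[[consumer]] * dsm$activities$rework_impact[ci] *
      ic_partial_sum(dsm$activities$improvement_curve[[ci]], nr[i])
  }
  names(nr) <- names(dur) <- sub("\r", "->", key)
  list(duration = sum(dur), nr = nr, edge_durations = dur)
}

#' Simulate a single run of the procedure
#'
#' One Monte Carlo realisation: draw (or fix at MLV) every activity's
#' first-trial duration in declared order, walk the partition's active sets,
#' add the rework duration of every rework loop and of every single
#' (non-loop) rework dependency, and return the run record.  The total
#' satisfies the accounting identity
#' `total = first_trial_total + sum(loop durations) + sum(edge rework)`
#' exactly.
#'
#' @param dsm a [build_dsm()] object.
#' @param part the [partition_dsm()] of `dsm`.
#' @param cfg a [sim_config()]; uses the current RNG stream.
#' @return List with `d0` (named first-trial durations),
#'   `first_trial_total`, `loop_durations`, `edge_rework` (per single edge),
#'   `rework_counts` (named, loop edges then single edges) and `total`.
#' @export
simulate_run <- function(dsm, part = partition_dsm(dsm), cfg = sim_config()) {
  prep <- sim_prep(dsm, part, cfg)
  simulate_run_prepped(prep, cfg)
}

simulate_run_prepped <- function(prep, cfg) {
  n <- length(prep$ids)
  if (cfg$duration_source == "sampled") {
    u <- stats::runif(n)
    d0 <- qtriangular(u, prep$bcv, prep$mlv, prep$wcv)
  } else {
    d0 <- prep$mlv
  }
  names(d0) <- prep$ids
  first_trial <- sum(d0)

  le <- prep$loop_edges
  nle <- nrow(le)
  loop_dur <- numeric(prep$n_loops)
  nr_all <- integer(nle + nrow(prep$single_edges))
  if (nle) {
    for (i in seq_len(nle)) {
      ci <- match(le$to[i], prep$ids)
      nr <- sample_rework_count(le$p[i], le$cap[i], cfg$rework_trigger)
      nr_all[i] <- nr
      loop_dur[le$loop[i]] <- loop_dur[le$loop[i]] +
        d0[[ci]] * prep$ri[ci] * ic_partial_sum(prep$ic[[ci]], nr)
    }
  }
  se <- prep$single_edges
  edge_rework <- numeric(nrow(se))
  if (nrow(se)) {
    for (i in seq_len(nrow(se))) {
      ci <- match(se$to[i], prep$ids)
      nr <- sample_rework_count(se$p[i], se$cap[i], cfg$rework_trigger)
      nr_all[nle + i] <- nr
      edge_rework[i] <- d0[[ci]] * prep$ri[ci] * ic_partial_sum(prep$ic[[ci]], nr)
    }
  }
  names(nr_all) <- c(if (nle) paste(le$from, le$to, sep = "->"),
                     if (nrow(se)) paste(se$from, se$to, sep = "->"))
  total <- first_trial + sum(loop_dur) + sum(edge_rework)
  list(d0 = d0, first_trial_total = first_trial,
       loop_durations = loop_dur, edge_rework = edge_rework,
       rework_counts = nr_all, total = total)
}

#' Run the Monte Carlo duration simulation
#'
#' Executes `cfg$n_runs` independent runs of [simulate_run()] under a single
#' seeded random stream consumed in a fixed activity-then-edge order, and
#' summarises the distribution of total procedure duration.  Identical
#' configurations give bit-identical results; the caller's RNG state is
#' left untouched.
#'
#' @param dsm a [build_dsm()] object.
#' @param cfg a [sim_config()].
#' @return An object of class `dsm_simulation`: list with `totals`,
#'   `first_trial_total`, `loop_durations` (runs x loops matrix),
#'   `edge_rework` (runs x single edges), `rework_counts` (runs x edges),
#'   `summary` (mean, sd, min, max, p5, p50, p95, n_runs, seed), the
#'   `partition` used and the `config`.
#' @examples
#' res <- run_monte_carlo(make_aplt_fixture(), sim_config(n_runs = 200, seed = 7))
#' res$summary$mean
#' @export
run_monte_carlo <- function(dsm, cfg = sim_config()) {
  stopifnot(inherits(dsm, "dsm"), inherits(cfg, "sim_config"))
  part <- partition_dsm(dsm)
  prep <- sim_prep(dsm, part, cfg)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  nr_edges <- nrow(prep$loop_edges) + nrow(prep$single_edges)
  totals <- numeric(cfg$n_runs)
  first_trial <- numeric(cfg$n_runs)
  loop_mat <- matrix(0, cfg$n_runs, prep$n_loops)
  edge_mat <- matrix(0, cfg$n_runs, nrow(prep$single_edges))
  nr_mat <- matrix(0L, cfg$n_runs, nr_edges)
  for (r in seq_len(cfg$n_runs)) {
    rec <- simulate_run_prepped(prep, cfg)
    totals[r] <- rec$total
    first_trial[r] <- rec$first_trial_total
    if (prep$n_loops) loop_mat[r, ] <- rec$loop_durations
    if (ncol(edge_mat)) edge_mat[r, ] <- rec$edge_rework
    if (nr_edges) nr_mat[r, ] <- rec$rework_counts
  }
  if (prep$n_loops)
    colnames(loop_mat) <- vapply(part$loops, paste, character(1), collapse = "+")
  if (ncol(edge_mat))
    colnames(edge_mat) <- paste(prep$single_edges$from,
                                prep$single_edges$to, sep = "->")
  if (nr_edges)
    colnames(nr_mat) <- c(
      if (nrow(prep$loop_edges)) paste(prep$loop_edges$from,
                                       prep$loop_edges$to, sep = "->"),
      if (nrow(prep$single_edges)) paste(prep$single_edges$from,
                                         prep$single_edges$to, sep = "->"))
  structure(list(totals = totals,
                 first_trial_total = first_trial,
                 loop_durations = loop_mat,
                 edge_rework = edge_mat,
                 rework_counts = nr_mat,
                 summary = summarize_totals(totals, cfg),
                 partition = part,
                 config = cfg),
            class = "dsm_simulation")
}

summarize_totals <- function(totals, cfg) {
  q <- stats::quantile(totals, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  list(mean = mean(totals),
       sd = if (length(totals) > 1) stats::sd(totals) else 0,
       min = min(totals), max = max(totals),
       p5 = q[1], p50 = q[2], p95 = q[3],
       n_runs = cfg$n_runs, seed = cfg$seed)
}

#' @export
print.dsm_simulation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<dsm simulation: %d runs, seed %d>\n", s$n_runs, s$seed))
  cat(sprintf("  total duration: mean %.1f min (sd %.1f), range [%.1f, %.1f]\n",
              s$mean, s$sd, s$min, s$max))
  cat(sprintf("  percentiles: p5 %.1f, p50 %.1f, p95 %.1f min\n",
              s$p5, s$p50, s$p95))
  invisible(x)
}

#' Deterministic expected total duration
#'
#' Expected-value analogue of the Monte Carlo engine based on the most
#' likely values: the sum of all MLVs plus, for every rework relation
#' (cyclic loop edges and single rework dependencies), the consumer's
#' `MLV * RI` multiplied by the exact expectation of the improvement-curve
#' sum under the truncated geometric iteration count,
#' `sum_k IC_k * q^k` with `q` the per-iteration trigger probability.
#' Equals the mean of [run_monte_carlo()] in `mlv_only` mode as
#' `n_runs` grows.
#'
#' @param dsm a [build_dsm()] object.
#' @param max_reworks_per_edge optional explicit iteration cap (default:
#'   per-edge rule of [sim_config()]).
#' @param rework_trigger `"standard"` or `"literal"`.
#' @return Expected total duration in minutes.
#' @export
expected_duration <- function(dsm, max_reworks_per_edge = NULL,
                              rework_trigger = c("standard", "literal")) {
  rework_trigger <- match.arg(rework_trigger)
  stopifnot(inherits(dsm, "dsm"))
  cfg <- sim_config(max_reworks_per_edge = max_reworks_per_edge,
                    rework_trigger = rework_trigger)
  part <- partition_dsm(dsm)
  prep <- sim_prep(dsm, part, cfg)
  relations <- rbind(prep$loop_edges[, c("from", "to", "p", "cap")],
                     prep$single_edges[, c("from", "to", "p", "cap")])
  total <- sum(prep$mlv)
  if (nrow(relations)) {
    for (i in seq_len(nrow(relations))) {
      ci <- match(relations$to[i], prep$ids)
      q <- if (rework_trigger == "standard") relations$p[i] else 1 - relations$p[i]
      ks <- seq_len(relations$cap[i])
      ic <- prep$ic[[ci]]
      ic_k <- c(ic, rep(ic[length(ic)], max(0, length(ks) - length(ic))))[ks]
      total <- total + prep$mlv[ci] * prep$ri[ci] * sum(ic_k * q ^ ks)
    }
  }
  total
}
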