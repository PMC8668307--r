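# Synthetic per-activity duration profiles.  The validated protocols'
# per-activity duration figures are not publicly recoverable, so the
# fixtures carry synthetic MLV weights (longer dissection/separation steps,
# shorter cutting steps) rescaled to a requested total; only the dependency
# structure, the rework probabilities and the rework impacts follow the
# described protocols.
amis_mlv_weights <- c(1.2, 1.2, 1.6, 1.2, 0.4, 1.2, 0.4, 0.8, 2.0)
aplt_mlv_weights <- c(1.0, 1.0, 1.2, 1.4, 1.0, 0.4, 1.0, 0.4, 0.6, 1.6, 1.4)

fixture_activities <- function(ids, labels, weights, duration_scale, ri) {
  mlv <- weights / sum(weights) * duration_scale
  data.frame(id = ids, label = labels,
             bcv = 0.8 * mlv, mlv = mlv, wcv = 1.5 * mlv,
             rework_impact = ri,
             improvement_curve = 1,
             stringsAsFactors = FALSE)
}

#' Synthetic standard laparoscopic cholecystectomy (LC) protocol fixture
#'
#' A nine-activity DSM emulating the structure of a standard LC protocol:
#' activities A1-A9 in chain order, one two-activity rework loop between
#' dissection/clipping of the cystic artery (A6) and cutting it (A7) with
#' rework probability 1 in both directions (a bleeding event observed once
#' forces both to be redone), additional dependencies from the
#' dissection/cutting activities A4-A6 to the cleaning activity A8 (bile
#' leakage or bleeding requires extra cleaning; A7 -> A8 is already a chain
#' edge), and all remaining rework probabilities 0.1.  Rework impacts equal
#' each activity's incoming rework probability (1 for the loop members, 0.1
#' elsewhere) and the improvement curve is constant at 1 (fully trained
#' surgeons).
#'
#' Per-activity durations are synthetic: fixed MLV weights rescaled so the
#' MLVs sum to `duration_scale`, with `bcv = 0.8 * mlv` and
#' `wcv = 1.5 * mlv`.
#'
#' @param duration_scale total of the most likely values, minutes.
#' @return A [build_dsm()] object.
#' @examples
#' partition_dsm(make_amis_fixture())$loops
#' @export
make_amis_fixture <- function(duration_scale = 10) {
  stopifnot(duration_scale > 0)
  ids <- paste0("A", 1:9)
  labels <- c("peritoneal dissection, left side",
              "peritoneal dissection, right side",
              "dissection of the triangle of Calot",
              "dissection and clipping the cystic duct",
              "cutting the cystic duct",
              "dissection and clipping the cystic artery",
              "cutting the cystic artery",
              "cleaning bile and/or blood",
              "separation of the gallbladder from liver")
  ri <- rep(0.1, 9)
  ri[6:7] <- 1                       # loop members: rework impact = loop P
  acts <- fixture_activities(ids, labels, amis_mlv_weights, duration_scale, ri)
  chain <- data.frame(from = ids[1:8], to = ids[2:9], p = 0.1,
                      stringsAsFactors = FALSE)
  chain$p[chain$from == "A6"] <- 1   # A6 -> A7 is a loop edge
  extra <- data.frame(from = c("A7", "A4", "A5", "A6"),
                      to = c("A6", "A8", "A8", "A8"),
                      p = c(1, 0.1, 0.1, 0.1),
                      stringsAsFactors = FALSE)
  build_dsm(acts, rbind(chain, extra))
}

#' Synthetic pediatric laparoscopic cholecystectomy protocol fixture
#'
#' An eleven-activity, strictly feed-forward DSM emulating the structure of
#' a pediatric LC protocol (infundibulum retraction opens the triangle of
#' Calot at a wide angle, decoupling the dissection steps): chain
#' dependencies only, no rework loop, all rework probabilities and rework
#' impacts 0.1, improvement curve constant at 1.  Durations are synthetic
#' (see [make_amis_fixture()]).
#'
#' @param duration_scale total of the most likely values, minutes.
#' @return A [build_dsm()] object.
#' @export
make_aplt_fixture <- function(duration_scale = 5.7) {
  stopifnot(duration_scale > 0)
  ids <- paste0("A", 1:11)
  labels <- c("port placement and exposure",
              "grasping and retracting the infundibulum",
              "peritoneal dissection, left side",
              "peritoneal dissection, right side",
              "dissection of the triangle of Calot",
              "clipping the cystic duct",
              "cutting the cystic duct",
              "clipping the cystic artery",
              "cutting the cystic artery",
              "cleaning bile and/or blood",
              "separation of the gallbladder from liver")
  acts <- fixture_activities(ids, labels, aplt_mlv_weights, duration_scale,
                             rep(0.1, 11))
  chain <- data.frame(from = ids[1:10], to = ids[2:11], p = 0.1,
                      stringsAsFactors = FALSE)
  build_dsm(acts, chain)
}

#' Reproducible random DSM generator
#'
#' Draws a random dependency structure for property testing: each ordered
#' activity pair becomes an edge independently with probability `density`,
#' rework probabilities uniform in `p_range`, rework impacts uniform in
#' `[0, 1]`, positive triangular durations, improvement curve constant 1.
#' The caller's RNG state is left untouched.
#'
#' @param n number of activities, `>= 1`.
#' @param density edge density in `[0, 1]`; `1` gives the complete directed
#'   graph.
#' @param p_range length-2 numeric range for rework probabilities.
#' @param seed integer seed; same arguments give an identical DSM.
#' @return A [build_dsm()] object.
#' @export
make_random_dsm <- function(n, density = 0.3, p_range = c(0.05, 0.5),
                            seed = 1L) {
  stopifnot(n >= 1, density >= 0, density <= 1, length(p_range) == 2L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  ids <- sprintf("A%d", seq_len(n))
  mlv <- stats::runif(n, 1, 5)
  acts <- data.frame(id = ids, label = ids,
                     bcv = mlv * stats::runif(n, 0.5, 1),
                     mlv = mlv,
                     wcv = mlv * stats::runif(n, 1, 2),
                     rework_impact = stats::runif(n),
                     improvement_curve = 1,
                     stringsAsFactors = FALSE)
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < density
  pairs <- pairs[keep, , drop = FALSE]
  edges <- data.frame(from = ids[pairs$from], to = ids[pairs$to],
                      p = stats::runif(nrow(pairs), p_range[1], p_range[2]),
                      stringsAsFactors = FALSE)
  build_dsm(acts, edges)
}

#' Relative validation error
#'
#' Percentage difference between a model-predicted duration and a reference
#' protocol duration, with the prediction as denominator:
#' `|predicted - reference| / predicted * 100`.
#'
#' @param predicted model-predicted duration, minutes, `> 0`.
#' @param reference reference protocol duration, minutes.
#' @return Relative error in percent.
#' @examples
#' relative_error(10, 9.75)  # 2.5
#' @export
relative_error <- function(predicted, reference) {
  if (any(!is.finite(predicted)) || any(predicted <= 0))
    stop("predicted duration must be finite and > 0", call. = FALSE)
  abs(predicted - reference) / predicted * 100
}
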