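#' Annotation tallies for one dependency
#'
#' Counts extracted from annotated procedure recordings for a provider
#' (input) activity feeding a consumer activity:
#' `n_o` observations of the input activity, `n_oc` of which deviated from
#' the protocol-standard execution, `n_ic` deviant executions considered for
#' their downstream effect, and `n_ir` of those that caused rework of the
#' consumer.  `n_ic` normally equals `n_oc` when both tally the same
#' deviation class; a mismatch is flagged with a warning rather than
#' resolved.
#'
#' @param n_o,n_oc,n_ic,n_ir non-negative integer counts with
#'   `n_oc <= n_o` and `n_ir <= n_ic`.
#' @param linked if `TRUE` (default), warn when `n_ic != n_oc`.
#' @return An object of class `observation_counts`.
#' @export
observation_counts <- function(n_o, n_oc, n_ic = n_oc, n_ir = 0,
                               linked = TRUE) {
  counts <- c(n_o = n_o, n_oc = n_oc, n_ic = n_ic, n_ir = n_ir)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("observation counts must be non-negative integers", call. = FALSE)
  if (n_oc > n_o)
    stop("n_oc (", n_oc, ") cannot exceed n_o (", n_o, ")", call. = FALSE)
  if (n_ir > n_ic)
    stop("n_ir (", n_ir, ") cannot exceed n_ic (", n_ic, ")", call. = FALSE)
  if (linked && n_ic != n_oc)
    warning("n_ic (", n_ic, ") differs from n_oc (", n_oc,
            "); tallies accepted as independent", call. = FALSE)
  structure(as.list(counts), class = "observation_counts")
}

#' Estimate input volatility from observation tallies
#'
#' Volatility is the probability that an input activity deviates from its
#' protocol-standard execution, estimated as the deviant fraction
#' `n_oc / n_o` of observed executions.
#'
#' @param counts an [observation_counts()] object.
#' @return Probability in `[0, 1]`.
#' @export
estimate_volatility <- function(counts) {
  stopifnot(inherits(counts, "observation_counts"))
  if (counts$n_o == 0)
    stop("volatility undefined: no observations of the input activity (n_o = 0)",
         call. = FALSE)
  counts$n_oc / counts$n_o
}

#' Estimate sensitivity from observation tallies
#'
#' Sensitivity is the probability that a deviation in the input activity
#' causes rework of the consumer, estimated as `n_ir / n_ic`.
#'
#' @param counts an [observation_counts()] object.
#' @return Probability in `[0, 1]`.
#' @export
estimate_sensitivity <- function(counts) {
  stopifnot(inherits(counts, "observation_counts"))
  if (counts$n_ic == 0)
    stop("sensitivity undefined: no deviant executions tallied (n_ic = 0)",
         call. = FALSE)
  counts$n_ir / counts$n_ic
}

#' Rework probability of a dependency
#'
#' The probability that a change in the provider activity triggers rework of
#' the consumer: the product of the provider's volatility and the
#' dependency's sensitivity.
#'
#' @param p_i volatility, in `[0, 1]`.
#' @param p_r sensitivity, in `[0, 1]`.
#' @return Probability in `[0, 1]`.
#' @export
rework_probability <- function(p_i, p_r) {
  check_probability(p_i, "p_i")
  check_probability(p_r, "p_r")
  p_i * p_r
}

check_probability <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(name, " must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' Combine per-class rework probabilities
#'
#' Different deviation classes of the same dependency may have different
#' sensitivities, giving one rework probability per class.  The combined
#' probability that at least one class triggers rework is
#' `1 - prod(1 - p)`.  A single class passes through unchanged.
#'
#' @param p numeric vector of per-class rework probabilities in `[0, 1]`.
#' @return Combined probability in `[0, 1]`.
#' @export
combine_rework_probabilities <- function(p) {
  if (!length(p)) stop("no class probabilities supplied", call. = FALSE)
  check_probability(p, "class probabilities")
  1 - prod(1 - p)
}

#' Aggregate expert rework-impact assessments
#'
#' Rework impact is elicited as a range of plausible values over situations
#' (complications, operating areas); the simulation uses their arithmetic
#' mean.
#'
#' @param values numeric vector of rework-impact assessments in `[0, 1]`.
#' @return Mean rework impact in `[0, 1]`.
#' @export
aggregate_rework_impact <- function(values) {
  if (!length(values)) stop("no rework-impact assessments supplied", call. = FALSE)
  check_probability(values, "rework-impact values")
  mean(values)
}

# Half-sample mode: repeatedly keep the densest half of the sorted sample.
half_sample_mode <- function(x) {
  x <- sort(x)
  while (length(x) > 3L) {
    h <- ceiling(length(x) / 2)
    widths <- x[seq(h, length(x))] - x[seq_len(length(x) - h + 1L)]
    i <- which.min(widths)
    x <- x[i:(i + h - 1L)]
  }
  if (length(x) == 3L) {
    x <- if ((x[2] - x[1]) <= (x[3] - x[2])) x[1:2] else x[2:3]
  }
  mean(x)
}

#' Fit a triangular duration to observed execution times
#'
#' The three-point estimate is anchored at the sample extremes
#' (`bcv = min`, `wcv = max`); the most likely value is a mode estimate:
#' the sample median for small samples (n <= 5) and a half-sample mode for
#' larger ones, always clamped to `[min, max]`.  A single observation yields
#' a degenerate (deterministic) duration.
#'
#' @param durations numeric vector of observed durations in minutes,
#'   non-empty, all `>= 0`.
#' @param mode_estimator `"auto"` (default: median for n <= 5, half-sample
#'   mode otherwise), `"median"`, or `"hsm"`.
#' @return A [triangular_duration()].
#' @export
fit_triangular <- function(durations,
                           mode_estimator = c("auto", "median", "hsm")) {
  mode_estimator <- match.arg(mode_estimator)
  if (!length(durations))
    stop("cannot fit a triangular duration to an empty sample", call. = FALSE)
  if (any(!is.finite(durations)) || any(durations < 0))
    stop("durations must be finite and >= 0", call. = FALSE)
  lo <- min(durations)
  hi <- max(durations)
  est <- switch(mode_estimator,
                auto = if (length(durations) <= 5L) "median" else "hsm",
                mode_estimator)
  mode <- switch(est,
                 median = stats::median(durations),
                 hsm = half_sample_mode(durations))
  triangular_duration(lo, min(max(mode, lo), hi), hi)
}

#' Estimate per-dependency rework probabilities from an observation table
#'
#' Takes a long-format observation table (one row per dependency and
#' deviation class) and returns one rework probability per dependency:
#' volatility times sensitivity within each class, classes combined as the
#' probability that at least one triggers rework.
#'
#' @param observations data frame with columns `input_id`, `consumer_id`,
#'   `class`, `n_o`, `n_oc`, `n_ic`, `n_ir`.
#' @return Data frame with columns `from`, `to`, `p` suitable as the edge
#'   table of [build_dsm()].
#' @export
estimate_rework_probabilities <- function(observations) {
  required <- c("input_id", "consumer_id", "n_o", "n_oc", "n_ic", "n_ir")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols))
    stop("observation table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  key <- paste(observations$input_id, observations$consumer_id, sep = "\r")
  groups <- split(observations, key)
  out <- lapply(groups, function(g) {
    p_class <- vapply(seq_len(nrow(g)), function(i) {
      cts <- observation_counts(g$n_o[i], g$n_oc[i], g$n_ic[i], g$n_ir[i],
                                linked = FALSE)
      rework_probability(estimate_volatility(cts), estimate_sensitivity(cts))
    }, numeric(1))
    data.frame(from = g$input_id[1], to = g$consumer_id[1],
               p = combine_rework_probabilities(p_class),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$from, unique(observations$input_id)),
            match(res$to, unique(observations$consumer_id))), , drop = FALSE]
}

#' Fit triangular durations for every activity in a duration-sample table
#'
#' @param samples data frame with columns `activity_id` and `duration_min`
#'   (long format, one row per observed execution).
#' @param mode_estimator passed to [fit_triangular()].
#' @return Data frame with columns `id`, `bcv`, `mlv`, `wcv`.
#' @export
estimate_durations <- function(samples, mode_estimator = "auto") {
  required <- c("activity_id", "duration_min")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("duration-sample table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  groups <- split(samples$duration_min, samples$activity_id)
  ids <- names(groups)
  fits <- lapply(groups, fit_triangular, mode_estimator = mode_estimator)
  data.frame(id = ids,
             bcv = vapply(fits, `[[`, numeric(1), "bcv"),
             mlv = vapply(fits, `[[`, numeric(1), "mlv"),
             wcv = vapply(fits, `[[`, numeric(1), "wcv"),
             row.names = NULL, stringsAsFactors = FALSE)
}
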