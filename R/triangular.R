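#' Triangular three-point duration estimate
#'
#' Construct a triangular duration distribution from a three-point estimate:
#' the best case value (`bcv`, the distribution minimum), the most likely
#' value (`mlv`, the mode) and the worst case value (`wcv`, the maximum), all
#' in minutes.  The degenerate case `bcv == mlv == wcv` is allowed and
#' represents a deterministic duration.
#'
#' @param bcv best case value (minimum), minutes, `>= 0`.
#' @param mlv most likely value (mode), minutes, `bcv <= mlv <= wcv`.
#' @param wcv worst case value (maximum), minutes.
#' @return An object of class `triangular_duration` with fields `bcv`,
#'   `mlv`, `wcv`.
#' @examples
#' d <- triangular_duration(2, 3, 6)
#' sample_duration(d, 0.5)
#' @export
triangular_duration <- function(bcv, mlv, wcv) {
  stopifnot(is.numeric(bcv), is.numeric(mlv), is.numeric(wcv),
            length(bcv) == 1L, length(mlv) == 1L, length(wcv) == 1L)
  if (!is.finite(bcv) || !is.finite(mlv) || !is.finite(wcv))
    stop("triangular duration values must be finite", call. = FALSE)
  if (bcv < 0)
    stop("bcv must be >= 0, got ", bcv, call. = FALSE)
  if (!(bcv <= mlv && mlv <= wcv))
    stop(sprintf("triangular duration requires bcv <= mlv <= wcv, got (%g, %g, %g)",
                 bcv, mlv, wcv), call. = FALSE)
  structure(list(bcv = as.numeric(bcv), mlv = as.numeric(mlv),
                 wcv = as.numeric(wcv)),
            class = "triangular_duration")
}

#' @export
print.triangular_duration <- function(x, ...) {
  cat(sprintf("<triangular duration: bcv=%.1f, mlv=%.1f, wcv=%.1f min>\n",
              x$bcv, x$mlv, x$wcv))
  invisible(x)
}

#' @export
format.triangular_duration <- function(x, ...) {
  sprintf("(%g, %g, %g)", x$bcv, x$mlv, x$wcv)
}

# Vectorised inverse CDF of the triangular distribution.  For u at the
# mode's CDF value both branches agree; degenerate spans collapse to a point.
qtriangular <- function(u, bcv, mlv, wcv) {
  if (any(u < 0 | u > 1, na.rm = TRUE))
    stop("uniform variate must lie in [0, 1]", call. = FALSE)
  n <- max(length(u), length(bcv), length(mlv), length(wcv))
  u <- rep_len(u, n); b <- rep_len(bcv, n)
  m <- rep_len(mlv, n); w <- rep_len(wcv, n)
  out <- numeric(n)
  degen <- (w - b) == 0
  out[degen] <- b[degen]
  if (any(!degen)) {
    fc <- ifelse(degen, 0, (m - b) / (w - b))  # CDF at the mode
    left <- !degen & u <= fc
    right <- !degen & u > fc
    out[left] <- b[left] + sqrt(u[left] * (w[left] - b[left]) * (m[left] - b[left]))
    out[right] <- w[right] -
      sqrt((1 - u[right]) * (w[right] - b[right]) * (w[right] - m[right]))
  }
  pmin(pmax(out, b), w)
}

#' Sample a duration from a triangular distribution by inverse transform
#'
#' Maps a uniform variate `u` in `[0, 1]` through the inverse cumulative
#' distribution function of the triangular distribution, so the result always
#' lies in `[bcv, wcv]` and `u = 0.5` of a symmetric triangle returns the
#' mode.
#'
#' @param d a [triangular_duration()].
#' @param u uniform variate(s) in `[0, 1]`.
#' @return Sampled duration(s) in minutes.
#' @export
sample_duration <- function(d, u) {
  stopifnot(inherits(d, "triangular_duration"))
  qtriangular(u, d$bcv, d$mlv, d$wcv)
}

#' Mean of a triangular duration
#'
#' The triangular distribution mean, `(bcv + mlv + wcv) / 3`.
#'
#' @param d a [triangular_duration()].
#' @return Mean duration in minutes.
#' @export
triangular_mean <- function(d) {
  stopifnot(inherits(d, "triangular_duration"))
  (d$bcv + d$mlv + d$wcv) / 3
}
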