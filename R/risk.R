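#' Rework risk factor of a dependency
#'
#' The per-step risk that a dependency propagates rework: the product of
#' its rework probability and the consumer's rework impact.
#'
#' @param p_ir rework probability in `[0, 1]`.
#' @param ri rework impact in `[0, 1]`.
#' @return Risk factor in `[0, 1]`.
#' @export
risk_factor <- function(p_ir, ri) {
  check_probability(p_ir, "p_ir")
  check_probability(ri, "ri")
  p_ir * ri
}

#' Maximum cumulative risk of rework propagation
#'
#' The n-step propagation risk of a dependency with risk factor `r` is
#' `r^n`; the cumulative risk sums the geometric series over all steps,
#' `sum_{n>=1} r^n = r / (1 - r)` for `r < 1`.  For `r >= 1` the series
#' diverges and the risk is unbounded: `Inf` is returned (with a warning)
#' so that batch analyses can flag the pair rather than crash.
#'
#' @param r risk factor(s), `>= 0`.
#' @return Cumulative risk; `Inf` where `r >= 1`.
#' @examples
#' cumulative_risk(0.5)  # 1
#' cumulative_risk(0.1)  # 0.1111...
#' @export
cumulative_risk <- function(r) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("risk factor must be finite and >= 0", call. = FALSE)
  div <- r >= 1
  if (any(div))
    warning(sum(div), " risk factor(s) >= 1: cumulative risk diverges ",
            "(reported as Inf)", call. = FALSE)
  ifelse(div, Inf, r / (1 - r))
}

#' Row/column risk margins of a cumulative-risk matrix
#'
#' For a cumulative-risk matrix oriented with providing activities in
#' columns and receiving activities in rows (`cr[i, j]` = risk activity `i`
#' receives from activity `j`), returns the column sums `f` (total maximum
#' risk each activity transfers to others), the row sums `e` (total maximum
#' risk each activity receives), the grand total, and the per-activity total
#' `f + e`.  Non-finite entries (divergent pairs) are excluded from all sums
#' and counted.
#'
#' @param cr numeric square matrix of cumulative risks; `NA`/`Inf` entries
#'   mark divergent pairs.
#' @return List with `f`, `e`, `tr_total`, `tr_activity`, `n_divergent`.
#' @export
risk_margins <- function(cr) {
  stopifnot(is.matrix(cr), nrow(cr) == ncol(cr))
  finite <- is.finite(cr)
  masked <- cr
  masked[!finite] <- 0
  f <- colSums(masked)
  e <- rowSums(masked)
  list(f = f, e = e, tr_total = sum(masked),
       tr_activity = f + e, n_divergent = sum(!finite))
}

#' Rework-risk propagation report for a DSM
#'
#' Computes, for every declared dependency, the risk factor
#' `R = P_ir * RI` (rework probability times the consumer's rework impact),
#' the geometric-series cumulative risk `CR = R / (1 - R)`, and the margins:
#' `f[j]` the total maximum risk activity `j` transfers to others, `e[i]`
#' the total maximum risk activity `i` receives, the grand total over all
#' pairs, and the per-activity total `f + e`.  Pairs with `R >= 1`
#' (divergent series) are excluded from the sums and listed separately.
#'
#' Matrices are oriented with receiving (consumer) activities in rows and
#' providing activities in columns, so column sums are transferred risk and
#' row sums are received risk.
#'
#' @param dsm a [build_dsm()] object.
#' @return An object of class `risk_report`: list with matrices `r` and
#'   `cr` (divergent entries `Inf`), vectors `f`, `e`, `tr_activity`,
#'   scalar `tr_total`, and data frame `divergent` (`from`, `to`, `r`).
#' @examples
#' rr <- risk_report(make_aplt_fixture())
#' rr$tr_total
#' @export
risk_report <- function(dsm) {
  stopifnot(inherits(dsm, "dsm"))
  ids <- dsm$activities$id
  m <- length(ids)
  rmat <- matrix(0, m, m, dimnames = list(receiver = ids, provider = ids))
  e <- dsm$edges
  if (nrow(e)) {
    ri <- dsm$activities$rework_impact[match(e$to, ids)]
    rmat[cbind(e$to, e$from)] <- risk_factor(e$p, ri)
  }
  crmat <- suppressWarnings(matrix(cumulative_risk(rmat), m, m,
                                   dimnames = dimnames(rmat)))
  div_idx <- which(rmat >= 1, arr.ind = TRUE, useNames = FALSE)
  divergent <- data.frame(from = ids[div_idx[, 2]],
                          to = ids[div_idx[, 1]],
                          r = rmat[div_idx],
                          stringsAsFactors = FALSE)
  margins <- risk_margins(crmat)
  structure(list(r = rmat, cr = crmat,
                 f = margins$f, e = margins$e,
                 tr_total = margins$tr_total,
                 tr_activity = margins$tr_activity,
                 divergent = divergent),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("<risk report: %d activities>\n", nrow(x$cr)))
  cat(sprintf("  total cumulative risk (finite pairs): %.4f\n", x$tr_total))
  if (nrow(x$divergent))
    cat(sprintf("  divergent pairs (R >= 1, excluded): %s\n",
                paste(sprintf("%s->%s", x$divergent$from, x$divergent$to),
                      collapse = ", ")))
  top <- order(x$tr_activity, decreasing = TRUE)[seq_len(min(3, length(x$tr_activity)))]
  cat("  highest-risk activities (f + e):",
      paste(sprintf("%s=%.3f", names(x$tr_activity)[top],
                    x$tr_activity[top]), collapse = ", "), "\n")
  invisible(x)
}
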