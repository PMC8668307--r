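#' Build a validated design structure matrix (DSM) over surgical activities
#'
#' A DSM is a square dependency structure over an ordered list of activities
#' (surgemes).  The activity order is the intended execution sequence of the
#' protocol.  Each directed edge runs from a provider activity (whose output
#' is an input of the consumer) to a consumer activity and carries the rework
#' probability `p` that a change in the provider forces the consumer to be
#' repeated.  Self-edges are rejected: the matrix diagonal is blank.
#'
#' @param activities a data frame with columns:
#'   \describe{
#'     \item{id}{short unique identifier (character).}
#'     \item{label}{free-text description (optional, defaults to `id`).}
#'     \item{bcv, mlv, wcv}{triangular three-point duration estimate,
#'       minutes, `0 <= bcv <= mlv <= wcv`.}
#'     \item{rework_impact}{fraction of the activity that must be repeated
#'       when rework occurs, in `[0, 1]`.}
#'     \item{improvement_curve}{either a numeric column (constant multiplier)
#'       or a list column of numeric vectors: the multiplier applied to the
#'       i-th successive rework iteration, each in `(0, 1]`.  A single value
#'       means a constant improvement curve.}
#'   }
#' @param edges a data frame with columns `from` (provider id), `to`
#'   (consumer id) and `p` (rework probability in `[0, 1]`).  May have zero
#'   rows.  `p = 0` edges are kept as declared dependencies that never
#'   trigger rework.
#' @return An object of class `dsm`: a list with elements `activities`
#'   (validated data frame, `improvement_curve` as a list column) and `edges`.
#' @examples
#' acts <- data.frame(id = c("A1", "A2"), bcv = c(1, 2), mlv = c(2, 3),
#'                    wcv = c(4, 5), rework_impact = 0.1,
#'                    improvement_curve = 1)
#' dsm <- build_dsm(acts, data.frame(from = "A1", to = "A2", p = 0.1))
#' dsm
#' @export
build_dsm <- function(activities, edges = NULL) {
  activities <- as.data.frame(activities, stringsAsFactors = FALSE)
  if (nrow(activities) < 1L)
    stop("a DSM needs at least one activity", call. = FALSE)
  required <- c("id", "bcv", "mlv", "wcv")
  missing_cols <- setdiff(required, names(activities))
  if (length(missing_cols))
    stop("activity table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  activities$id <- as.character(activities$id)
  dup <- activities$id[duplicated(activities$id)]
  if (length(dup))
    stop("duplicate activity id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (is.null(activities$label)) activities$label <- activities$id
  if (is.null(activities$rework_impact)) activities$rework_impact <- 0
  if (is.null(activities$improvement_curve)) activities$improvement_curve <- 1

  bad_ri <- activities$rework_impact < 0 | activities$rework_impact > 1 |
    !is.finite(activities$rework_impact)
  if (any(bad_ri))
    stop("rework_impact outside [0, 1] for activity: ",
         paste(activities$id[bad_ri], collapse = ", "), call. = FALSE)

  # normalise the improvement curve to a list column of numeric vectors
  ic <- activities$improvement_curve
  if (!is.list(ic)) ic <- as.list(as.numeric(ic))
  ic <- lapply(ic, as.numeric)
  ok_ic <- vapply(ic, function(v) {
    length(v) >= 1L && all(is.finite(v)) && all(v > 0) && all(v <= 1)
  }, logical(1))
  if (any(!ok_ic))
    stop("improvement_curve multipliers must all lie in (0, 1] for activity: ",
         paste(activities$id[!ok_ic], collapse = ", "), call. = FALSE)
  activities$improvement_curve <- ic

  for (i in seq_len(nrow(activities))) {
    tryCatch(
      triangular_duration(activities$bcv[i], activities$mlv[i],
                          activities$wcv[i]),
      error = function(e)
        stop("invalid duration for activity ", activities$id[i], ": ",
             conditionMessage(e), call. = FALSE))
  }

  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(), p = numeric(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    missing_e <- setdiff(c("from", "to"), names(edges))
    if (length(missing_e))
      stop("edge table is missing column(s): ",
           paste(missing_e, collapse = ", "), call. = FALSE)
    if (is.null(edges$p)) edges$p <- 1
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    dangling <- setdiff(c(edges$from, edges$to), activities$id)
    if (length(dangling))
      stop("edge endpoint(s) not in activity list: ",
           paste(unique(dangling), collapse = ", "), call. = FALSE)
    self <- edges$from == edges$to
    if (any(self))
      stop("self-edge(s) not allowed (diagonal is blank): ",
           paste(unique(edges$from[self]), collapse = ", "), call. = FALSE)
    bad_p <- !is.finite(edges$p) | edges$p < 0 | edges$p > 1
    if (any(bad_p))
      stop("rework probability outside [0, 1] on edge(s): ",
           paste(sprintf("%s->%s", edges$from[bad_p], edges$to[bad_p]),
                 collapse = ", "), call. = FALSE)
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop("duplicate edge: ", sub("\r", "->", d), call. = FALSE)
    }
    rownames(edges) <- NULL
  }
  rownames(activities) <- NULL
  structure(list(activities = activities[, c("id", "label", "bcv", "mlv",
                                             "wcv", "rework_impact",
                                             "improvement_curve")],
                 edges = edges[, c("from", "to", "p")]),
            class = "dsm")
}

#' @export
print.dsm <- function(x, ...) {
  n <- nrow(x$activities)
  cat(sprintf("<dsm: %d activities, %d dependencies>\n", n, nrow(x$edges)))
  cat("  sequence:", paste(x$activities$id, collapse = " -> "), "\n")
  cat(sprintf("  total MLV: %.1f min\n", sum(x$activities$mlv)))
  invisible(x)
}

#' Number of activities in a DSM
#' @param dsm a [build_dsm()] object.
#' @return Integer activity count.
#' @export
n_activities <- function(dsm) {
  stopifnot(inherits(dsm, "dsm"))
  nrow(dsm$activities)
}

# Dense rework-probability matrix in the "column-inputs" convention:
# cell [i, j] holds P for the edge i -> j (reading down column j gives the
# inputs of activity j).  Missing dependencies are 0.
dsm_matrix <- function(dsm) {
  ids <- dsm$activities$id
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(dsm$edges))
    m[cbind(dsm$edges$from, dsm$edges$to)] <- dsm$edges$p
  m
}
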