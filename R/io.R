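#' Read and write the activity table CSV
#'
#' Columns: `id,label,bcv,mlv,wcv,rework_impact,improvement_curve`, with the
#' improvement curve serialised as semicolon-separated multipliers (one per
#' successive rework iteration).
#'
#' @param path CSV file path.
#' @return `read_activity_table()`: a data frame suitable for
#'   [build_dsm()]; `write_activity_table()`: the path, invisibly.
#' @export
read_activity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  if (!is.null(df$improvement_curve))
    df$improvement_curve <- lapply(strsplit(as.character(df$improvement_curve),
                                            ";", fixed = TRUE),
                                   as.numeric)
  df
}

#' @param activities an activity data frame or a `dsm` object.
#' @rdname read_activity_table
#' @export
write_activity_table <- function(activities, path) {
  if (inherits(activities, "dsm")) activities <- activities$activities
  out <- activities
  ic <- out$improvement_curve
  if (is.list(ic))
    out$improvement_curve <- vapply(ic, function(v)
      paste(sprintf("%.17g", v), collapse = ";"), character(1))
  # %.17g so doubles survive the text round trip bit-exactly
  for (col in c("bcv", "mlv", "wcv", "rework_impact"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write the square DSM matrix CSV
#'
#' The matrix file has identical first-row and first-column activity ids;
#' a cell holds the rework probability of a dependency and blank or `0`
#' means no dependency.  Orientation `"column-inputs"` (default) means that
#' reading down column `j` gives the inputs of activity `j` (a value in row
#' `i`, column `j` is the edge `i -> j`); `"row-inputs"` is the transposed
#' convention.
#'
#' @param path CSV file path.
#' @param orientation `"column-inputs"` or `"row-inputs"`.
#' @return `read_dsm_matrix()`: a list with `ids` (row/column order) and
#'   `edges` (`from`, `to`, `p`); `write_dsm_matrix()`: the path, invisibly.
#' @export
read_dsm_matrix <- function(path,
                            orientation = c("column-inputs", "row-inputs")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         row.names = 1)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("DSM matrix must be square with identical row and column ids",
         call. = FALSE)
  mode(m) <- "numeric"
  m[is.na(m)] <- 0
  if (orientation == "row-inputs") m <- t(m)
  nz <- which(m != 0, arr.ind = TRUE)
  edges <- data.frame(from = rownames(m)[nz[, 1]],
                      to = colnames(m)[nz[, 2]],
                      p = m[nz], stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$from, rownames(m)),
                       match(edges$to, colnames(m))), , drop = FALSE]
  rownames(edges) <- NULL
  list(ids = rownames(m), edges = edges)
}

#' @param dsm a [build_dsm()] object.
#' @rdname read_dsm_matrix
#' @export
write_dsm_matrix <- function(dsm, path,
                             orientation = c("column-inputs", "row-inputs")) {
  orientation <- match.arg(orientation)
  m <- dsm_matrix(dsm)
  if (orientation == "row-inputs") m <- t(m)
  chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  chr[m == 0] <- ""                  # blank cell = no dependency
  utils::write.csv(as.data.frame(chr), path, row.names = TRUE)
  invisible(path)
}

#' Read and write a DSM as JSON
#'
#' Format: `{"activities": [...], "edges": [{"from": .., "to": .., "p": ..}]}`
#' with the improvement curve as an array per activity.
#'
#' @param dsm a [build_dsm()] object.
#' @param path JSON file path.
#' @return `read_dsm_json()`: a validated `dsm`; `write_dsm_json()`: the
#'   path, invisibly.
#' @export
write_dsm_json <- function(dsm, path) {
  acts <- dsm$activities
  payload <- list(
    activities = lapply(seq_len(nrow(acts)), function(i) list(
      id = acts$id[i], label = acts$label[i],
      bcv = acts$bcv[i], mlv = acts$mlv[i], wcv = acts$wcv[i],
      rework_impact = acts$rework_impact[i],
      improvement_curve = as.numeric(acts$improvement_curve[[i]]))),
    edges = if (nrow(dsm$edges)) lapply(seq_len(nrow(dsm$edges)), function(i)
      list(from = dsm$edges$from[i], to = dsm$edges$to[i],
           p = dsm$edges$p[i])) else list())
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_dsm_json
#' @export
read_dsm_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  acts <- do.call(rbind, lapply(payload$activities, function(a)
    data.frame(id = a$id, label = a$label, bcv = a$bcv, mlv = a$mlv,
               wcv = a$wcv, rework_impact = a$rework_impact,
               stringsAsFactors = FALSE)))
  acts$improvement_curve <- lapply(payload$activities, function(a)
    as.numeric(unlist(a$improvement_curve)))
  edges <- if (length(payload$edges))
    do.call(rbind, lapply(payload$edges, function(e)
      data.frame(from = e$from, to = e$to, p = e$p,
                 stringsAsFactors = FALSE)))
  else NULL
  build_dsm(acts, edges)
}

#' Read a simulation configuration from JSON or YAML
#'
#' Recognised keys: `n_runs`, `seed`, `max_reworks_per_edge`,
#' `rework_trigger`, `duration_source`; missing keys take the
#' [sim_config()] defaults.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("unsupported config format: .", ext, call. = FALSE))
  defaults <- list(n_runs = 1000L, seed = 1L, max_reworks_per_edge = NULL,
                   rework_trigger = "standard", duration_source = "sampled")
  known <- intersect(names(raw), names(defaults))
  args <- utils::modifyList(defaults, raw[known])
  do.call(sim_config, args)
}

#' Write simulation results to disk
#'
#' Writes the summary statistics as JSON and, optionally, the per-run
#' totals and a histogram binning as CSV.
#'
#' @param result a [run_monte_carlo()] result.
#' @param path output JSON path for the summary.
#' @param totals_csv optional path for a per-run totals CSV
#'   (`run,total_min`).
#' @param histogram_csv optional path for a histogram-bin CSV
#'   (`bin_lower,bin_upper,count`).
#' @param bins number of histogram bins.
#' @return `path`, invisibly.
#' @export
write_simulation_result <- function(result, path, totals_csv = NULL,
                                    histogram_csv = NULL, bins = 30L) {
  stopifnot(inherits(result, "dsm_simulation"))
  jsonlite::write_json(result$summary, path, auto_unbox = TRUE,
                       digits = I(17))
  if (!is.null(totals_csv))
    utils::write.csv(data.frame(run = seq_along(result$totals),
                                total_min = result$totals),
                     totals_csv, row.names = FALSE)
  if (!is.null(histogram_csv)) {
    h <- graphics::hist(result$totals, breaks = bins, plot = FALSE)
    utils::write.csv(data.frame(bin_lower = utils::head(h$breaks, -1),
                                bin_upper = h$breaks[-1],
                                count = h$counts),
                     histogram_csv, row.names = FALSE)
  }
  invisible(path)
}

#' Read observation tallies and duration samples
#'
#' Observation CSV columns: `input_id,consumer_id,class,n_o,n_oc,n_ic,n_ir`;
#' duration-sample CSV columns: `activity_id,duration_min` (long format).
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_observations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(input_id = "character",
                                 consumer_id = "character"))
}

#' @rdname read_observations
#' @export
read_duration_samples <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(activity_id = "character"))
}

#' Write a risk report
#'
#' JSON layout: activity ids, `r` and `cr` as nested arrays in id order
#' (divergent entries as the string `"divergent"`), the margins and the
#' divergent-pair list.  Optionally also writes the cumulative-risk matrix
#' as CSV.
#'
#' @param report a [risk_report()].
#' @param path output JSON path.
#' @param cr_csv optional CSV path for the cumulative-risk matrix.
#' @return `path`, invisibly.
#' @export
write_risk_report <- function(report, path, cr_csv = NULL) {
  stopifnot(inherits(report, "risk_report"))
  cr <- report$cr
  cr_cells <- apply(cr, 1, function(row)
    lapply(row, function(v) if (is.finite(v)) v else "divergent"),
    simplify = FALSE)
  payload <- list(activities = colnames(cr),
                  orientation = "rows receive, columns provide",
                  r = apply(report$r, 1, as.list, simplify = FALSE),
                  cr = cr_cells,
                  f = as.list(report$f), e = as.list(report$e),
                  tr_total = report$tr_total,
                  tr_activity = as.list(report$tr_activity),
                  divergent = report$divergent)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(cr_csv))
    utils::write.csv(as.data.frame(report$cr), cr_csv, row.names = TRUE)
  invisible(path)
}
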