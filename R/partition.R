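#' Partition a DSM into rework loops and active sets
#'
#' Identifies the rework loops of a dependency structure as the strongly
#' connected components of size two or more of the directed dependency
#' graph, sequences the activities consistently with a topological sort of
#' the loop-condensed graph (ties broken by the declared activity order, and
#' members of a loop kept in declared order), and cuts the sequence into
#' active sets: maximal consecutive groups of activities executable before
#' encountering a dependency on an activity that has not yet been executed.
#'
#' The declared activity order is the protocol's execution sequence; loops
#' are reported, not reordered.
#'
#' @param dsm a [build_dsm()] object.
#' @return An object of class `dsm_partition`: a list with
#'   \describe{
#'     \item{order}{character vector, the sequenced activity ids.}
#'     \item{loops}{list of character vectors, each a rework loop in
#'       declared activity order; empty list when the graph is acyclic.}
#'     \item{active_sets}{list of character vectors partitioning `order`.}
#'   }
#' @examples
#' dsm <- make_amis_fixture()
#' partition_dsm(dsm)$loops
#' @export
partition_dsm <- function(dsm) {
  stopifnot(inherits(dsm, "dsm"))
  ids <- dsm$activities$id
  n <- length(ids)
  g <- igraph::graph_from_data_frame(
    dsm$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g, mode = "strong")
  membership <- comp$membership[ids]  # by declared order

  # loops: SCCs of size >= 2, members listed in declared order
  sizes <- tabulate(membership, nbins = comp$no)
  loop_comp_ids <- which(sizes >= 2L)
  loops <- lapply(loop_comp_ids, function(cid) ids[membership == cid])
  # report loops in order of first member appearance
  if (length(loops) > 1L) {
    first <- vapply(loops, function(l) match(l[1], ids), integer(1))
    loops <- loops[order(first)]
  }

  # condensation topological order, Kahn's algorithm with ties broken by
  # the smallest declared index among each component's members
  comp_key <- vapply(seq_len(comp$no), function(cid)
    min(which(membership == cid)), integer(1))
  cfrom <- membership[dsm$edges$from]
  cto <- membership[dsm$edges$to]
  keep <- cfrom != cto
  cedges <- unique(data.frame(from = cfrom[keep], to = cto[keep]))
  indeg <- tabulate(cedges$to, nbins = comp$no)
  remaining <- rep(TRUE, comp$no)
  comp_order <- integer(0)
  while (any(remaining)) {
    avail <- which(remaining & indeg == 0L)
    nxt <- avail[which.min(comp_key[avail])]
    comp_order <- c(comp_order, nxt)
    remaining[nxt] <- FALSE
    out <- cedges$to[cedges$from == nxt]
    for (v in out) indeg[v] <- indeg[v] - 1L
  }
  order_ids <- unlist(lapply(comp_order, function(cid)
    ids[membership == cid]), use.names = FALSE)

  # active sets: scan the order, cut when the next activity has an
  # unexecuted upstream dependency
  providers <- split(dsm$edges$from, dsm$edges$to)
  executed <- character(0)
  sets <- list()
  current <- character(0)
  for (a in order_ids) {
    prov <- providers[[a]]
    if (length(current) && length(prov) && !all(prov %in% executed)) {
      sets[[length(sets) + 1L]] <- current
      current <- character(0)
    }
    current <- c(current, a)
    executed <- c(executed, a)
  }
  if (length(current)) sets[[length(sets) + 1L]] <- current

  structure(list(order = order_ids, loops = loops, active_sets = sets),
            class = "dsm_partition")
}

#' @export
print.dsm_partition <- function(x, ...) {
  cat("<dsm partition>\n")
  cat("  order:", paste(x$order, collapse = " -> "), "\n")
  if (length(x$loops)) {
    for (i in seq_along(x$loops))
      cat(sprintf("  loop %d: {%s}\n", i, paste(x$loops[[i]], collapse = ", ")))
  } else {
    cat("  loops: none\n")
  }
  for (i in seq_along(x$active_sets))
    cat(sprintf("  active set %d: %s\n", i,
                paste(x$active_sets[[i]], collapse = ", ")))
  invisible(x)
}
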