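# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: reachability by Boolean closure, series by brute
# summation, quantiles by numeric CDF inversion.

# Strongly connected components of size >= 2 by Warshall reachability:
# a brute-force check for partition_dsm()'s loop detection.
oracle_loops <- function(ids, edges) {
  n <- length(ids)
  reach <- matrix(FALSE, n, n)
  if (nrow(edges))
    reach[cbind(match(edges$from, ids), match(edges$to, ids))] <- TRUE
  for (k in seq_len(n))
    for (i in seq_len(n))
      if (reach[i, k])
        reach[i, ] <- reach[i, ] | reach[k, ]
  mutual <- reach & t(reach)
  in_cycle <- diag(reach)
  seen <- rep(FALSE, n)
  loops <- list()
  for (i in seq_len(n)) {
    if (!in_cycle[i] || seen[i]) next
    members <- which(mutual[i, ] & in_cycle)
    members <- sort(unique(c(i, members)))
    seen[members] <- TRUE
    if (length(members) >= 2L)
      loops[[length(loops) + 1L]] <- ids[members]
  }
  loops
}

loops_as_canonical <- function(loops) {
  if (!length(loops)) return(character(0))
  sort(vapply(loops, function(l) paste(sort(l), collapse = "|"), character(1)))
}

# Exhaustive pmf summation for the capped leading-run count:
# P(nr = k) = q^k (1 - q) for k < cap, P(nr = cap) = q^cap.
oracle_truncated_geometric_mean <- function(q, cap) {
  k <- seq_len(cap - 1)
  sum(k * q^k * (1 - q)) + cap * q^cap
}

# Triangular CDF in closed form, used to invert numerically.
oracle_tri_cdf <- function(x, a, m, b) {
  if (x <= a) return(0)
  if (x >= b) return(1)
  if (x <= m) (x - a)^2 / ((b - a) * (m - a)) else 1 - (b - x)^2 / ((b - a) * (b - m))
}

oracle_tri_quantile <- function(u, a, m, b) {
  if (u == 0) return(a)
  if (u == 1) return(b)
  stats::uniroot(function(x) oracle_tri_cdf(x, a, m, b) - u,
                 lower = a, upper = b, tol = 1e-12)$root
}

# Independent triangular sampler for distribution-level comparisons.
oracle_tri_sample <- function(n, a, m, b) {
  u <- stats::runif(n)
  vapply(u, oracle_tri_quantile, numeric(1), a = a, m = m, b = b)
}

# Degenerate-duration two-activity rework loop used in analytic checks.
make_two_activity_loop <- function(d = 10, p = 0.5, ri = 0.5) {
  acts <- data.frame(id = c("A", "B"), bcv = d, mlv = d, wcv = d,
                     rework_impact = ri, improvement_curve = 1,
                     stringsAsFactors = FALSE)
  build_dsm(acts, data.frame(from = c("A", "B"), to = c("B", "A"), p = p))
}
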