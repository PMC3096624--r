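# Independent oracles used by the property and acceptance tests.
# These deliberately avoid the package's interval-sweep code path:
# heights come from ape's edge-depth routine and lineage counts are
# obtained geometrically, by counting edges that span each interval's
# midpoint, with entities re-derived directly from the threshold.

oracle_heights <- function(phy) {
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  max(depth[seq_len(n)]) - depth
}

# log-likelihood of the threshold model recomputed from scratch;
# lambda1/lambda2 with exponents p1/p2, threshold T in height units
oracle_threshold_loglik <- function(phy, threshold, lambda1, lambda2,
                                    p1, p2) {
  n <- length(phy$tip.label)
  h <- oracle_heights(phy)
  internal <- (n + 1L):(2L * n - 1L)
  ev <- sort(h[internal], decreasing = TRUE)
  bounds <- c(ev, 0)
  ## cluster roots: coalescent nodes (h <= T) whose parent is
  ## diversification (h > T) or that are the root
  parent <- integer(2L * n - 1L)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  is_coal <- h <= threshold
  cl_roots <- internal[vapply(internal, function(nd) {
    is_coal[nd] && (nd == n + 1L || !is_coal[parent[nd]])
  }, NA)]
  desc <- lapply(cl_roots, function(r) {
    ## all nodes with r on their path to the root
    vapply(seq_len(2L * n - 1L), function(nd) {
      while (nd != n + 1L && nd != r) nd <- parent[nd]
      nd == r
    }, NA)
  })
  any_div <- any(!is_coal[internal])
  ## entities = lineages crossing the threshold: cluster roots plus tips
  ## whose parent is above it; the Yule count is frozen there below T
  n_entities <- length(cl_roots) +
    sum(vapply(seq_len(n), function(tp) !is_coal[parent[tp]], NA))

  ll <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    x <- bounds[i] - bounds[i + 1L]
    mid <- (bounds[i] + bounds[i + 1L]) / 2
    crossing <- which(h[phy$edge[, 2L]] < mid & h[phy$edge[, 1L]] > mid)
    child <- phy$edge[crossing, 2L]
    b <- 0
    for (j in seq_along(cl_roots)) {
      inside <- desc[[j]][child]           # child within cluster subtree
      ncl <- sum(inside)
      if (ncl > 1L) b <- b + lambda2 * (ncl * (ncl - 1L))^p2
    }
    ## above the threshold every crossing edge is a Yule lineage (no
    ## cluster-internal edge can reach up there); below it the count is
    ## frozen at the number of entities
    n_div <- if (mid > threshold) length(crossing) else n_entities
    if (any_div) b <- b + lambda1 * n_div^p1
    ll <- ll + log(b) - b * x
  }
  ll
}

# chi-square upper-tail probability by numeric integration of the
# density, independent of stats::pchisq
oracle_chisq_upper <- function(q, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) /
    (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, lower = q, upper = Inf,
                   rel.tol = 1e-10)$value
}

# brute-force maximization of the null likelihood over lambda with p
# fixed, on a log-spaced grid refined by optimize(); independent route
# for the analytic-MLE check
oracle_null_lambda_hat <- function(iv, p) {
  f <- function(loglam) gmycdelim::null_loglik(iv, exp(loglam), p)
  stats::optimize(f, interval = c(log(1e-10), log(1e10)),
                  maximum = TRUE, tol = 1e-12)$maximum
}
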