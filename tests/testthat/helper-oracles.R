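# Independent oracles shared across test files. Each re-derives its target
# quantity from first principles, independently of the package internals.

# Union of all minimum spanning trees, by exhaustive enumeration of every
# spanning tree of the complete graph on the distance matrix.
msn_oracle <- function(d) {
  k <- nrow(d)
  if (k == 1) return(matrix(numeric(0), 0, 2))
  all_edges <- t(combn(k, 2))
  trees <- combn(nrow(all_edges), k - 1, simplify = FALSE)
  spanning <- Filter(function(sel) {
    g <- igraph::graph_from_edgelist(all_edges[sel, , drop = FALSE],
                                     directed = FALSE)
    igraph::vcount(g) == k && igraph::is_connected(g)
  }, trees)
  weights <- vapply(spanning, function(sel)
    sum(d[all_edges[sel, , drop = FALSE]]), 1)
  keep <- spanning[weights <= min(weights) + 1e-9]
  unique(do.call(rbind, lapply(keep, function(sel)
    all_edges[sel, , drop = FALSE])))
}

sort_edges <- function(m) {
  m <- t(apply(m, 1, sort))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Tajima's D from the 1989 coefficient chain, written independently.
taj_oracle <- function(n, S, khat) {
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (khat - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# Sums of squared distances within one index set, by explicit loops.
ssd_oracle <- function(d2, idx) {
  s <- 0
  for (i in idx) for (j in idx) s <- s + d2[i, j]
  s / (2 * length(idx))
}
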