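# Independent brute-force oracles used to cross-check the package's
# graph and FDR code. Deliberately written with different algorithms
# from the implementation.

# All-pairs shortest paths by Floyd-Warshall on a logical adjacency.
floydWarshall <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Efficiency of the induced subgraph via Floyd-Warshall distances.
efficiencyOracle <- function(A, nodes) {
  d <- floydWarshall(A[nodes, nodes, drop = FALSE])
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

# MST-anchored threshold oracle: igraph's minimum spanning tree on
# negated weights, then greedy addition of the strongest positive
# non-tree links until the edge target is reached. Assumes no weight
# ties (use continuous random weights).
mstThresholdOracle <- function(W, density) {
  n <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(-W, mode = "upper",
                                           weighted = TRUE, diag = FALSE)
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  te <- igraph::as_edgelist(tree)
  te <- t(apply(matrix(as.integer(te), ncol = 2), 1, sort))
  key <- function(e) paste(e[, 1], e[, 2])
  idx <- which(upper.tri(W), arr.ind = TRUE)
  ord <- order(-W[idx])
  target <- density * n * (n - 1) / 2
  chosen <- key(te)
  for (r in ord) {
    if (length(chosen) >= target) break
    k <- paste(idx[r, 1], idx[r, 2])
    if (k %in% chosen || W[idx[r, 1], idx[r, 2]] <= 0) next
    chosen <- c(chosen, k)
  }
  sort(chosen)
}

# Participation coefficient by direct per-node edge counting.
participationOracle <- function(A, comm) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k == 0) return(0)
    1 - sum((table(comm[nb]) / k)^2)
  }, numeric(1))
}

# Literal step-up BH implementation.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}

# Edge-set key of a BinaryGraph, comparable with mstThresholdOracle().
graphKey <- function(g) {
  e <- graphEdges(g)
  sort(paste(e[, 1], e[, 2]))
}
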