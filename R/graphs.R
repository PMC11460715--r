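# Union-find with path compression (for Kruskal).
.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' MST-anchored proportional thresholding
#'
#' Binarizes a weighted adjacency matrix while guaranteeing a connected
#' network: the maximum spanning tree of the weights is always included,
#' then the strongest remaining positive links are added (weight
#' descending, ties broken by the lexicographically smaller node pair)
#' until the edge count reaches `density * n(n-1)/2`. Negative links are
#' never added beyond the MST; if the MST itself needs a negative weight
#' to connect the graph, it is used. If the MST alone already exceeds the
#' requested density, the MST is returned and the realized density is
#' reported in the object.
#'
#' @param adjacency [Adjacency-class] or symmetric numeric matrix.
#' @param density requested edge density; the study grid is 0.10, 0.20,
#'   0.30.
#' @return a [BinaryGraph-class].
#' @export
mstThreshold <- function(adjacency, density) {
  W <- if (is(adjacency, "Adjacency")) adjacencyWeights(adjacency)
  else as.matrix(adjacency)
  n <- nrow(W)
  if (density <= 0 || density > 1) stop("'density' must lie in (0, 1]")
  idx <- .linkIndex(n)
  w <- W[idx]
  w[is.na(w)] <- -Inf
  ord <- order(-w, idx[, 1], idx[, 2])   # weight desc, then (i, j) asc
  parent <- seq_len(n)
  inMst <- logical(nrow(idx))
  nComp <- n
  for (e in ord) {
    if (nComp == 1L) break
    ri <- .ufFind(parent, idx[e, 1])
    rj <- .ufFind(parent, idx[e, 2])
    if (ri != rj) {
      parent[ri] <- rj
      inMst[e] <- TRUE
      nComp <- nComp - 1L
    }
  }
  target <- density * n * (n - 1) / 2
  chosen <- inMst
  count <- sum(chosen)
  if (count >= target && count > 0) {
    if (count > target)
      message("MST alone (", count, " edges) exceeds the requested ",
              "density; realized density ", signif(count / (n * (n - 1) / 2), 3))
  } else {
    for (e in ord) {
      if (count >= target) break
      if (chosen[e] || w[e] <= 0) next
      chosen[e] <- TRUE
      count <- count + 1L
    }
  }
  edges <- idx[chosen, , drop = FALSE]
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  new("BinaryGraph", edges = edges, nNodes = as.integer(n),
      density = nrow(edges) / (n * (n - 1) / 2),
      requestedDensity = density)
}

#' Participation coefficient
#'
#' For node i with degree k_i and k_is edges into community s,
#' `PC_i = 1 - sum_s (k_is / k_i)^2`: 0 when all edges stay inside one
#' community, approaching 1 when edges spread evenly over many
#' communities. An isolated node is assigned PC 0 by convention. The
#' network mean (between-network integration of a network) averages PC
#' over the network's nodes.
#'
#' @param graph a [BinaryGraph-class].
#' @param communities character/factor community label per node.
#' @return list with `perNode` (numeric per node) and `perNetwork`
#'   (named numeric, mean PC per community).
#' @export
participation <- function(graph, communities) {
  stopifnot(is(graph, "BinaryGraph"))
  n <- graphNodes(graph)
  if (length(communities) != n)
    stop("need one community label per node")
  A <- graphMatrix(graph)
  k <- rowSums(A)
  comm <- as.character(communities)
  labs <- unique(comm)
  kis <- sapply(labs, function(s) rowSums(A[, comm == s, drop = FALSE]))
  frac <- kis / pmax(k, 1)
  pc <- 1 - rowSums(frac^2)
  pc[k == 0] <- 0
  perNetwork <- vapply(labs, function(s) mean(pc[comm == s]), numeric(1))
  list(perNode = pc, perNetwork = perNetwork)
}

#' Within-network global efficiency
#'
#' Induces the subgraph on one network's nodes and returns the mean
#' inverse shortest-path length over its unordered node pairs
#' (unweighted paths; disconnected pairs contribute 0). A singleton
#' network has no pairs and is reported as NA.
#'
#' @param graph a [BinaryGraph-class].
#' @param networkLabel the community whose nodes are used.
#' @param communities community label per node.
#' @return efficiency in `[0, 1]`, or NA for a singleton network.
#' @export
efficiencyWithin <- function(graph, networkLabel, communities) {
  stopifnot(is(graph, "BinaryGraph"))
  nodes <- which(as.character(communities) == networkLabel)
  if (length(nodes) < 2) return(NA_real_)
  A <- graphMatrix(graph)[nodes, nodes, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  d <- igraph::distances(g)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Graph-metric series across sessions, networks and thresholds
#'
#' Thresholds every session's adjacency at each density and tabulates
#' the network-mean participation coefficient and the within-network
#' global efficiency for the networks of interest. The whole-graph
#' matrix is thresholded first and then subdivided (`mode = "whole"`,
#' the default); `mode = "subnetwork"` instead thresholds each network's
#' block separately before computing efficiency.
#'
#' @param stack list of [Adjacency-class] objects (r domain), one per
#'   session.
#' @param atlas atlas data.frame with a `network` column.
#' @param networks character vector of networks of interest.
#' @param densities numeric vector of proportional thresholds
#'   (default `c(0.10, 0.20, 0.30)`).
#' @param mode `"whole"` or `"subnetwork"` (efficiency only; the
#'   participation coefficient always needs the whole graph).
#' @return data.frame with columns `sessionDay`, `task`, `network`,
#'   `metric`, `threshold`, `value`.
#' @export
metricSeries <- function(stack, atlas, networks = unique(atlas$network),
                         densities = c(0.10, 0.20, 0.30),
                         mode = c("whole", "subnetwork")) {
  mode <- match.arg(mode)
  comm <- atlas$network
  rows <- list()
  for (a in stack) {
    W <- adjacencyWeights(a)
    for (dens in densities) {
      g <- mstThreshold(a, dens)
      pc <- participation(g, comm)$perNetwork
      for (net in networks) {
        eff <- if (mode == "whole") {
          efficiencyWithin(g, net, comm)
        } else {
          nodes <- which(comm == net)
          gSub <- mstThreshold(W[nodes, nodes, drop = FALSE], dens)
          efficiencyWithin(gSub, "all",
                           rep("all", length(nodes)))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sessionDay = a@sessionDay, task = a@task, network = net,
          metric = c("participation", "efficiency"),
          threshold = dens, value = c(pc[[net]], eff),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
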