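test_that("MST-anchored thresholding matches contracts on small graphs", {
  # 4 nodes whose 3 strongest links form a spanning tree: density 0.5
  # (3 of 6 edges) keeps exactly those
  W <- matrix(0, 4, 4)
  W[1, 2] <- 0.9; W[2, 3] <- 0.8; W[3, 4] <- 0.7
  W[1, 3] <- 0.2; W[1, 4] <- 0.1; W[2, 4] <- 0.05
  W <- W + t(W); diag(W) <- 1
  g <- mstThreshold(W, 0.5)
  expect_equal(graphKey(g), c("1 2", "2 3", "3 4"))
  expect_equal(graphDensity(g), 0.5)

  # equal weights: deterministic lexicographic tie-break
  We <- matrix(0.5, 5, 5); diag(We) <- 1
  g1 <- mstThreshold(We, 0.4)
  g2 <- mstThreshold(We, 0.4)
  expect_identical(graphEdges(g1), graphEdges(g2))
  expect_equal(nrow(graphEdges(g1)), 4L)  # ceil-free target 0.4*10 = 4

  # density below the MST floor returns the MST with a message
  expect_message(gm <- mstThreshold(W, 0.1), "exceeds")
  expect_equal(nrow(graphEdges(gm)), 3L)
})

test_that("thresholded edge sets equal the independent MST oracle", {
  set.seed(10)
  for (rep in 1:5) {
    n <- 20
    W <- matrix(rnorm(n * n, sd = 0.4), n)
    W <- (W + t(W)) / 2
    diag(W) <- 1
    for (dens in c(0.1, 0.2, 0.3)) {
      g <- mstThreshold(W, dens)
      expect_equal(graphKey(g), mstThresholdOracle(W, dens))
      a <- igraph::graph_from_adjacency_matrix(graphMatrix(g),
                                               mode = "undirected")
      expect_true(igraph::is_connected(a))
    }
  }
})

test_that("participation coefficient matches closed forms and the count oracle", {
  # node 1 with both edges inside its community -> PC 0
  comm <- c("A", "A", "A", "B", "B")
  e <- rbind(c(1, 2), c(1, 3), c(4, 5), c(2, 4))
  g <- new("BinaryGraph", edges = e, nNodes = 5L,
           density = nrow(e) / 10, requestedDensity = 0.4)
  pc <- participation(g, comm)
  expect_equal(pc$perNode[1], 0)
  # node 2: one edge in A, one in B -> 1 - 2 * (1/2)^2 = 0.5
  expect_equal(pc$perNode[2], 0.5)

  set.seed(11)
  for (rep in 1:5) {
    n <- 15
    A <- matrix(runif(n * n) < 0.3, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    A <- A | t(A)
    idx <- which(upper.tri(A) & A, arr.ind = TRUE)
    gr <- new("BinaryGraph",
              edges = idx[order(idx[, 1], idx[, 2]), , drop = FALSE],
              nNodes = as.integer(n), density = nrow(idx) / choose(n, 2),
              requestedDensity = 0.3)
    cm <- sample(c("x", "y", "z"), n, replace = TRUE)
    expect_equal(participation(gr, cm)$perNode,
                 participationOracle(A, cm), tolerance = 1e-12)
    # efficiency against the Floyd-Warshall oracle
    for (lab in unique(cm)) {
      if (sum(cm == lab) < 2) next
      expect_equal(efficiencyWithin(gr, lab, cm),
                   efficiencyOracle(A, which(cm == lab)),
                   tolerance = 1e-12)
    }
  }
})

test_that("within-network efficiency matches closed forms", {
  comm <- rep("N", 3)
  path <- new("BinaryGraph", edges = rbind(c(1L, 2L), c(2L, 3L)),
              nNodes = 3L, density = 2 / 3, requestedDensity = 0.5)
  expect_equal(efficiencyWithin(path, "N", comm), 5 / 6)

  full <- new("BinaryGraph", edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
              nNodes = 3L, density = 1, requestedDensity = 1)
  expect_equal(efficiencyWithin(full, "N", comm), 1)

  # two disconnected pairs: 4 of 6 pairs unreachable contribute 0
  comm4 <- rep("N", 4)
  pairs <- new("BinaryGraph", edges = rbind(c(1L, 2L), c(3L, 4L)),
               nNodes = 4L, density = 2 / 6, requestedDensity = 0.3)
  expect_equal(efficiencyWithin(pairs, "N", comm4), 2 / 6)

  single <- new("BinaryGraph", edges = rbind(c(1L, 2L)), nNodes = 2L,
                density = 1, requestedDensity = 1)
  expect_true(is.na(efficiencyWithin(single, "solo", c("N", "N"))))
})

test_that("mean PC of uniformly random edges over m equal communities is 1 - 1/m", {
  set.seed(12)
  n <- 200; m <- 4
  comm <- rep(letters[1:m], each = n / m)
  A <- matrix(runif(n * n) < 0.5, n, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  A <- A | t(A)
  idx <- which(upper.tri(A) & A, arr.ind = TRUE)
  g <- new("BinaryGraph",
           edges = idx[order(idx[, 1], idx[, 2]), , drop = FALSE],
           nNodes = as.integer(n), density = nrow(idx) / choose(n, 2),
           requestedDensity = 0.5)
  expect_equal(mean(participation(g, comm)$perNode), 1 - 1 / m,
               tolerance = 0.02)
})

test_that("metric series behave across sessions and thresholds", {
  st <- tinyStudy(seed = 13, nSessions = 5, nTime = 250)
  stack <- rawStack(st$sessions)

  # identical adjacency -> constant series
  same <- rep(stack[1], 4)
  mt <- metricSeries(same, st$atlas, densities = 0.2)
  for (nw in unique(mt$network)) {
    for (met in c("participation", "efficiency")) {
      v <- mt$value[mt$network == nw & mt$metric == met]
      expect_equal(var(v), 0)
    }
  }

  # efficiency is non-decreasing in density per session/network
  mt3 <- metricSeries(stack, st$atlas, densities = c(0.1, 0.2, 0.3))
  eff <- mt3[mt3$metric == "efficiency", ]
  for (nw in unique(eff$network)) {
    for (d in unique(eff$sessionDay)) {
      sel <- eff$network == nw & eff$sessionDay == d
      v <- eff$value[sel][order(eff$threshold[sel])]
      expect_true(all(diff(v) >= -1e-12))
    }
  }
})

test_that("injected within-network densification drives the efficiency series", {
  atlas <- genAtlas(20, 4, seed = 14)
  dmn <- which(atlas$network == "DMN")
  links <- t(combn(dmn, 2))
  es <- effectSpec(links, "total_sleep", lagDays = 0, slope = 0.8,
                   baseCorr = 0.3)
  sc <- tinyConfig(nSessions = 20, nTime = 500, nDays = 120)
  beh <- genBehavior(sc, seed = 15)
  gen <- genSessions(sc, atlas, beh$truth, list(es), seed = 16)
  stack <- rawStack(gen$sessions)
  mt <- metricSeries(stack, atlas, networks = "DMN", densities = 0.1)
  eff <- mt[mt$metric == "efficiency", ]
  eff <- eff[order(eff$sessionDay), ]
  fac <- beh$truth$total_sleep[sc$sessionDays]
  expect_gt(cor(fac, eff$value), 0)
})
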