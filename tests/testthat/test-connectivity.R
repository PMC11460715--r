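test_that("Pearson adjacency honors correlation contracts", {
  set.seed(1)
  x <- rnorm(1000)
  m <- cbind(a = x, b = -x, c = rnorm(1000), d = rnorm(1000))
  s <- SessionSeries(m, trSeconds = 0.594, task = "rest", sessionDay = 1)
  A <- adjacencyWeights(pearsonAdjacency(s))
  expect_equal(A["a", "b"], -1, tolerance = 1e-12)
  expect_lt(abs(A["c", "d"]), 0.11)          # 3 / sqrt(n) null bound

  dup <- SessionSeries(cbind(x, x), trSeconds = 0.594)
  expect_equal(adjacencyWeights(pearsonAdjacency(dup))[1, 2], 1)

  flat <- SessionSeries(cbind(x, rep(1, 1000)), trSeconds = 0.594)
  expect_warning(Af <- pearsonAdjacency(flat), "zero-variance")
  expect_true(is.na(adjacencyWeights(Af)[1, 2]))

  short <- SessionSeries(matrix(rnorm(8), 4, 2), trSeconds = 0.594)
  expect_error(pearsonAdjacency(short, keep = c(TRUE, TRUE, FALSE, FALSE)),
               "3 retained")
})

test_that("Pearson adjacency is invariant to positive affine rescaling", {
  set.seed(2)
  m <- matrix(rnorm(600), 200, 3)
  s1 <- SessionSeries(m, trSeconds = 0.594)
  m2 <- sweep(sweep(m, 2, c(2, 5, 0.1), "*"), 2, c(-3, 7, 0), "+")
  s2 <- SessionSeries(m2, trSeconds = 0.594)
  expect_equal(adjacencyWeights(pearsonAdjacency(s1)),
               adjacencyWeights(pearsonAdjacency(s2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("beta-series GLM recovers noiseless trial amplitudes", {
  tr <- 0.594
  nVol <- 400
  trials <- genTrials(12, c(8, 14), seed = 3)
  tGrid <- (seq_len(nVol) - 1) * tr
  set.seed(3)
  amps <- matrix(rnorm(12 * 3, mean = 2), 12, 3)
  D <- sapply(trials$onset, function(o) canonicalHRF(tGrid - o))
  Y <- D %*% amps
  s <- SessionSeries(Y + 1e-9 * matrix(rnorm(length(Y)), nVol),
                     trSeconds = tr, task = "pvt")
  bs <- fitBetaSeries(s, trials)
  expect_equal(unname(bs$betas), amps, tolerance = 1e-6)

  # zero signal (tiny jitter to satisfy finite-data validity) -> betas ~ 0
  s0 <- SessionSeries(matrix(rnorm(nVol * 2, sd = 1e-8), nVol),
                      trSeconds = tr, task = "pvt")
  bs0 <- fitBetaSeries(s0, trials)
  expect_lt(max(abs(bs0$betas)), 1e-6)

  # single trial without drift equals the OLS slope on one regressor
  one <- trials[1, , drop = FALSE]
  set.seed(4)
  y <- rnorm(nVol)
  sy <- SessionSeries(matrix(y, nVol, 1), trSeconds = tr, task = "pvt")
  b1 <- fitBetaSeries(sy, one, drift = FALSE)$betas[1, 1]
  reg <- canonicalHRF(tGrid - one$onset)
  expect_equal(b1, unname(coef(lm(y ~ reg))[2]), tolerance = 1e-8)

  expect_error(fitBetaSeries(sy, data.frame(onset = 1e5)), "run duration")
})

test_that("LSS and LSA agree for well-separated trials", {
  tr <- 0.594
  nVol <- 500
  trials <- genTrials(8, c(20, 30), seed = 5)
  s <- tinyStudy(seed = 6, nSessions = 1, nTime = nVol, nRois = 4)$sessions[[1]]
  lsa <- fitBetaSeries(s, trials, method = "lsa")
  lss <- fitBetaSeries(s, trials, method = "lss")
  expect_equal(cor(as.numeric(lsa$betas), as.numeric(lss$betas)), 1,
               tolerance = 0.01)
})

test_that("beta adjacency requires trials and flags constant series", {
  set.seed(7)
  B <- list(betas = matrix(rnorm(30), 10, 3), trials = NULL)
  A <- betaAdjacency(B)
  expect_equal(adjacencyDomain(A), "r")
  expect_error(betaAdjacency(list(betas = matrix(1, 2, 3))), "3 trials")
})

test_that("Fisher transform matches closed forms and round-trips", {
  W <- matrix(c(1, 0.5, 0, 0.5, 1, -0.3, 0, -0.3, 1), 3)
  A <- Adjacency(W)
  Z <- fisherZ(A)
  expect_equal(adjacencyWeights(Z)[1, 2], log(3) / 2, tolerance = 1e-12)
  expect_equal(adjacencyWeights(Z)[1, 3], 0)
  back <- fisherInverse(Z)
  expect_equal(adjacencyWeights(back), W, tolerance = 1e-12)

  # |r| = 1 is clipped, not infinite
  W1 <- matrix(c(1, 1, 1, 1), 2)
  z1 <- adjacencyWeights(fisherZ(Adjacency(W1)))
  expect_true(all(is.finite(z1)))
})

test_that("motion residualization removes FD but preserves link means", {
  st <- tinyStudy(seed = 8, nSessions = 12, nTime = 300)
  stackZ <- lapply(rawStack(st$sessions), fisherZ)
  set.seed(8)
  fd <- runif(12, 0.05, 0.15)

  out <- residualizeMotion(stackZ, fd)
  expect_equal(adjacencyDomain(out[[1]]), "r")

  Zin <- stackLinkMatrix(stackZ)
  Zout <- stackLinkMatrix(lapply(out, fisherZ))
  # after the round trip through tanh/atanh the means match closely
  expect_equal(colMeans(Zout), colMeans(Zin), tolerance = 1e-6)
  # residualized fisher-z weights are uncorrelated with FD
  cors <- apply(Zout, 2, function(v)
    if (sd(v) > 0) cor(v, fd) else 0)
  expect_lt(max(abs(cors)), 1e-6)

  # constant FD is the identity
  expect_message(same <- residualizeMotion(stackZ, rep(0.1, 12)),
                 "identity")
  expect_equal(stackLinkMatrix(lapply(same, fisherZ)), Zin,
               tolerance = 1e-10, ignore_attr = TRUE)

  # a link exactly linear in FD collapses to its mean
  Z2 <- stackZ
  for (k in seq_along(Z2)) {
    w <- adjacencyWeights(Z2[[k]])
    w[1, 2] <- w[2, 1] <- 0.1 + 2 * fd[k]
    Z2[[k]]@weights <- w
  }
  out2 <- residualizeMotion(Z2, fd)
  v <- vapply(out2, function(a) adjacencyWeights(a)[1, 2], numeric(1))
  expect_equal(v, rep(tanh(0.1 + 2 * mean(fd)), 12), tolerance = 1e-10)
})
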