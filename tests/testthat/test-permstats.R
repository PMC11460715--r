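test_that("standardization matches closed forms", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(as.numeric(z), c(-1, 0, 1))

  set.seed(1)
  x <- standardize(rnorm(50))
  expect_equal(as.numeric(standardize(x)), as.numeric(x),
               tolerance = 1e-12)

  expect_error(standardize(cbind(a = rep(2, 5), b = 1:5)), "a")
})

test_that("permutation regression attains the floor p and exact betas", {
  set.seed(2)
  x <- rnorm(30)
  fit <- permLM(x, cbind(x = x), nPerm = 500, seed = 3)
  expect_equal(fit$beta, 1, tolerance = 1e-12)
  expect_equal(fit$p, 1 / 501)

  # relabeling invariance: a joint row permutation of X and y leaves the
  # observed statistics exactly invariant and the sampled permutation p
  # within Monte-Carlo error
  X <- cbind(a = rnorm(30), b = rnorm(30))
  y <- rnorm(30)
  f1 <- permLM(y, X, nPerm = 500, seed = 9)
  ord <- sample(30)
  f2 <- permLM(y[ord], X[ord, ], nPerm = 500, seed = 9)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$t, f2$t, tolerance = 1e-10)
  expect_lt(max(abs(f1$p - f2$p)), 0.1)

  expect_warning(permLM(y, X, nPerm = 50, seed = 1), "unstable")
  expect_error(permLM(rnorm(3), cbind(rnorm(3), rnorm(3))), "observations")
})

test_that("permutation p-values agree with an exhaustive-style t reference", {
  # observed t must match lm()'s t statistic on standardized data
  set.seed(4)
  X <- cbind(a = rnorm(25), b = rnorm(25))
  y <- rnorm(25)
  fit <- permLM(y, X, nPerm = 100, seed = 5)
  ref <- summary(lm(standardize(y) ~ standardize(X)))$coefficients
  expect_equal(fit$t, unname(ref[2:3, "t value"]), tolerance = 1e-8)
})

test_that("Freedman-Lane scheme gives calibrated results near the simple scheme", {
  set.seed(6)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  y <- 0.8 * X[, 1] + rnorm(40)
  f1 <- permLM(y, X, nPerm = 400, seed = 7)
  f2 <- permLM(y, X, nPerm = 400, seed = 7, scheme = "freedman-lane")
  expect_lt(f1$p[1], 0.05)
  expect_lt(f2$p[1], 0.05)
  expect_gt(f2$p[2], 0.05)
})

test_that("BH adjustment matches hand and brute-force step-up computations", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(0.2), 0.2)
  expect_equal(bhFDR(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bhFDR(c(0, 0.5)), "0, 1")

  set.seed(8)
  for (rep in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(bhFDR(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("previous-day alignment pairs sessions with lagged factors", {
  beh <- data.frame(day = 1:20, f = (1:20) * 10)
  al <- alignPreviousDay(beh, c(14, 18), "f", lag = 1)
  expect_equal(al$f, c(130, 170))
  expect_error(alignPreviousDay(beh, c(1, 5), "f"), "day")
  expect_error(alignPreviousDay(beh, c(5), "missing_factor"), "factor")
})

test_that("link model controls the null and errors on duplicate predictors", {
  st <- tinyStudy(seed = 20, nSessions = 14, nTime = 300)
  stack <- rawStack(st$sessions)
  behImp <- st$behavior$truth
  res <- modelLinks(stack, behImp, c("total_sleep", "steps"), st$atlas,
                    c("DMN", "FPN"), nPerm = 300, seed = 21)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_equal(sum(res$q < 0.05), 0L)

  behDup <- behImp
  behDup$dup <- behDup$total_sleep
  expect_error(modelLinks(stack, behDup, c("total_sleep", "dup"),
                          st$atlas, "DMN", nPerm = 100, seed = 1))
})

test_that("betas are invariant to permuting session order", {
  st <- tinyStudy(seed = 22, nSessions = 12, nTime = 200)
  stack <- rawStack(st$sessions)
  behImp <- st$behavior$truth
  r1 <- modelLinks(stack, behImp, "total_sleep", st$atlas, "DMN",
                   nPerm = 100, seed = 23)
  ord <- c(5, 1, 12, 3, 8, 2, 10, 7, 4, 11, 6, 9)
  r2 <- modelLinks(stack[ord], behImp, "total_sleep", st$atlas, "DMN",
                   nPerm = 100, seed = 23)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
})

test_that("network-metric model recovers injected structure and controls nulls", {
  atlas <- genAtlas(20, 4, seed = 24)
  dmn <- which(atlas$network == "DMN")
  es <- effectSpec(t(combn(dmn, 2)), "total_sleep", lagDays = 1,
                   slope = 0.8, baseCorr = 0.3)
  sc <- tinyConfig(nSessions = 24, nTime = 500, nDays = 140)
  beh <- genBehavior(sc, seed = 25)
  gen <- genSessions(sc, atlas, beh$truth, list(es), seed = 26)
  mt <- metricSeries(rawStack(gen$sessions), atlas, densities = 0.1)
  res <- modelMetrics(mt, beh$truth, "total_sleep", nPerm = 500,
                      seed = 27)
  effDMN <- res[res$network == "DMN" & res$metric == "efficiency", ]
  expect_gt(effDMN$beta, 0)
  expect_lt(effDMN$q, 0.05)
})
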