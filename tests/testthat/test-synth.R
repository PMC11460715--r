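test_that("atlas generation covers every community exactly once per ROI", {
  atlas <- genAtlas(300, 13, seed = 1)
  expect_equal(nrow(atlas), 300)
  expect_equal(length(unique(atlas$network)), 13)
  expect_true(all(table(atlas$network) >= 1))

  small <- genAtlas(4, 2, seed = 1)
  expect_true(all(table(small$network) >= 1))

  singletons <- genAtlas(10, 10, seed = 7)
  expect_true(all(table(singletons$network) == 1))

  expect_false(anyDuplicated(atlas[, c("x", "y", "z")]) > 0)
  expect_error(genAtlas(3, 5), "at least")
})

test_that("behavioral factors have the configured autocorrelation and missingness", {
  white <- genBehavior(tinyConfig(nDays = 400, arCoefficient = 0),
                       factors = "f", seed = 3)
  x <- white$truth$f
  ac <- cor(x[-1], x[-length(x)])
  expect_lt(abs(ac), 3 / sqrt(400))

  ar <- genBehavior(synthConfig(nSessions = 4, nDays = 500,
                                sessionDays = c(20, 24, 27, 31),
                                arCoefficient = 0.8),
                    factors = "f", seed = 4)
  y <- ar$truth$f
  ac1 <- cor(y[-1], y[-length(y)])
  expect_gt(ac1, 0.7)
  expect_lt(ac1, 0.9)

  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_equal(sd(y), 1, tolerance = 1e-12)

  noMiss <- genBehavior(tinyConfig(missingFraction = 0), seed = 5)
  expect_false(anyNA(noMiss$observed))

  expect_error(synthConfig(arCoefficient = 1), "arCoefficient")
})

test_that("session generator realizes baseline and injected correlations", {
  # slope 0: realized generating correlation equals the base exactly
  es0 <- effectSpec(rbind(c(1, 5)), "total_sleep", lagDays = 0,
                    slope = 0, baseCorr = 0.25)
  st <- tinyStudy(list(es0), seed = 11, nTime = 400)
  expect_equal(unique(st$truth$rGenerating), 0.25, tolerance = 1e-10)

  # estimated link correlation tracks the base across sessions
  est <- vapply(st$sessions, function(s)
    cor(seriesData(s)[, 1], seriesData(s)[, 5]), numeric(1))
  expect_equal(mean(est), 0.25, tolerance = 0.1)

  # positive slope at lag 0 is recovered in the estimated weights
  es1 <- effectSpec(rbind(c(1, 5)), "total_sleep", lagDays = 0,
                    slope = 0.3, baseCorr = 0.2)
  st1 <- tinyStudy(list(es1), seed = 12, nSessions = 30, nTime = 800,
                   nDays = 130)
  est1 <- vapply(st1$sessions, function(s)
    cor(seriesData(s)[, 1], seriesData(s)[, 5]), numeric(1))
  fac <- st1$behavior$truth$total_sleep[st1$config$sessionDays]
  expect_gt(cor(fac, est1), 0)

  # consistency: long sessions converge to the generating correlation
  esBig <- effectSpec(rbind(c(1, 5)), "total_sleep", lagDays = 0,
                      slope = 0.3, baseCorr = 0.2)
  stBig <- tinyStudy(list(esBig), seed = 13, nSessions = 2, nTime = 10000)
  estBig <- vapply(stBig$sessions, function(s)
    cor(seriesData(s)[, 1], seriesData(s)[, 5]), numeric(1))
  expect_equal(estBig, stBig$truth$rGenerating, tolerance = 0.02)
})

test_that("injected lag is exactly recoverable from the generating truth", {
  es <- effectSpec(rbind(c(1, 5)), "total_sleep", lagDays = 2,
                   slope = 0.5, baseCorr = 0.1)
  st <- tinyStudy(list(es), seed = 21, nSessions = 20, nDays = 110,
                  nTime = 50, arCoefficient = 0)
  w <- st$truth$rGenerating
  fac <- st$behavior$truth$total_sleep
  days <- st$truth$day
  rhoAtLag <- vapply(0:6, function(L) abs(cor(w, fac[days - L])),
                     numeric(1))
  expect_equal(which.max(rhoAtLag) - 1L, 2L)
})

test_that("generated correlation targets are positive semidefinite", {
  es <- effectSpec(rbind(c(1, 2), c(1, 3), c(2, 3)), "total_sleep",
                   lagDays = 0, slope = 0.8, baseCorr = 0.5)
  st <- tinyStudy(list(es), seed = 31, nSessions = 4, nTime = 5000,
                  nRois = 10, nNetworks = 2)
  for (s in st$sessions) {
    ev <- eigen(cor(seriesData(s)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
  expect_true(all(abs(st$truth$rGenerating) < 1))
})

test_that("FD traces respect the censoring threshold contract", {
  sc <- tinyConfig(nSessions = 2, nTime = 1000)
  none <- genFD(sc, spikeProb = 0, seed = 1)
  expect_true(all(unlist(none) <= 0.2))
  expect_true(all(unlist(none) >= 0))

  all_ <- genFD(sc, spikeProb = 1, seed = 2)
  expect_true(all(flagVolumes(all_[[1]])))

  some <- genFD(sc, spikeProb = 0.1, seed = 3)
  flagged <- sum(flagVolumes(some[[1]]))
  expect_gte(flagged, 70)
  expect_lte(flagged, 130)
})

test_that("trial onsets are increasing with gaps in the ITI range", {
  one <- genTrials(1, c(2, 10), seed = 1)
  expect_equal(nrow(one), 1)
  expect_gte(one$onset, 2)

  t20 <- genTrials(20, c(2, 10), seed = 2)
  gaps <- diff(c(0, t20$onset))
  expect_true(all(gaps >= 2 & gaps <= 10))
  expect_true(all(diff(t20$onset) > 0))

  expect_equal(nrow(genTrials(0)), 0)
})

test_that("generation is byte-identical under a fixed seed", {
  a <- tinyStudy(seed = 5, nSessions = 3, nTime = 60)
  b <- tinyStudy(seed = 5, nSessions = 3, nTime = 60)
  expect_identical(lapply(a$sessions, seriesData),
                   lapply(b$sessions, seriesData))
  expect_identical(a$behavior, b$behavior)
})
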