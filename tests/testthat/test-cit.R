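test_that("degenerate tested variables yield statistic 0 and p-value 1", {
  sim <- genCategoricalDataset(n = 120, p = 4, K = 3, nRelevant = 1,
                               effectSize = 1, seed = 21)
  fm <- featureMatrix(sim$data)
  fm[, 2] <- 2.5            # zero variance
  fm[, 3] <- fm[, 4]        # duplicate of a conditioning variable
  d <- makeDataset(fm, outcomeCodes(sim$data))

  r1 <- mcCIT(d, 2L, cond = 4L)
  expect_equal(testStatistic(r1), 0)
  expect_equal(pValue(r1), 1)
  r2 <- mcCIT(d, 3L, cond = 4L)
  expect_equal(testStatistic(r2), 0, tolerance = 1e-8)
  expect_equal(pValue(r2), 1, tolerance = 1e-7)
  expect_error(mcCIT(d, 4L, cond = 4L), "conditioning")
})

test_that("the deviance agrees with a brute-force generic-optimizer LRT", {
  for (s in 1:5) {
    sim <- genCategoricalDataset(n = 200, p = 4, K = 3, nRelevant = 2,
                                 effectSize = 0.7, seed = 100 + s)
    fm <- featureMatrix(sim$data)
    yv <- outcomeCodes(sim$data)
    cond <- c(2L, 3L)
    res <- mcCIT(sim$data, 1L, cond)
    llF <- bruteMnlLogLik(fm[, c(cond, 1L)], yv, 3L)
    llA <- bruteMnlLogLik(fm[, cond], yv, 3L)
    expect_equal(testStatistic(res), 2 * (llF - llA), tolerance = 1e-4)
  }
})

test_that("K = 2 MC-CIT equals the binary logistic LRT", {
  for (s in 1:8) {
    sim <- genCategoricalDataset(n = 150, p = 4, K = 2, nRelevant = 2,
                                 effectSize = 0.6, seed = 200 + s)
    fm <- featureMatrix(sim$data)
    yv <- outcomeCodes(sim$data)
    full <- glm(yv ~ fm[, 2] + fm[, 1], family = binomial())
    alt <- glm(yv ~ fm[, 2], family = binomial())
    dev <- as.numeric(2 * (logLik(full) - logLik(alt)))
    pRef <- pchisq(dev, 1, lower.tail = FALSE)

    expect_equal(pValue(mcCIT(sim$data, 1L, 2L)), pRef, tolerance = 1e-6)
    dOrd <- makeDataset(fm, yv, "ordinal")
    expect_equal(pValue(mcCIT(dOrd, 1L, 2L)), pRef, tolerance = 1e-6)
  }
})

test_that("the statistic is invariant to permuting nominal class codes", {
  sim <- genCategoricalDataset(n = 180, p = 3, K = 3, nRelevant = 2,
                               effectSize = 0.8, seed = 31)
  fm <- featureMatrix(sim$data)
  yv <- outcomeCodes(sim$data)
  base <- testStatistic(mcCIT(sim$data, 1L, 2L))
  for (perm in list(c(1L, 0L, 2L), c(2L, 1L, 0L), c(1L, 2L, 0L))) {
    dPerm <- makeDataset(fm, perm[yv + 1L])
    expect_equal(testStatistic(mcCIT(dPerm, 1L, 2L)), base,
                 tolerance = 1e-6)
  }
})

test_that("df conventions drive the chi-squared reference", {
  sim <- genCategoricalDataset(n = 150, p = 3, K = 4, nRelevant = 1,
                               effectSize = 0.5, seed = 32)
  r1 <- mcCIT(sim$data, 1L, config = citConfig("mc_cit", "param_diff"))
  r2 <- mcCIT(sim$data, 1L, config = citConfig("mc_cit", "single_df"))
  expect_equal(r1@df, 3L)
  expect_equal(r2@df, 1L)
  expect_equal(testStatistic(r1), testStatistic(r2))
  expect_equal(pValue(r1), pchisq(testStatistic(r1), 3, lower.tail = FALSE))
  expect_equal(pValue(r2), pchisq(testStatistic(r2), 1, lower.tail = FALSE))
})

test_that("Fisher Z matches its closed form and the residual oracle", {
  # exact r = 0.5 at n = 103, unconditional
  dat <- withSeed(41, makeExactCorrData(51, 52, 0.5))
  d <- makeDataset(cbind(x = dat$x, z = rnorm(103)), dat$y)
  res <- fisherZCIT(d, 1L)
  z <- 0.5 * log(1.5 / 0.5)
  expect_equal(testStatistic(res), sqrt(100) * z, tolerance = 1e-10)
  expect_equal(pValue(res), 2 * pnorm(10 * z, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(pValue(res), 3.97e-8, tolerance = 0.02)

  # r = 0: orthogonal x
  dat0 <- withSeed(42, makeExactCorrData(40, 40, 0))
  d0 <- makeDataset(cbind(x = dat0$x, z = rnorm(80)), dat0$y)
  r0 <- fisherZCIT(d0, 1L)
  expect_equal(testStatistic(r0), 0, tolerance = 1e-10)
  expect_equal(pValue(r0), 1, tolerance = 1e-10)

  # conditional r equals the residual-regression partial correlation
  for (s in 1:4) {
    sim <- genNullTriplet(n = 80, K = 3, zDim = 2, seed = 400 + s)
    fm <- featureMatrix(sim$data)
    yv <- as.numeric(outcomeCodes(sim$data))
    for (cond in list(2L, c(2L, 3L))) {
      res <- fisherZCIT(sim$data, 1L, cond)
      r <- partialCorOracle(fm[, 1], yv, fm[, cond])
      zr <- 0.5 * log((1 + r) / (1 - r))
      expect_equal(testStatistic(res),
                   sqrt(80 - length(cond) - 3) * abs(zr),
                   tolerance = 1e-10)
    }
  }

  # insufficient samples
  tiny <- makeDataset(matrix(rnorm(8), 4, 2), c(0L, 1L, 0L, 1L))
  expect_false(fisherZCIT(tiny, 1L, 2L)@assessable)
})

test_that("three-bin discretization follows the mean +/- sd rule", {
  expect_equal(discretizeThreeBins(rep(7, 10)), rep(1L, 10))
  expect_equal(discretizeThreeBins(c(0, 0, 0, 0, 10)),
               c(1L, 1L, 1L, 1L, 2L))
  v <- withSeed(43, rnorm(20000))
  props <- tabulate(discretizeThreeBins(v) + 1L, 3) / 20000
  expect_equal(props, c(pnorm(-1), pnorm(1) - pnorm(-1), pnorm(-1)),
               tolerance = 0.02)
})

test_that("G-squared matches direct contingency-table evaluation", {
  # diagonal 2x2 table: G2 = 40 log 2
  x <- c(rep(0L, 10), rep(1L, 10))
  d <- makeDataset(cbind(a = as.numeric(x), b = rnorm(20)), x)
  res <- g2CIT(d, 1L, discretize = FALSE)
  expect_equal(testStatistic(res), 40 * log(2), tolerance = 1e-10)
  expect_equal(res@df, 1L)
  expect_equal(pValue(res), pchisq(40 * log(2), 1, lower.tail = FALSE))
  expect_equal(pValue(res), 1.4e-7, tolerance = 0.05)

  # proportional table: statistic 0
  xp <- rep(c(0, 1), each = 10)
  yp <- rep(c(0L, 1L, 0L, 1L), each = 5)
  dp <- makeDataset(cbind(a = xp, b = rnorm(20)), yp)
  rp <- g2CIT(dp, 1L, discretize = FALSE)
  expect_equal(testStatistic(rp), 0, tolerance = 1e-12)
  expect_equal(pValue(rp), 1)

  # power heuristic: n = 20 < 5 * df with df = 12
  xh <- rep(0:2, length.out = 20)
  zh <- rep(0:2, each = 7)[1:20]
  yh <- rep(0:2, length.out = 20)
  dh <- makeDataset(cbind(a = as.numeric(xh), z = as.numeric(zh)), yh)
  rh <- g2CIT(dh, 1L, cond = 2L, discretize = FALSE)
  expect_false(rh@assessable)
  expect_equal(pValue(rh), 1)

  # single-level x after discretization
  dz <- makeDataset(cbind(a = rep(1, 40), b = rnorm(40)),
                    rep(0:1, each = 20))
  expect_false(g2CIT(dz, 1L)@assessable)
})

test_that("Fisher Z and G-squared are calibrated under the conditional null", {
  nRep <- 600
  rejF <- rejG <- 0
  pF <- numeric(nRep)
  for (i in seq_len(nRep)) {
    sim <- genNullTriplet(n = 150, K = 3, zDim = 1, seed = 5000 + i)
    pf <- pValue(fisherZCIT(sim$data, 1L, sim$zIndices))
    pg <- pValue(g2CIT(sim$data, 1L, sim$zIndices))
    pF[i] <- pf
    rejF <- rejF + (pf <= 0.05)
    rejG <- rejG + (pg <= 0.05)
  }
  band <- qbinom(c(0.005, 0.995), nRep, 0.05) / nRep
  expect_gte(rejF / nRep, band[1])
  expect_lte(rejF / nRep, band[2])
  expect_gte(rejG / nRep, band[1])
  expect_lte(rejG / nRep, band[2])
  expect_gt(ks.test(pF, "punif")$p.value, 0.01)
})

test_that("MC-CIT power grows with sample size and effect size", {
  power <- function(n, eff) {
    mean(sapply(1:60, function(s) {
      sim <- genCategoricalDataset(n = n, p = 2, K = 3, nRelevant = 1,
                                   effectSize = eff, seed = 7000 + s)
      pValue(mcCIT(sim$data, sim$truth@relevantFeatures[1])) <= 0.05
    }))
  }
  pw <- c(power(50, 0.4), power(150, 0.4), power(500, 0.4))
  expect_true(all(diff(pw) >= -0.05))
  expect_gt(pw[3], pw[1])
  expect_gt(power(150, 1.2), power(150, 0.4) - 0.05)
})

test_that("citTest dispatches on the configured test kind", {
  sim <- genCategoricalDataset(n = 100, p = 3, K = 3, nRelevant = 1,
                               effectSize = 1, seed = 55)
  expect_equal(citTest(sim$data, 1L, config = citConfig("mc_cit"))@testName,
               "mc_cit")
  expect_equal(citTest(sim$data, 1L,
                       config = citConfig("fisher_z"))@testName, "fisher_z")
  expect_equal(citTest(sim$data, 1L, config = citConfig("g2"))@testName,
               "g2")
})
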