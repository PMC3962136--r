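test_that("intercept-only fits equal the closed-form saturated MLE", {
  y <- rep(c(0L, 1L, 2L), times = c(5, 3, 2))
  X <- matrix(rnorm(10 * 3), 10, 3)
  d <- makeDataset(X, y)
  llExp <- 5 * log(0.5) + 3 * log(0.3) + 2 * log(0.2)

  ml <- fitMultinomialLogit(d, integer(0))
  expect_equal(logLikelihood(ml), llExp, tolerance = 1e-12)
  expect_equal(nParams(ml), 2L)
  P <- predictProba(ml, matrix(numeric(0), nrow = 2, ncol = 0))
  expect_equal(unname(P[1, ]), c(0.5, 0.3, 0.2), tolerance = 1e-10)

  dOrd <- makeDataset(X, y, "ordinal")
  ol <- fitOrderedLogit(dOrd, integer(0))
  expect_equal(logLikelihood(ol), llExp, tolerance = 1e-12)
  expect_equal(plogis(ol@thresholds), c(0.5, 0.8), tolerance = 1e-10)
  Po <- predictProba(ol, matrix(numeric(0), nrow = 1, ncol = 0))
  expect_equal(unname(Po[1, ]), c(0.5, 0.3, 0.2), tolerance = 1e-10)
})

test_that("K = 2 fits collapse to binary logistic regression", {
  for (s in 1:5) {
    sim <- genCategoricalDataset(n = 120, p = 3, K = 2, nRelevant = 2,
                                 effectSize = 0.8, seed = s)
    fm <- featureMatrix(sim$data)
    yv <- outcomeCodes(sim$data)
    ref <- glm(yv ~ fm[, 1] + fm[, 2], family = binomial())

    ml <- fitMultinomialLogit(sim$data, 1:2)
    # baseline is class K-1 = 1, so signs are flipped w.r.t. glm on P(y=1)
    expect_equal(unname(coef(ml)[1, ]), unname(-coef(ref)),
                 tolerance = 1e-5)
    expect_equal(logLikelihood(ml), as.numeric(logLik(ref)),
                 tolerance = 1e-6)

    dOrd <- makeDataset(fm, yv, "ordinal")
    ol <- fitOrderedLogit(dOrd, 1:2)
    expect_equal(logLikelihood(ol), as.numeric(logLik(ref)),
                 tolerance = 1e-6)
    # latent parametrisation: intercept of glm equals -mu1
    expect_equal(ol@thresholds[1], -unname(coef(ref)[1]),
                 tolerance = 1e-3)
  }
})

test_that("fits agree with independent reference implementations", {
  skip_if_not_installed("nnet")
  skip_if_not_installed("MASS")
  sim <- genCategoricalDataset(n = 250, p = 4, K = 3, nRelevant = 3,
                               effectSize = 1, seed = 9)
  fm <- featureMatrix(sim$data)
  yv <- outcomeCodes(sim$data)
  ml <- fitMultinomialLogit(sim$data, 1:4)
  nn <- nnet::multinom(factor(yv) ~ fm[, 1] + fm[, 2] + fm[, 3] + fm[, 4],
                       trace = FALSE, reltol = 1e-14)
  expect_equal(logLikelihood(ml), -nn$value, tolerance = 1e-5)

  simo <- genOrdinalDataset(n = 250, p = 4, K = 4, nRelevant = 2,
                            effectSize = 1, seed = 10)
  fmo <- featureMatrix(simo$data)
  yo <- outcomeCodes(simo$data)
  ol <- fitOrderedLogit(simo$data, 1:3)
  po <- MASS::polr(factor(yo, ordered = TRUE) ~ fmo[, 1] + fmo[, 2] +
                     fmo[, 3], method = "logistic")
  expect_equal(logLikelihood(ol), as.numeric(logLik(po)), tolerance = 1e-4)
  expect_equal(unname(ol@slope), unname(coef(po)), tolerance = 1e-3)
  expect_equal(unname(ol@thresholds), unname(po$zeta), tolerance = 1e-3)
})

test_that("generated coefficients are recovered and error shrinks with n", {
  errs <- sapply(c(500, 5000), function(n) {
    sim <- genCategoricalDataset(n = n, p = 3, K = 3, nRelevant = 2,
                                 effectSize = 1, seed = 11)
    fit <- fitMultinomialLogit(sim$data, sim$truth@relevantFeatures)
    max(abs(coef(fit)[, -1] - sim$truth@params$coefficients))
  })
  expect_lt(errs[2], 0.1)
  expect_lt(errs[2], errs[1] + 0.02)

  errsO <- sapply(c(500, 5000), function(n) {
    sim <- genOrdinalDataset(n = n, p = 3, K = 4, nRelevant = 2,
                             effectSize = 1, seed = 12)
    fit <- fitOrderedLogit(sim$data, sim$truth@relevantFeatures)
    max(abs(c(fit@slope - sim$truth@params$beta,
              fit@thresholds - sim$truth@params$thresholds)))
  })
  expect_lt(errsO[2], 0.1)
  expect_lt(errsO[2], errsO[1] + 0.02)
})

test_that("nested models never lose log-likelihood and rescaling is inert", {
  sim <- genCategoricalDataset(n = 150, p = 5, K = 3, nRelevant = 2,
                               effectSize = 0.8, seed = 13)
  d <- sim$data
  for (S in list(integer(0), 1L, c(1L, 2L), c(1L, 2L, 3L))) {
    xNew <- max(S, 0L) + 1L
    llS <- logLikelihood(fitMultinomialLogit(d, S))
    llSx <- logLikelihood(fitMultinomialLogit(d, c(S, xNew)))
    expect_gte(llSx, llS - 1e-8)
  }

  fm <- featureMatrix(d)
  fm2 <- fm
  fm2[, 2] <- fm2[, 2] * 37 - 5
  d2 <- makeDataset(fm2, outcomeCodes(d))
  expect_equal(logLikelihood(fitMultinomialLogit(d, 1:3)),
               logLikelihood(fitMultinomialLogit(d2, 1:3)),
               tolerance = 1e-6)

  dOrd <- makeDataset(fm, outcomeCodes(d), "ordinal")
  dOrd2 <- makeDataset(fm2, outcomeCodes(d), "ordinal")
  expect_equal(logLikelihood(fitOrderedLogit(dOrd, 1:3)),
               logLikelihood(fitOrderedLogit(dOrd2, 1:3)),
               tolerance = 1e-6)
})

test_that("zero-variance and duplicated regressors are dropped", {
  sim <- genCategoricalDataset(n = 100, p = 4, K = 3, nRelevant = 1,
                               effectSize = 1, seed = 14)
  fm <- featureMatrix(sim$data)
  fm[, 2] <- 1.5            # constant
  fm[, 3] <- fm[, 1]        # duplicate
  d <- makeDataset(fm, outcomeCodes(sim$data))
  fit <- fitMultinomialLogit(d, 1:4)
  expect_setequal(fit@dropped, c(2L, 3L))
  expect_equal(nParams(fit), 2L * 3L)  # intercept + two kept columns
  ref <- fitMultinomialLogit(d, c(1L, 4L))
  expect_equal(logLikelihood(fit), logLikelihood(ref), tolerance = 1e-8)
})

test_that("predicted probabilities obey the model equations", {
  # all-zero coefficients: uniform over K classes
  sim <- genCategoricalDataset(n = 60, p = 2, K = 3, nRelevant = 0,
                               effectSize = 0, seed = 15)
  fit <- fitMultinomialLogit(sim$data, 1:2)
  B0 <- fit@coefficients
  B0[] <- 0
  fit@coefficients <- B0
  P <- predictProba(fit, matrix(rnorm(10), 5, 2))
  expect_equal(unname(P), matrix(1 / 3, 5, 3), tolerance = 1e-12)

  # ordered logit with beta = 0: rows equal the threshold-implied marginals
  simo <- genOrdinalDataset(n = 80, p = 2, K = 3, nRelevant = 1,
                            effectSize = 0.5, seed = 16)
  ol <- fitOrderedLogit(simo$data, 1L)
  ol@slope[] <- 0
  Po <- predictProba(ol, matrix(rnorm(8), 8, 1))
  marg <- diff(c(0, plogis(ol@thresholds), 1))
  for (i in 1:8) expect_equal(unname(Po[i, ]), marg, tolerance = 1e-12)

  # seeded model rows agree with a direct scalar evaluation of the formulas
  fit2 <- fitMultinomialLogit(sim$data, 1:2)
  xrow <- c(0.3, -1.2)
  P2 <- predictProba(fit2, matrix(xrow, 1))
  B <- fit2@coefficients
  num <- exp(B %*% c(1, xrow))
  expect_equal(unname(P2[1, ]), c(num, 1) / (1 + sum(num)),
               tolerance = 1e-12)
  expect_equal(rowSums(P2), 1, ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(predictProba(fit2, matrix(0, 1, 5)), "columns")
})
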