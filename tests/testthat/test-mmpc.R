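# A plug-in test that counts its own invocations, for cache/enumeration
# checks: p-values are deterministic functions of (x, cond).
countingTest <- function(counter, pFun) {
  function(data, x, cond = integer(0)) {
    counter$n <- counter$n + 1L
    CITResult(pValue = pFun(x, cond), statistic = 1 - pFun(x, cond),
              df = 1L, assessable = TRUE, testName = "counting")
  }
}

test_that("minAssoc maximises the p-value over conditioning subsets", {
  sim <- genCategoricalDataset(n = 150, p = 5, K = 3, nRelevant = 2,
                               effectSize = 0.8, seed = 61)
  d <- sim$data
  # empty candidate set: the unconditional p-value
  ma <- minAssoc(d, 1L, integer(0), mmpcConfig(test = "mc_cit"))
  expect_equal(ma$pMax, pValue(mcCIT(d, 1L)))
  expect_length(ma$witness, 0)

  # one candidate: max of the two subsets, by enumeration
  ma2 <- minAssoc(d, 1L, 2L, mmpcConfig(test = "mc_cit", kMax = 1L))
  expect_equal(ma2$pMax, max(pValue(mcCIT(d, 1L)),
                             pValue(mcCIT(d, 1L, 2L))))

  # |cpc| = 4, kMax = 3: exactly C(4,0)+C(4,1)+C(4,2)+C(4,3) = 15 subsets
  counter <- new.env(); counter$n <- 0L
  cfg <- mmpcConfig(kMax = 3L,
                    test = countingTest(counter, function(x, cond) 0.001))
  minAssoc(d, 5L, 1:4, cfg)
  expect_equal(counter$n, 15L)
})

test_that("kMax = 0 reduces MMPC to univariate filtering", {
  sim <- genCategoricalDataset(n = 150, p = 12, K = 3, nRelevant = 3,
                               effectSize = 1, seed = 62)
  d <- sim$data
  res <- mmpc(d, mmpcConfig(alpha = 0.05, kMax = 0L, test = "mc_cit"))
  pvals <- sapply(1:12, function(j) pValue(mcCIT(d, j)))
  expected <- which(pvals <= 0.05)
  expect_setequal(selectedFeatures(res), expected)
  # added in increasing-p order
  expect_equal(selectedFeatures(res), expected[order(pvals[expected])])
})

test_that("MMPC is deterministic and cache results are reused", {
  sim <- genCategoricalDataset(n = 120, p = 20, K = 3, nRelevant = 3,
                               effectSize = 1, seed = 63)
  r1 <- mmpc(sim$data, mmpcConfig(0.05, 3, "mc_cit"))
  r2 <- mmpc(sim$data, mmpcConfig(0.05, 3, "mc_cit"))
  expect_identical(selectedFeatures(r1), selectedFeatures(r2))
  expect_identical(mmpcTrace(r1), mmpcTrace(r2))
  expect_identical(testsPerformed(r1), testsPerformed(r2))

  # distinct (x, Z) pairs are evaluated at most once
  counter <- new.env(); counter$n <- 0L
  seen <- new.env(parent = emptyenv())
  probe <- function(data, x, cond = integer(0)) {
    key <- paste0(x, "|", paste(sort(cond), collapse = ","))
    expect_null(seen[[key]])
    seen[[key]] <- TRUE
    counter$n <- counter$n + 1L
    CITResult(pValue = if (x <= 3) 0.001 else 0.9, statistic = 1,
              df = 1L, testName = "probe")
  }
  res <- mmpc(sim$data, mmpcConfig(0.05, 2, probe))
  expect_equal(testsPerformed(res), counter$n)
})

test_that("the hand-built five-node fixture is recovered through the oracle", {
  # Y <- X1, Y <- X2, X3 <- Y, X4 -> X3: PC(Y) = {X1, X2, X3}; X5 isolated
  adj <- matrix(0L, 6, 6,
                dimnames = list(NULL, c("Y", paste0("X", 1:5))))
  adj[2, 1] <- 1L  # X1 -> Y
  adj[3, 1] <- 1L  # X2 -> Y
  adj[1, 4] <- 1L  # Y -> X3
  adj[5, 4] <- 1L  # X4 -> X3
  oracle <- function(data, x, cond = integer(0)) {
    sep <- bruteDsep(adj, x + 1L, 1L, as.integer(cond) + 1L)
    CITResult(pValue = as.numeric(sep), statistic = as.numeric(!sep),
              df = 1L, testName = "oracle")
  }
  X <- withSeed(64, matrix(rnorm(40 * 5), 40, 5,
                           dimnames = list(NULL, paste0("X", 1:5))))
  d <- makeDataset(X, rep(0:2, length.out = 40))

  fw <- mmpcForward(d, mmpcConfig(0.05, 3, oracle))
  expect_true(all(c(1L, 2L, 3L) %in% fw$cpc))
  expect_false(5L %in% fw$cpc)
  sel <- mmpcBackward(d, fw$cpc, mmpcConfig(0.05, 3, oracle))
  expect_setequal(sel, c(1L, 2L, 3L))  # the spouse X4 is pruned

  # the collider opens when X3 is conditioned on
  expect_equal(pValue(oracle(d, 4L, integer(0))), 1)  # X4 dsep Y | {}
  expect_equal(pValue(oracle(d, 4L, 3L)), 0)          # open given X3
})

test_that("oracle MMPC recovers the PC set on random sparse fixtures", {
  for (s in 1:6) {
    fx <- genBNFixture(6 + 2 * s, seed = 600 + s)
    res <- mmpc(fx$data, mmpcConfig(0.05, 3, fx$oracle))
    expect_identical(sort(selectedFeatures(res)), as.integer(fx$pcSet))
  }
})

test_that("non-assessable tests are skipped, not treated as independence", {
  sim <- genCategoricalDataset(n = 100, p = 6, K = 3, nRelevant = 2,
                               effectSize = 1, seed = 65)
  # marginal tests significant for features 1-2; every conditional test
  # refuses assessment -> both features must still be selected
  skipTest <- function(data, x, cond = integer(0)) {
    if (length(cond))
      CITResult(1, NA, 1L, assessable = FALSE, testName = "skip")
    else
      CITResult(if (x <= 2) 1e-6 else 0.8, 1, 1L, testName = "skip")
  }
  res <- mmpc(sim$data, mmpcConfig(0.05, 3, skipTest))
  expect_setequal(selectedFeatures(res), c(1L, 2L))

  # a candidate with no assessable test at all is never selected
  neverTest <- function(data, x, cond = integer(0))
    CITResult(1, NA, 1L, assessable = FALSE, testName = "never")
  res2 <- mmpc(sim$data, mmpcConfig(0.05, 3, neverTest))
  expect_length(selectedFeatures(res2), 0)
})

test_that("planted signals are recovered in moderate dimensions", {
  hits <- 0
  for (s in 1:3) {
    sim <- genCategoricalDataset(n = 300, p = 1000, K = 3, nRelevant = 5,
                                 effectSize = 1, seed = 660 + s)
    res <- mmpc(sim$data, mmpcConfig(0.05, 3, "mc_cit"))
    hits <- hits +
      (sum(sim$truth@relevantFeatures %in% selectedFeatures(res)) >= 4)
  }
  expect_gte(hits, 2)
})

test_that("maxCpc caps the selected set size", {
  sim <- genCategoricalDataset(n = 200, p = 20, K = 3, nRelevant = 6,
                               effectSize = 1.2, seed = 67)
  res <- mmpc(sim$data, mmpcConfig(0.05, 3, "mc_cit", maxCpc = 2))
  expect_lte(length(selectedFeatures(res)), 2)
})

test_that("trace records admissions, rejections and removals coherently", {
  sim <- genCategoricalDataset(n = 150, p = 10, K = 3, nRelevant = 2,
                               effectSize = 1, seed = 68)
  res <- mmpc(sim$data, mmpcConfig(0.05, 3, "mc_cit"))
  tr <- mmpcTrace(res)
  expect_true(all(tr$action %in% c("added", "rejected", "removed")))
  for (f in selectedFeatures(res)) {
    acts <- tr$action[tr$feature == f]
    expect_true("added" %in% acts)
    expect_false("removed" %in% acts)
  }
  js <- jsonlite::fromJSON(mmpcResultJSON(res))
  expect_equal(js$selected, selectedFeatures(res))
})
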