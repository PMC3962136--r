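#' Classification accuracy
#'
#' Fraction of exact matches between predictions and truth.
#'
#' @param predictions,truth equal-length vectors.
#' @return numeric in `[0, 1]`.
#' @export
accuracy <- function(predictions, truth) {
  if (!length(predictions)) stop("empty input")
  if (length(predictions) != length(truth)) stop("length mismatch")
  mean(predictions == truth)
}

#' Trivial (majority-class) classifier
#'
#' Returns a constant predictor of the class that appears most frequently in
#' the training labels; ties are broken toward the lowest class code. This
#' is the baseline any selected signature must beat.
#'
#' @param trainLabels integer class codes of the training samples.
#' @return function(m) returning m copies of the modal class code.
#' @export
trivialClassifier <- function(trainLabels) {
  if (!length(trainLabels)) stop("empty training labels")
  tab <- table(trainLabels)
  modal <- as.integer(names(tab)[which.max(tab)])  # which.max: first max
  function(m) rep(modal, m)
}

#' Exact binomial comparison of two pooled prediction vectors
#'
#' The paired exact test on pooled predictions: among samples where exactly
#' one method is correct, the split between "only A correct" and "only B
#' correct" is referred to a Binomial(b + c, 1/2). The default two-sided
#' convention is minimum-likelihood (the sum of all outcome probabilities no
#' larger than the observed one, as in [stats::binom.test()]);
#' `method = "double"` doubles the smaller tail instead. With no discordant
#' samples the p-value is 1.
#'
#' @param predsA,predsB predictions of the two methods.
#' @param truth true classes.
#' @param method two-sided convention, `"minlike"` (default) or `"double"`.
#' @return p-value.
#' @examples
#' # 8 vs 2 discordant predictions
#' truth <- rep(0, 12)
#' a <- c(rep(0, 10), 1, 1)
#' b <- c(rep(1, 8), 0, 0, 1, 1)
#' exactBinomialCompare(a, b, truth)  # 112/1024
#' @export
exactBinomialCompare <- function(predsA, predsB, truth,
                                 method = c("minlike", "double")) {
  method <- match.arg(method)
  if (length(predsA) != length(truth) || length(predsB) != length(truth))
    stop("length mismatch")
  okA <- predsA == truth
  okB <- predsB == truth
  b <- sum(okA & !okB)
  cc <- sum(!okA & okB)
  m <- b + cc
  if (m == 0L) return(1)
  if (method == "minlike")
    return(binom.test(b, m, p = 0.5)$p.value)
  min(1, 2 * min(pbinom(b, m, 0.5), pbinom(m - b, m, 0.5)))
}

#' Two-tailed t comparison of selected-feature counts
#'
#' Standard two-sample two-tailed t-test (Welch) on per-outer-fold
#' selected-feature counts of two methods. Degenerate inputs with zero
#' variance on both sides return 1 when the means agree and 0 otherwise.
#'
#' @param countsA,countsB numeric vectors of per-fold counts (length >= 2).
#' @return p-value.
#' @export
compareFeatureCounts <- function(countsA, countsB) {
  if (length(countsA) < 2L || length(countsB) < 2L)
    stop("need at least 2 folds per method")
  if (var(countsA) + var(countsB) < 1e-24)
    return(as.numeric(mean(countsA) == mean(countsB)))
  t.test(countsA, countsB)$p.value
}

#' Stratified nested cross-validation fold plan
#'
#' Splits samples into `nOuter` disjoint, exhaustive outer test folds and,
#' within each outer training set, `nInner` inner folds, stratifying by
#' class so every training fold keeps all classes. Reproducible from `seed`.
#'
#' @param outcome integer class codes (or a
#'   \linkS4class{MulticlassExperiment}).
#' @param nOuter,nInner fold counts.
#' @param stratified stratify by class (default).
#' @param seed integer seed.
#' @return list of class `"FoldPlan"` with `outer` (test index sets),
#'   `inner` (per outer fold, inner test index sets within the outer
#'   training set), and the parameters.
#' @export
foldPlan <- function(outcome, nOuter = 10L, nInner = 5L, stratified = TRUE,
                     seed = 1L) {
  if (is(outcome, "MulticlassExperiment")) outcome <- outcomeCodes(outcome)
  n <- length(outcome)
  assignFolds <- function(idx, labels, k) {
    fold <- integer(length(idx))
    if (stratified) {
      for (cl in unique(labels)) {
        ic <- which(labels == cl)
        ic <- ic[sample.int(length(ic))]
        fold[ic] <- rep_len(sample.int(k), length(ic))
      }
    } else {
      fold <- rep_len(sample.int(k), length(idx))[sample.int(length(idx))]
    }
    lapply(seq_len(k), function(f) idx[fold == f])
  }
  plan <- .withSeed(seed, {
    outer <- assignFolds(seq_len(n), outcome, nOuter)
    inner <- lapply(outer, function(test) {
      tr <- setdiff(seq_len(n), test)
      if (any(tabulate(outcome[tr] + 1L) == 0L))
        stop("an outer training fold lost a class; reduce nOuter")
      assignFolds(tr, outcome[tr], nInner)
    })
    list(outer = outer, inner = inner)
  })
  structure(list(outer = plan$outer, inner = plan$inner, nOuter = nOuter,
                 nInner = nInner, stratified = stratified, seed = seed),
            class = "FoldPlan")
}

#' The comparative evaluation grid
#'
#' Builds the grid of feature-selection configurations and classifier
#' configurations used by [nestedCV()]. Defaults follow the comparative
#' protocol: MMPC with alpha in {0.01, 0.05} x k-max in {3, 4} for each
#' requested test, Lasso selection with penalty lambda in
#' {0.05, 0.1, 0.15, 0.20}; classifiers are one-vs-all SVMs (linear,
#' polynomial degree 2 and 3, Gaussian kernels; cost 1 and 10), Lasso
#' regression over the same lambda grid, and the multinomial-logit /
#' ordered-logit model (routed by the outcome kind, no tuning parameters).
#'
#' @param fsTests character subset of `c("mc_cit", "fisher_z", "g2")` to
#'   couple with MMPC.
#' @param alphas,kMaxes MMPC parameter grids.
#' @param lassoLambdas penalty grid for Lasso selection / regression.
#' @param includeLassoSelection include the Lasso selection method.
#' @param classifiers character subset of `c("svm", "lasso", "glm")`.
#' @param svmKernels,svmCosts SVM grids.
#' @param dfConvention MC-CIT degrees-of-freedom convention.
#' @return a list of class `"MethodGrid"` with one element per
#'   feature-selection method family; each element carries `fsConfigs` and
#'   `clfConfigs`.
#' @export
methodGrid <- function(fsTests = c("mc_cit", "fisher_z", "g2"),
                       alphas = c(0.01, 0.05), kMaxes = c(3L, 4L),
                       lassoLambdas = c(0.05, 0.1, 0.15, 0.20),
                       includeLassoSelection = TRUE,
                       classifiers = c("svm", "lasso", "glm"),
                       svmKernels = c("linear", "poly2", "poly3",
                                      "gaussian"),
                       svmCosts = c(1, 10),
                       dfConvention = "param_diff") {
  clf <- list()
  if ("svm" %in% classifiers)
    for (k in svmKernels) for (C in svmCosts)
      clf[[length(clf) + 1L]] <- list(type = "svm", kernel = k, cost = C)
  if ("lasso" %in% classifiers)
    for (l in lassoLambdas)
      clf[[length(clf) + 1L]] <- list(type = "lasso", lambda = l)
  if ("glm" %in% classifiers)
    clf[[length(clf) + 1L]] <- list(type = "glm")
  if (!length(clf)) stop("empty classifier grid")

  grid <- list()
  for (tst in fsTests) {
    fs <- list()
    for (a in alphas) for (km in kMaxes)
      fs[[length(fs) + 1L]] <- list(type = "mmpc", test = tst, alpha = a,
                                    kMax = km,
                                    dfConvention = dfConvention)
    grid[[paste0("mmpc_", tst)]] <- list(fsConfigs = fs, clfConfigs = clf)
  }
  if (includeLassoSelection) {
    fs <- lapply(lassoLambdas, function(l) list(type = "lasso", lambda = l))
    grid[["lasso"]] <- list(fsConfigs = fs, clfConfigs = clf)
  }
  structure(grid, class = "MethodGrid")
}

# ---- classifier plug-in registry ------------------------------------------

.svmKernelArgs <- function(kernel) {
  switch(kernel,
         linear = list(kernel = "linear"),
         poly2 = list(kernel = "polynomial", degree = 2L, coef0 = 1),
         poly3 = list(kernel = "polynomial", degree = 3L, coef0 = 1),
         gaussian = list(kernel = "radial"),
         stop("unknown kernel: ", kernel))
}

# One-vs-all SVM: one binary machine per class, predicted class = argmax of
# the per-class decision values.
.fitSvmOva <- function(x, y, params, K, kind) {
  machines <- vector("list", K)
  for (k in seq_len(K) - 1L) {
    lab <- factor(y == k, levels = c(FALSE, TRUE))
    if (length(unique(lab[!is.na(lab)])) < 2L || sum(y == k) < 1L) {
      machines[[k + 1L]] <- NULL
      next
    }
    args <- c(list(x = x, y = lab, cost = params$cost, scale = FALSE,
                   probability = FALSE),
              .svmKernelArgs(params$kernel))
    machines[[k + 1L]] <- do.call(e1071::svm, args)
  }
  list(machines = machines, K = K)
}

.predictSvmOva <- function(model, x) {
  scores <- matrix(-Inf, nrow(x), model$K)
  for (k in seq_len(model$K)) {
    m <- model$machines[[k]]
    if (is.null(m)) next
    pr <- predict(m, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient the decision value toward the "TRUE" (one) side
    flip <- if (grepl("^FALSE", colnames(dv)[1L])) -1 else 1
    scores[, k] <- flip * dv[, 1L]
  }
  max.col(scores, ties.method = "first") - 1L
}

# glmnet wants >= 2 columns; pad with an all-zero ghost column when needed.
.padTwoCols <- function(x) {
  if (ncol(x) >= 2L) return(x)
  cbind(x, ghost = rep(0, nrow(x)))
}

.fitLassoClf <- function(x, y, params, K, kind) {
  xp <- .padTwoCols(x)
  fit <- suppressWarnings(glmnet::glmnet(xp, factor(y, levels = seq_len(K) - 1L),
                        family = "multinomial", standardize = TRUE))
  list(fit = fit, lambda = params$lambda, K = K, padded = ncol(x) < 2L)
}

.predictLassoClf <- function(model, x) {
  xp <- .padTwoCols(x)
  pr <- predict(model$fit, xp, s = model$lambda, type = "class")
  as.integer(pr[, 1L])
}

.fitGlmClf <- function(x, y, params, K, kind) {
  fitFun <- if (kind == "ordinal") .fitOlCore else .fitMnlCore
  suppressWarnings(fitFun(x, y, K, seq_len(ncol(x))))
}

.predictGlmClf <- function(model, x) predictClass(model, x)

#' Default classifier registry
#'
#' The plug-in contract used by [nestedCV()]: each entry has a `fit`
#' function `(x, y, params, K, kind)` and a `predict` function
#' `(model, x)` returning integer class codes. Standard classifiers are
#' delegated to e1071 (SVM) and glmnet (Lasso); the glm entry uses the
#' package's own multinomial / ordered logit fits.
#'
#' @return named list of classifier entries.
#' @export
classifierRegistry <- function() {
  list(svm = list(fit = .fitSvmOva, predict = .predictSvmOva,
                  complexity = 3),
       lasso = list(fit = .fitLassoClf, predict = .predictLassoClf,
                    complexity = 2),
       glm = list(fit = .fitGlmClf, predict = .predictGlmClf,
                  complexity = 1))
}

# ---- feature selection ----------------------------------------------------

.selectFeatures <- function(fsConfig, fm, y, K, kind, labs) {
  if (fsConfig$type == "mmpc") {
    data <- .newDataset(fm, y, kind, labs)
    cfg <- mmpcConfig(alpha = fsConfig$alpha, kMax = fsConfig$kMax,
                      test = fsConfig$test,
                      cit = citConfig(fsConfig$test,
                                      dfConvention = fsConfig$dfConvention
                                        %||% "param_diff"))
    selectedFeatures(mmpc(data, cfg))
  } else if (fsConfig$type == "lasso") {
    xp <- .padTwoCols(fm)
    fit <- suppressWarnings(glmnet::glmnet(xp, factor(y, levels = seq_len(K) - 1L),
                          family = "multinomial", standardize = TRUE))
    cf <- coef(fit, s = fsConfig$lambda)
    nz <- sort(unique(unlist(lapply(cf, function(m) {
      i <- which(m[-1L, 1L] != 0)  # drop intercept row
      i
    }))))
    nz[nz <= ncol(fm)]
  } else if (fsConfig$type == "none") {
    seq_len(ncol(fm))
  } else stop("unknown feature-selection type: ", fsConfig$type)
}

.fsConfigId <- function(fs) {
  paste(vapply(fs, function(v) paste0(v, collapse = "+"), character(1)),
        collapse = "|")
}

# ---- nested cross-validation ----------------------------------------------

#' Nested cross-validation benchmark
#'
#' Runs the comparative evaluation protocol: an outer cross-validation loop
#' estimates performance while an inner loop, run within each outer training
#' set, selects — per feature-selection method family — the combination of
#' selection parameters, classifier, and classifier parameters with the
#' best inner accuracy. The winner is refit on the full outer training set
#' and scored on the held-out outer fold. Pooled outer predictions (exactly
#' one per sample) feed the exact binomial comparisons; per-fold
#' selected-feature counts feed the two-tailed t comparisons. The trivial
#' majority-class classifier is always included as the baseline method, and
#' any fold where a method selects zero features falls back to it (logged
#' in the report).
#'
#' Inner ties are broken toward fewer selected features, then toward the
#' simpler classifier.
#'
#' @param data a \linkS4class{MulticlassExperiment}.
#' @param grid a [methodGrid()].
#' @param plan a [foldPlan()] for the samples of `data`.
#' @param registry classifier registry, see [classifierRegistry()].
#' @return an \linkS4class{EvaluationReport}.
#' @export
nestedCV <- function(data, grid = methodGrid(), plan = foldPlan(data),
                     registry = classifierRegistry()) {
  fm <- featureMatrix(data)
  y <- outcomeCodes(data)
  K <- nClasses(data)
  kind <- outcomeKind(data)
  labs <- classLabels(data)
  n <- length(y)
  methods <- names(grid)
  nOuter <- length(plan$outer)

  pooled <- data.frame(sample = seq_len(n), truth = y)
  accMat <- matrix(NA_real_, nOuter, length(methods),
                   dimnames = list(NULL, methods))
  cntMat <- matrix(NA_real_, nOuter, length(methods),
                   dimnames = list(NULL, methods))
  winners <- list()
  fallbacks <- list()
  for (m in methods) pooled[[m]] <- NA_integer_
  pooled[["trivial"]] <- NA_integer_
  trivAcc <- numeric(nOuter)

  evalCombo <- function(trainIdx, testIdx, sel, clfConfig) {
    reg <- registry[[clfConfig$type]]
    if (!length(sel)) {
      pred <- trivialClassifier(y[trainIdx])(length(testIdx))
      return(list(pred = pred, fallback = TRUE))
    }
    xtr <- fm[trainIdx, sel, drop = FALSE]
    xte <- fm[testIdx, sel, drop = FALSE]
    model <- reg$fit(xtr, y[trainIdx], clfConfig, K, kind)
    list(pred = reg$predict(model, xte), fallback = FALSE)
  }

  for (f in seq_len(nOuter)) {
    testIdx <- plan$outer[[f]]
    trainIdx <- setdiff(seq_len(n), testIdx)
    innerFolds <- plan$inner[[f]]

    # trivial baseline
    trivPred <- trivialClassifier(y[trainIdx])(length(testIdx))
    pooled[testIdx, "trivial"] <- trivPred
    trivAcc[f] <- accuracy(trivPred, y[testIdx])

    for (m in methods) {
      fsConfigs <- grid[[m]]$fsConfigs
      clfConfigs <- grid[[m]]$clfConfigs

      # inner loop: per fsConfig, selection is shared across classifiers
      best <- NULL
      for (fs in fsConfigs) {
        innerSel <- lapply(innerFolds, function(teI) {
          trI <- setdiff(trainIdx, teI)
          .selectFeatures(fs, fm[trI, , drop = FALSE], y[trI], K, kind,
                          labs)
        })
        meanSel <- mean(vapply(innerSel, length, numeric(1)))
        for (clf in clfConfigs) {
          accs <- vapply(seq_along(innerFolds), function(i) {
            teI <- innerFolds[[i]]
            trI <- setdiff(trainIdx, teI)
            out <- evalCombo(trI, teI, innerSel[[i]], clf)
            accuracy(out$pred, y[teI])
          }, numeric(1))
          cand <- list(fs = fs, clf = clf, acc = mean(accs),
                       meanSel = meanSel,
                       cx = registry[[clf$type]]$complexity)
          if (is.null(best) || cand$acc > best$acc + 1e-12 ||
              (abs(cand$acc - best$acc) <= 1e-12 &&
               (cand$meanSel < best$meanSel - 1e-9 ||
                (abs(cand$meanSel - best$meanSel) <= 1e-9 &&
                 cand$cx < best$cx))))
            best <- cand
        }
      }

      # refit the winner on the full outer training set
      sel <- .selectFeatures(best$fs, fm[trainIdx, , drop = FALSE],
                             y[trainIdx], K, kind, labs)
      out <- evalCombo(trainIdx, testIdx, sel, best$clf)
      pooled[testIdx, m] <- out$pred
      accMat[f, m] <- accuracy(out$pred, y[testIdx])
      cntMat[f, m] <- length(sel)
      winners[[length(winners) + 1L]] <-
        data.frame(fold = f, method = m,
                   fsConfig = .fsConfigId(best$fs),
                   classifier = .fsConfigId(best$clf),
                   innerAccuracy = best$acc, selected = length(sel))
      if (out$fallback)
        fallbacks[[length(fallbacks) + 1L]] <-
          data.frame(fold = f, method = m)
    }
  }

  allMethods <- c(methods, "trivial")
  accDf <- data.frame(
    method = allMethods,
    meanAccuracy = c(colMeans(accMat), mean(trivAcc)),
    sdAccuracy = c(apply(accMat, 2L, sd), sd(trivAcc)),
    pooledAccuracy = vapply(allMethods, function(m)
      accuracy(pooled[[m]], pooled$truth), numeric(1)),
    row.names = NULL)

  binP <- matrix(NA_real_, length(allMethods), length(allMethods),
                 dimnames = list(allMethods, allMethods))
  for (a in allMethods) for (b in allMethods)
    binP[a, b] <- exactBinomialCompare(pooled[[a]], pooled[[b]],
                                       pooled$truth)
  cntP <- matrix(NA_real_, length(methods), length(methods),
                 dimnames = list(methods, methods))
  for (a in methods) for (b in methods)
    cntP[a, b] <- compareFeatureCounts(cntMat[, a], cntMat[, b])

  new("EvaluationReport",
      methods = allMethods,
      accuracy = accDf,
      pooled = pooled,
      featureCounts = as.data.frame(cntMat),
      binomialP = binP,
      countTTestP = cntP,
      winners = do.call(rbind, winners),
      fallbacks = if (length(fallbacks)) do.call(rbind, fallbacks)
                  else data.frame(fold = integer(0),
                                  method = character(0)),
      plan = list(nOuter = plan$nOuter, nInner = plan$nInner,
                  stratified = plan$stratified, seed = plan$seed))
}

#' @export
setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport over", nrow(object@pooled), "samples,",
      object@plan$nOuter, "outer x", object@plan$nInner, "inner folds\n")
  df <- object@accuracy
  df$meanAccuracy <- round(df$meanAccuracy, 3)
  df$sdAccuracy <- round(df$sdAccuracy, 3)
  df$pooledAccuracy <- round(df$pooledAccuracy, 3)
  print(df, row.names = FALSE)
  if (nrow(object@featureCounts)) {
    cat("mean selected features per method:\n")
    print(round(colMeans(as.matrix(object@featureCounts)), 2))
  }
})

#' Serialize an evaluation report
#'
#' Writes the report as JSON plus two delimited tables mirroring the usual
#' presentation: a per-method accuracy table and a selected-feature-count
#' table, both with companion columns of comparison p-values against the
#' first method.
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param prefix file path prefix; files `<prefix>.json`,
#'   `<prefix>_accuracy.tsv` and `<prefix>_counts.tsv` are written.
#' @return invisibly, the paths written.
#' @export
writeEvaluationReport <- function(report, prefix) {
  ref <- report@methods[1L]
  accTab <- report@accuracy
  accTab$pVsFirst <- vapply(report@methods, function(m)
    report@binomialP[ref, m], numeric(1))
  cnt <- as.matrix(report@featureCounts)
  cntTab <- data.frame(method = colnames(cnt),
                       meanCount = colMeans(cnt),
                       sdCount = apply(cnt, 2L, sd),
                       row.names = NULL)
  cntTab$pVsFirst <- vapply(cntTab$method, function(m)
    report@countTTestP[colnames(cnt)[1L], m], numeric(1))

  paths <- paste0(prefix, c(".json", "_accuracy.tsv", "_counts.tsv"))
  jsonlite::write_json(
    list(accuracy = accTab, featureCounts = report@featureCounts,
         binomialP = report@binomialP, countTTestP = report@countTTestP,
         winners = report@winners, plan = report@plan),
    paths[1L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(accTab, paths[2L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cntTab, paths[3L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
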