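#' Fit a multinomial logistic regression by maximum likelihood
#'
#' Fits the multinomial-logit model
#' \deqn{\log\frac{\Pr(Y_i = k)}{\Pr(Y_i = K)} = \beta_k \cdot w_i, \quad
#'   k = 1, \dots, K-1,}
#' with the last class as baseline, by Newton-Raphson with step halving.
#' Convergence is declared when the relative log-likelihood change falls
#' below `1e-8` or the gradient max-norm below `1e-6`; the iteration cap is
#' 200. Coefficients are box-constrained to `[-30, 30]`, which keeps the
#' likelihood-ratio statistic finite under quasi-complete separation while
#' approximating the supremum of the likelihood.
#'
#' Zero-variance and rank-deficient regressor columns are dropped before
#' fitting (reported in the `dropped` slot), so duplicated or constant
#' columns cannot inflate the parameter count. With an empty regressor set
#' the closed-form intercept-only MLE is returned: fitted class probabilities
#' equal the empirical class frequencies and the log-likelihood equals
#' \eqn{\sum_k n_k \log(n_k/n)}.
#'
#' @param data a \linkS4class{MulticlassExperiment}.
#' @param regressors integer indices of the feature columns to use (may be
#'   empty for the intercept-only model).
#' @return a \linkS4class{MultinomialLogitModel}.
#' @examples
#' sim <- genCategoricalDataset(n = 200, p = 5, K = 3, nRelevant = 2,
#'                              effectSize = 1, seed = 1)
#' fit <- fitMultinomialLogit(sim$data, regressors = 1:2)
#' logLikelihood(fit)
#' @export
fitMultinomialLogit <- function(data, regressors = integer(0)) {
  fm <- featureMatrix(data)
  y <- outcomeCodes(data)
  .fitMnlCore(fm, y, length(classLabels(data)), as.integer(regressors),
              classLabels(data))
}

# Lean fitting path shared by the S4 wrapper and the MMPC hot loop: returns
# a plain list (coef is (q_kept+1) x (K-1), intercept row first).
.mnlFitRaw <- function(fm, y, K, regressors,
                       maxit = 200L, tol = 1e-8, gtol = 1e-6, cap = 30) {
  n <- length(y)
  if (n < K) stop("need at least as many samples as classes")
  X <- fm[, regressors, drop = FALSE]
  keptRel <- .keepFullRank(X)
  q <- length(keptRel)
  if (q == 0L) {
    counts <- tabulate(y + 1L, nbins = K)
    ph <- counts / n
    ll <- sum(counts[counts > 0] * log(ph[counts > 0]))
    return(list(coef = matrix(log(ph[seq_len(K - 1L)] / ph[K]),
                              nrow = 1L),
                loglik = ll, converged = TRUE, kept = keptRel,
                nParams = as.integer(K - 1L)))
  }
  Xd <- cbind(1, X[, keptRel, drop = FALSE])
  fit <- cpp_fit_mnl(Xd, as.integer(y), as.integer(K),
                     maxit = maxit, tol = tol, gtol = gtol, cap = cap)
  list(coef = fit$coefficients, loglik = fit$loglik,
       converged = fit$converged, kept = keptRel,
       nParams = as.integer((K - 1L) * (q + 1L)))
}

.fitMnlCore <- function(fm, y, K, regressors, labs = paste0("C", 0:(K - 1)),
                        maxit = 200L, tol = 1e-8, gtol = 1e-6, cap = 30) {
  raw <- .mnlFitRaw(fm, y, K, regressors, maxit, tol, gtol, cap)
  if (!raw$converged)
    warning("multinomial logit fit did not converge within ", maxit,
            " iterations")
  dropped <- setdiff(seq_along(regressors), raw$kept)
  B <- t(raw$coef)  # (K-1) x (q_kept+1)
  cn <- colnames(fm[, regressors, drop = FALSE])[raw$kept]
  dimnames(B) <- list(labs[seq_len(K - 1L)],
                      c("(Intercept)",
                        if (length(raw$kept))
                          cn %||% paste0("x", raw$kept)))
  new("MultinomialLogitModel",
      coefficients = B, baselineClass = K - 1L,
      logLik = raw$loglik, nParams = raw$nParams,
      converged = raw$converged,
      regressors = as.integer(regressors),
      dropped = as.integer(dropped), classLabels = labs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname mccit-generics
#' @export
setMethod("logLikelihood", "MultinomialLogitModel", function(model)
  model@logLik)

#' @rdname mccit-generics
#' @export
setMethod("nParams", "MultinomialLogitModel", function(model) model@nParams)

#' @rdname mccit-generics
#' @export
setMethod("isConverged", "MultinomialLogitModel", function(model)
  model@converged)

#' @export
setMethod("coef", "MultinomialLogitModel", function(object, ...)
  object@coefficients)

#' @export
setMethod("show", "MultinomialLogitModel", function(object) {
  cat("MultinomialLogitModel:", nrow(object@coefficients) + 1L, "classes,",
      ncol(object@coefficients) - 1L, "regressors\n")
  cat("  logLik:", format(object@logLik), " nParams:", object@nParams,
      " converged:", object@converged, "\n")
  if (length(object@dropped))
    cat("  dropped regressor positions:",
        paste(object@dropped, collapse = ", "), "\n")
})
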