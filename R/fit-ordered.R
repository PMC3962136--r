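#' Fit an ordered-logit (proportional odds) model by maximum likelihood
#'
#' Fits the latent-variable model \eqn{Y^*_i = \beta \cdot w_i + \epsilon_i}
#' with standard-logistic noise, where the observed class is k when
#' \eqn{\mu_{k-1} < Y^*_i \le \mu_k} for strictly increasing thresholds
#' \eqn{\mu_1 < \dots < \mu_{K-1}} (\eqn{\mu_0 = -\infty},
#' \eqn{\mu_K = +\infty}). The class-k probability is
#' \eqn{F(\mu_k - \beta w) - F(\mu_{k-1} - \beta w)} with F the logistic CDF.
#' The model spends q + K - 1 parameters against (K-1)(q+1) for the
#' multinomial logit, which is why it is preferred for ordinal outcomes at
#' small sample sizes.
#'
#' Threshold monotonicity is enforced by fitting the increments
#' \eqn{\delta_j = \log(\mu_{j+1} - \mu_j)}; optimisation is quasi-Newton
#' (L-BFGS-B) with analytic gradients, slope and first threshold bounded to
#' `[-30, 30]`. With an empty regressor set the closed-form intercept-only
#' MLE is returned (cumulative probabilities equal empirical cumulative
#' frequencies).
#'
#' @inheritParams fitMultinomialLogit
#' @return an \linkS4class{OrderedLogitModel}.
#' @examples
#' sim <- genOrdinalDataset(n = 300, p = 4, K = 3, nRelevant = 2,
#'                          effectSize = 1, seed = 1)
#' fit <- fitOrderedLogit(sim$data, regressors = 1:2)
#' fit@thresholds
#' @export
fitOrderedLogit <- function(data, regressors = integer(0)) {
  if (outcomeKind(data) != "ordinal")
    stop("ordered logit requires an ordinal outcome")
  .fitOlCore(featureMatrix(data), outcomeCodes(data),
             length(classLabels(data)), as.integer(regressors),
             classLabels(data))
}

# Lean fitting path shared by the S4 wrapper and the MMPC hot loop.
.olFitRaw <- function(fm, y, K, regressors, cap = 30) {
  n <- length(y)
  if (n < K) stop("need at least as many samples as classes")
  X <- fm[, regressors, drop = FALSE]
  keptRel <- .keepFullRank(X)
  q <- length(keptRel)
  counts <- tabulate(y + 1L, nbins = K)
  cum <- cumsum(counts)[seq_len(K - 1L)] / n

  if (q == 0L) {
    mu <- qlogis(pmin(pmax(cum, 1e-12), 1 - 1e-12))
    ll <- sum(counts[counts > 0] * log(counts[counts > 0] / n))
    return(list(beta = numeric(0), mu = mu, loglik = ll, converged = TRUE,
                kept = keptRel, nParams = as.integer(K - 1L)))
  }

  Xk <- X[, keptRel, drop = FALSE]
  yi <- as.integer(y)

  # theta = (beta_1..beta_q, mu_1, log-increments delta_1..delta_{K-2})
  unpackMu <- function(theta) {
    mu1 <- theta[q + 1L]
    if (K == 2L) mu1 else mu1 + cumsum(c(0, exp(theta[(q + 2L):(q + K - 1L)])))
  }
  nll <- function(theta) {
    beta <- theta[seq_len(q)]
    mu <- unpackMu(theta)
    eta <- drop(Xk %*% beta)
    up <- c(mu, Inf)[yi + 1L] - eta
    lo <- c(-Inf, mu)[yi + 1L] - eta
    P <- plogis(up) - plogis(lo)
    -sum(log(pmax(P, 1e-300)))
  }
  ngr <- function(theta) {
    beta <- theta[seq_len(q)]
    mu <- unpackMu(theta)
    eta <- drop(Xk %*% beta)
    up <- c(mu, Inf)[yi + 1L] - eta
    lo <- c(-Inf, mu)[yi + 1L] - eta
    P <- pmax(plogis(up) - plogis(lo), 1e-300)
    fU <- ifelse(is.finite(up), dlogis(up), 0)
    fL <- ifelse(is.finite(lo), dlogis(lo), 0)
    # d eta / d beta = x, and up/lo both carry -eta, hence the minus
    gBeta <- -drop(crossprod(Xk, (fU - fL) / P))
    gMu <- numeric(K - 1L)
    for (j in seq_len(K - 1L)) {
      iu <- yi == j - 1L     # mu_j is the upper cut for class j-1
      il <- yi == j          # and the lower cut for class j
      gMu[j] <- sum(fU[iu] / P[iu]) - sum(fL[il] / P[il])
    }
    gMu1 <- sum(gMu)
    gDelta <- if (K > 2L)
      exp(theta[(q + 2L):(q + K - 1L)]) *
        rev(cumsum(rev(gMu)))[-1L] else numeric(0)
    -c(gBeta, gMu1, gDelta)
  }

  mu0 <- qlogis(pmin(pmax(cum, 0.02), 0.98))
  start <- c(rep(0, q), mu0[1L],
             if (K > 2L) log(pmax(diff(mu0), 1e-3)) else numeric(0))
  lower <- c(rep(-cap, q), -cap, rep(-20, max(K - 2L, 0L)))
  upper <- c(rep(cap, q), cap, rep(10, max(K - 2L, 0L)))
  opt <- optim(start, nll, ngr, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = 200L, factr = 1e2))
  converged <- opt$convergence == 0L
  beta <- opt$par[seq_len(q)]
  names(beta) <- colnames(X)[keptRel] %||% paste0("x", keptRel)
  list(beta = beta, mu = as.numeric(unpackMu(opt$par)),
       loglik = -opt$value, converged = converged, kept = keptRel,
       nParams = as.integer(q + K - 1L))
}

.fitOlCore <- function(fm, y, K, regressors, labs = paste0("C", 0:(K - 1)),
                       cap = 30) {
  raw <- .olFitRaw(fm, y, K, regressors, cap)
  if (!raw$converged)
    warning("ordered logit fit did not converge")
  dropped <- setdiff(seq_along(regressors), raw$kept)
  new("OrderedLogitModel",
      slope = raw$beta, thresholds = raw$mu, logLik = raw$loglik,
      nParams = raw$nParams, converged = raw$converged,
      regressors = as.integer(regressors),
      dropped = as.integer(dropped), classLabels = labs)
}

#' @rdname mccit-generics
#' @export
setMethod("logLikelihood", "OrderedLogitModel", function(model) model@logLik)

#' @rdname mccit-generics
#' @export
setMethod("nParams", "OrderedLogitModel", function(model) model@nParams)

#' @rdname mccit-generics
#' @export
setMethod("isConverged", "OrderedLogitModel", function(model)
  model@converged)

#' @export
setMethod("coef", "OrderedLogitModel", function(object, ...)
  c(object@slope, setNames(object@thresholds,
                           paste0("mu", seq_along(object@thresholds)))))

#' @export
setMethod("show", "OrderedLogitModel", function(object) {
  cat("OrderedLogitModel:", length(object@classLabels), "ordered classes,",
      length(object@slope), "regressors\n")
  cat("  logLik:", format(object@logLik), " nParams:", object@nParams,
      " converged:", object@converged, "\n")
  cat("  thresholds:", paste(format(object@thresholds, digits = 4),
                             collapse = " < "), "\n")
})
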