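#' Multi-class conditional independence test (MC-CIT)
#'
#' Tests the null hypothesis that feature `x` is independent of the outcome
#' given the conditioning features `cond`, by comparing two nested regression
#' models of the outcome: the full model on `cond` and `x`, and the
#' alternative model on `cond` alone. The models are multinomial logits for
#' nominal outcomes and ordered logits for ordinal outcomes. The deviance
#' difference
#' \deqn{D = 2\,(\mathrm{LogL}_{Full} - \mathrm{LogL}_{Altern}) \ge 0}
#' is referred to a chi-squared distribution whose degrees of freedom follow
#' the configured convention (see [citConfig()]).
#'
#' A zero-variance `x`, or an `x` exactly collinear with the conditioning
#' set, is dropped during fitting, so the two models achieve the same
#' likelihood and the test returns statistic 0 and p-value 1. The test is
#' marked non-assessable only when neither model fit converged.
#'
#' @inheritParams citTest
#' @return a \linkS4class{CITResult}.
#' @examples
#' sim <- genCategoricalDataset(n = 150, p = 6, K = 3, nRelevant = 2,
#'                              effectSize = 1, seed = 7)
#' mcCIT(sim$data, x = sim$truth@relevantFeatures[1])
#' @export
mcCIT <- function(data, x, cond = integer(0), config = citConfig()) {
  fm <- featureMatrix(data)
  .mcCitCore(fm, outcomeCodes(data), nClasses(data), outcomeKind(data),
             x, cond, config$dfConvention)
}

.mcCitCore <- function(fm, y, K, kind, x, cond, dfConvention = "param_diff",
                       llAlt = NULL) {
  x <- as.integer(x); cond <- as.integer(cond)
  if (x %in% cond) stop("x must not be part of the conditioning set")
  n <- length(y)

  fitFun <- if (kind == "ordinal") .fitOlCore else .fitMnlCore
  full <- fitFun(fm, y, K, c(cond, x))
  alt <- if (!is.null(llAlt)) NULL else fitFun(fm, y, K, cond)
  llA <- if (is.null(llAlt)) alt@logLik else llAlt
  okFull <- full@converged
  okAlt <- if (is.null(llAlt)) alt@converged else TRUE

  stat <- max(0, 2 * (full@logLik - llA))
  df <- if (dfConvention == "single_df") 1L
        else if (kind == "ordinal") 1L else K - 1L
  if (!okFull && !okAlt) {
    warning("neither model fit converged; MC-CIT not assessable")
    return(CITResult(1, stat, df, assessable = FALSE,
                     testName = "mc_cit", nUsed = n))
  }
  CITResult(pchisq(stat, df, lower.tail = FALSE), stat, df,
            assessable = TRUE, testName = "mc_cit", nUsed = n)
}
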