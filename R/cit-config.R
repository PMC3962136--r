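#' Configuration for conditional independence tests
#'
#' @param testKind which test to run: `"mc_cit"` (nested multinomial / ordered
#'   logit likelihood-ratio test), `"fisher_z"` (partial-correlation z test
#'   with the outcome encoded as an integer), or `"g2"` (stratified
#'   G-squared on three-bin discretized features).
#' @param dfConvention degrees of freedom for the MC-CIT chi-squared
#'   reference: `"param_diff"` (the number of extra parameters the tested
#'   variable brings: K-1 for the multinomial model, 1 for the ordered
#'   logit — the statistically correct choice and the default) or
#'   `"single_df"` (a single degree of freedom regardless of K, for
#'   reproducing analyses that refer the deviance to one degree of
#'   freedom).
#' @param g2Hpa heuristic power threshold for the G-squared test: the test is
#'   assessed only when `n >= g2Hpa * df`, the usual
#'   average-samples-per-degree-of-freedom rule in constraint-based
#'   implementations. Default 5.
#' @return a list of class `"CITConfig"`.
#' @export
citConfig <- function(testKind = c("mc_cit", "fisher_z", "g2"),
                      dfConvention = c("param_diff", "single_df"),
                      g2Hpa = 5L) {
  stopifnot(g2Hpa >= 1)
  structure(list(testKind = match.arg(testKind),
                 dfConvention = match.arg(dfConvention),
                 g2Hpa = as.integer(g2Hpa)),
            class = "CITConfig")
}

#' Construct a CITResult
#'
#' Builds the uniform result object every conditional independence test
#' returns. User-supplied tests plugged into [mmpc()] should use this
#' constructor (see [genBNFixture()] for a d-separation oracle example).
#'
#' @param pValue p-value in `[0, 1]` (forced to 1 when `assessable` is
#'   `FALSE`).
#' @param statistic test statistic.
#' @param df degrees of freedom.
#' @param assessable whether the test could be carried out.
#' @param testName identifier of the test.
#' @param nUsed number of samples used.
#' @return a \linkS4class{CITResult}.
#' @export
CITResult <- function(pValue, statistic = NA_real_, df = 1L,
                      assessable = TRUE, testName = "custom",
                      nUsed = NA_integer_) {
  if (!assessable) pValue <- 1
  new("CITResult", pValue = as.numeric(pValue),
      statistic = as.numeric(statistic), df = as.integer(df),
      assessable = assessable, testName = testName,
      nUsed = as.integer(nUsed))
}

#' @rdname mccit-generics
#' @export
setMethod("pValue", "CITResult", function(object) object@pValue)

#' @rdname mccit-generics
#' @export
setMethod("testStatistic", "CITResult", function(object) object@statistic)

#' @export
setMethod("show", "CITResult", function(object) {
  cat("CITResult [", object@testName, "]\n", sep = "")
  cat("  statistic:", format(object@statistic, digits = 5),
      " df:", object@df,
      " p-value:", format.pval(object@pValue, digits = 4), "\n")
  if (!object@assessable)
    cat("  not assessable (p-value set to 1 by convention)\n")
})

#' Dispatch a conditional independence test by configuration
#'
#' Uniform entry point used by [mmpc()]: runs the test named in `config` for
#' feature `x` against the outcome given the conditioning features `cond`.
#'
#' @param data a \linkS4class{MulticlassExperiment}.
#' @param x feature index to test.
#' @param cond integer vector of conditioning feature indices (may be empty).
#' @param config a [citConfig()].
#' @return a \linkS4class{CITResult}.
#' @export
citTest <- function(data, x, cond = integer(0), config = citConfig()) {
  switch(config$testKind,
         mc_cit = mcCIT(data, x, cond, config),
         fisher_z = fisherZCIT(data, x, cond),
         g2 = g2CIT(data, x, cond, config))
}
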