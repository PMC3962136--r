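#' MulticlassExperiment: continuous features with a multi-class outcome
#'
#' A \linkS4class{SummarizedExperiment} subclass holding a continuous feature
#' matrix (features in rows, samples in columns, as usual for expression data)
#' together with a per-sample multi-class outcome declared either nominal or
#' ordinal. The outcome is stored in `colData` as integer class codes
#' `0..K-1`; the original class labels and the declared kind live in
#' `metadata`. For ordinal outcomes the label order is meaningful and class
#' codes respect it; for nominal outcomes labels are sorted lexicographically
#' before coding (the same convention the Fisher Z test uses to encode the
#' outcome as an integer).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso [MulticlassExperiment()], [featureMatrix()], [outcomeCodes()]
#' @exportClass MulticlassExperiment
setClass("MulticlassExperiment", contains = "SummarizedExperiment")

setValidity("MulticlassExperiment", function(object) {
  msg <- character(0)
  a <- assay(object)
  if (!is.numeric(a))
    msg <- c(msg, "feature matrix must be numeric")
  if (anyNA(a))
    msg <- c(msg, "feature matrix must not contain missing values")
  cd <- colData(object)
  if (!"outcomeCode" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain an 'outcomeCode' column")
  } else {
    y <- cd$outcomeCode
    labs <- metadata(object)$classLabels
    kind <- metadata(object)$outcomeKind
    if (is.null(kind) || !kind %in% c("nominal", "ordinal"))
      msg <- c(msg, "metadata$outcomeKind must be 'nominal' or 'ordinal'")
    if (anyNA(y))
      msg <- c(msg, "outcome must not contain missing values")
    K <- length(labs)
    if (K < 2)
      msg <- c(msg, "at least two outcome classes are required")
    if (length(y) && (min(y) < 0L || max(y) > K - 1L))
      msg <- c(msg, "outcome codes must lie in 0..K-1")
    if (!all((seq_len(K) - 1L) %in% y))
      msg <- c(msg, "every class code in 0..K-1 must appear at least once")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted multinomial-logit model
#'
#' Maximum-likelihood fit of the multinomial logistic model
#' \eqn{\log(\Pr(Y=k)/\Pr(Y=K)) = \beta_k \cdot w}, k = 1..K-1, with the last
#' class as baseline. Coefficients are stored as a (K-1) x (q+1) matrix whose
#' first column is the intercept and whose remaining columns follow the order
#' of the regressors actually kept after dropping zero-variance and
#' rank-deficient columns (the dropped positions are recorded in `dropped`).
#'
#' @slot coefficients (K-1) x (q+1) numeric matrix, column 1 = intercept.
#' @slot baselineClass integer code of the baseline class (K-1).
#' @slot logLik achieved maximised log-likelihood.
#' @slot nParams integer, (K-1) * (q+1) for the columns actually fitted.
#' @slot converged logical.
#' @slot regressors integer indices of the regressors requested at fit time.
#' @slot dropped integer positions (within `regressors`) dropped before
#'   fitting.
#' @slot classLabels character labels of the outcome classes.
#' @exportClass MultinomialLogitModel
setClass("MultinomialLogitModel", representation(
  coefficients = "matrix",
  baselineClass = "integer",
  logLik = "numeric",
  nParams = "integer",
  converged = "logical",
  regressors = "integer",
  dropped = "integer",
  classLabels = "character"
))

setValidity("MultinomialLogitModel", function(object) {
  K <- length(object@classLabels)
  if (nrow(object@coefficients) != K - 1L)
    return("coefficients must have K-1 rows")
  if (object@nParams != length(object@coefficients))
    return("nParams inconsistent with coefficient shape")
  TRUE
})

#' Fitted ordered-logit (proportional odds) model
#'
#' Maximum-likelihood fit of the latent-variable model \eqn{Y^* = \beta \cdot
#' w + \epsilon} with logistic noise, observed class k when \eqn{Y^*} falls
#' between consecutive thresholds \eqn{\mu_{k-1} < Y^* \le \mu_k}
#' (\eqn{\mu_0 = -\infty}, \eqn{\mu_K = +\infty}). Thresholds are strictly
#' increasing by construction (fitted through log-increments).
#'
#' @slot slope numeric vector of length q (regressors kept after dropping).
#' @slot thresholds strictly increasing numeric vector of length K-1.
#' @slot logLik achieved maximised log-likelihood.
#' @slot nParams integer, q + K - 1.
#' @slot converged logical.
#' @slot regressors,dropped as in \linkS4class{MultinomialLogitModel}.
#' @slot classLabels character labels of the outcome classes (in order).
#' @exportClass OrderedLogitModel
setClass("OrderedLogitModel", representation(
  slope = "numeric",
  thresholds = "numeric",
  logLik = "numeric",
  nParams = "integer",
  converged = "logical",
  regressors = "integer",
  dropped = "integer",
  classLabels = "character"
))

setValidity("OrderedLogitModel", function(object) {
  K <- length(object@classLabels)
  if (length(object@thresholds) != K - 1L)
    return("thresholds must have length K-1")
  if (length(object@thresholds) > 1L && any(diff(object@thresholds) <= 0))
    return("thresholds must be strictly increasing")
  if (object@nParams != length(object@slope) + K - 1L)
    return("nParams must equal q + K - 1")
  TRUE
})

#' Result of one conditional independence test
#'
#' Uniform result container returned by every conditional independence test
#' in the package (and by user-supplied tests plugged into [mmpc()]). When a
#' test cannot be assessed (e.g. the G-squared power heuristic refuses it, or
#' neither model fit converged) `assessable` is `FALSE` and the p-value is 1
#' by convention: independence is not refutable.
#'
#' @slot pValue numeric in `[0, 1]`.
#' @slot statistic numeric test statistic.
#' @slot df integer degrees of freedom (>= 1 when assessable).
#' @slot assessable logical.
#' @slot testName character identifier.
#' @slot nUsed integer number of samples used.
#' @exportClass CITResult
setClass("CITResult", representation(
  pValue = "numeric",
  statistic = "numeric",
  df = "integer",
  assessable = "logical",
  testName = "character",
  nUsed = "integer"
))

setValidity("CITResult", function(object) {
  if (length(object@pValue) != 1L || is.na(object@pValue) ||
      object@pValue < 0 || object@pValue > 1)
    return("pValue must be a single number in [0, 1]")
  if (object@assessable && object@df < 1L)
    return("df must be >= 1 when the test is assessable")
  if (!object@assessable && object@pValue != 1)
    return("non-assessable tests must carry pValue = 1")
  TRUE
})

#' Result of an MMPC run
#'
#' @slot selected integer feature indices, in insertion order after the
#'   backward phase.
#' @slot selectedNames character feature names for `selected`.
#' @slot trace data.frame of decision records with columns `phase`,
#'   `feature`, `condSet` (comma-separated indices), `pValue`, `action`
#'   (one of `added`, `rejected`, `removed`).
#' @slot testsPerformed integer count of distinct tests actually evaluated
#'   (cache hits are not recounted).
#' @slot config list echo of the resolved configuration.
#' @exportClass MMPCResult
setClass("MMPCResult", representation(
  selected = "integer",
  selectedNames = "character",
  trace = "data.frame",
  testsPerformed = "integer",
  config = "list"
))

setValidity("MMPCResult", function(object) {
  if (anyDuplicated(object@selected))
    return("selected features must be unique")
  TRUE
})

#' Ground truth attached to a synthetic dataset
#'
#' @slot relevantFeatures integer indices of features carrying signal.
#' @slot params list of generating parameters (coefficients, thresholds,
#'   weights as applicable).
#' @slot graph optional adjacency matrix of a generating DAG (0 x 0 when
#'   absent).
#' @slot pcSet integer indices of the outcome's true parents-and-children set
#'   (empty when no graph is involved).
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  relevantFeatures = "integer",
  params = "list",
  graph = "matrix",
  pcSet = "integer"
))

#' Nested cross-validation evaluation report
#'
#' Aggregated output of [nestedCV()]: per-method outer-fold accuracies,
#' pooled predictions, selected-feature counts, and pairwise comparison
#' p-values (exact binomial on pooled predictions, two-tailed t on counts).
#'
#' @slot methods character method identifiers (the trivial classifier is
#'   always included as `"trivial"`).
#' @slot accuracy data.frame with columns `method`, `meanAccuracy`,
#'   `sdAccuracy`, `pooledAccuracy`.
#' @slot pooled data.frame with `sample`, `truth`, one prediction column per
#'   method; exactly one row per sample.
#' @slot featureCounts data.frame of per-outer-fold selected-feature counts
#'   (methods in columns; NA for methods that do not select).
#' @slot binomialP symmetric matrix of pairwise exact binomial p-values on
#'   pooled predictions.
#' @slot countTTestP symmetric matrix of pairwise two-tailed t-test p-values
#'   on selected-feature counts.
#' @slot winners data.frame recording the winning configuration per method
#'   and outer fold.
#' @slot fallbacks data.frame logging folds where a method selected zero
#'   features and fell back to the trivial classifier.
#' @slot plan list echo of the fold plan parameters.
#' @exportClass EvaluationReport
setClass("EvaluationReport", representation(
  methods = "character",
  accuracy = "data.frame",
  pooled = "data.frame",
  featureCounts = "data.frame",
  binomialP = "matrix",
  countTTestP = "matrix",
  winners = "data.frame",
  fallbacks = "data.frame",
  plan = "list"
))
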