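#' Construct a MulticlassExperiment
#'
#' Bundles a continuous feature matrix (samples in rows, features in columns,
#' the orientation in which delimited files are usually shipped) with a
#' multi-class outcome into a \linkS4class{MulticlassExperiment}. The matrix
#' is transposed into the features-by-samples orientation that
#' SummarizedExperiment uses internally.
#'
#' Class coding follows the declared outcome kind: for `"ordinal"` outcomes
#' the order of `classOrder` (or of the factor levels) is respected; for
#' `"nominal"` outcomes labels are sorted lexicographically and then coded
#' `0..K-1`.
#'
#' @param features numeric matrix, n samples x p features. Column names are
#'   used as feature identifiers (generated as `F1..Fp` when absent).
#' @param outcome per-sample outcome: a factor, a character vector, or
#'   integer class codes in `0..K-1`.
#' @param outcomeKind `"nominal"` or `"ordinal"`.
#' @param classOrder optional character vector giving the class label order;
#'   required for ordinal outcomes supplied as character vectors.
#' @return a `MulticlassExperiment`.
#' @examples
#' x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("g1", "g2")))
#' y <- rep(c("A", "B"), 10)
#' mce <- MulticlassExperiment(x, y, "nominal")
#' nClasses(mce)
#' @export
MulticlassExperiment <- function(features, outcome,
                                 outcomeKind = c("nominal", "ordinal"),
                                 classOrder = NULL) {
  outcomeKind <- match.arg(outcomeKind)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features)))
    colnames(features) <- paste0("F", seq_len(ncol(features)))
  if (nrow(features) != length(outcome))
    stop("outcome length (", length(outcome),
         ") does not match the number of samples (", nrow(features), ")")

  if (is.factor(outcome)) {
    labs <- levels(outcome)
    if (outcomeKind == "nominal") labs <- sort(labs)
    codes <- match(as.character(outcome), labs) - 1L
  } else if (is.character(outcome)) {
    if (is.null(classOrder)) {
      if (outcomeKind == "ordinal")
        stop("ordinal outcomes supplied as character require 'classOrder'")
      labs <- sort(unique(outcome))
    } else {
      labs <- classOrder
      unknown <- setdiff(unique(outcome), labs)
      if (length(unknown))
        stop("unknown class label(s): ", paste(unknown, collapse = ", "))
    }
    codes <- match(outcome, labs) - 1L
  } else {
    codes <- as.integer(outcome)
    if (anyNA(codes)) stop("outcome contains missing values")
    K <- max(codes) + 1L
    labs <- if (is.null(classOrder)) paste0("C", seq_len(K) - 1L)
            else classOrder
  }

  se <- SummarizedExperiment(
    assays = list(features = t(features)),
    colData = DataFrame(outcomeCode = codes,
                        outcomeLabel = labs[codes + 1L]))
  metadata(se)$outcomeKind <- outcomeKind
  metadata(se)$classLabels <- labs
  as(se, "MulticlassExperiment")
}

# Internal constructor bypassing validity checks, for hot paths and for fold
# subsets that may legitimately miss a class.
.newDataset <- function(features, codes, kind, labs) {
  se <- SummarizedExperiment(
    assays = list(features = t(features)),
    colData = DataFrame(outcomeCode = as.integer(codes),
                        outcomeLabel = labs[as.integer(codes) + 1L]))
  metadata(se)$outcomeKind <- kind
  metadata(se)$classLabels <- labs
  new2("MulticlassExperiment", se, check = FALSE)
}

#' @describeIn MulticlassExperiment samples-by-features numeric matrix.
#' @param object a `MulticlassExperiment`.
#' @export
setMethod("featureMatrix", "MulticlassExperiment", function(object)
  t(assay(object)))

#' @describeIn MulticlassExperiment integer class codes `0..K-1`.
#' @export
setMethod("outcomeCodes", "MulticlassExperiment", function(object)
  colData(object)$outcomeCode)

#' @describeIn MulticlassExperiment `"nominal"` or `"ordinal"`.
#' @export
setMethod("outcomeKind", "MulticlassExperiment", function(object)
  metadata(object)$outcomeKind)

#' @describeIn MulticlassExperiment class labels, in code order.
#' @export
setMethod("classLabels", "MulticlassExperiment", function(object)
  metadata(object)$classLabels)

#' @describeIn MulticlassExperiment number of outcome classes K.
#' @export
setMethod("nClasses", "MulticlassExperiment", function(object)
  length(metadata(object)$classLabels))

#' @export
setMethod("show", "MulticlassExperiment", function(object) {
  cat("MulticlassExperiment:", ncol(object), "samples x", nrow(object),
      "features\n")
  cat("  outcome:", outcomeKind(object), "with",
      nClasses(object), "classes (",
      paste(classLabels(object), collapse = " < "), ")\n")
  tab <- table(factor(outcomeCodes(object),
                      levels = seq_len(nClasses(object)) - 1L))
  cat("  class counts:", paste(tab, collapse = " / "), "\n")
})
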