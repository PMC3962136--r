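#' @name mccit-generics
#' @title Accessor generics
#' @description Accessor generics for the package's S4 classes.
#' @param object,model an object of the documented class.
#' @param ... passed to methods.
NULL

#' @rdname mccit-generics
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname mccit-generics
#' @export
setGeneric("outcomeCodes", function(object) standardGeneric("outcomeCodes"))

#' @rdname mccit-generics
#' @export
setGeneric("outcomeKind", function(object) standardGeneric("outcomeKind"))

#' @rdname mccit-generics
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname mccit-generics
#' @export
setGeneric("nClasses", function(object) standardGeneric("nClasses"))

#' @rdname mccit-generics
#' @export
setGeneric("logLikelihood", function(model) standardGeneric("logLikelihood"))

#' @rdname mccit-generics
#' @export
setGeneric("nParams", function(model) standardGeneric("nParams"))

#' @rdname mccit-generics
#' @export
setGeneric("isConverged", function(model) standardGeneric("isConverged"))

#' Predict class probabilities from a fitted model
#'
#' Evaluates the fitted model's class-probability equations on new feature
#' rows. The matrix must have as many columns as regressors were requested at
#' fit time (columns dropped during fitting are dropped again here). Each
#' returned row is non-negative and sums to one; columns are ordered by class
#' code and named with the class labels.
#'
#' @param model a [MultinomialLogitModel-class] or [OrderedLogitModel-class].
#' @param features numeric matrix of new observations.
#' @return numeric matrix of class probabilities, one row per observation.
#' @export
setGeneric("predictProba", function(model, features)
  standardGeneric("predictProba"))

#' @rdname mccit-generics
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname mccit-generics
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))

#' @rdname mccit-generics
#' @export
setGeneric("selectedFeatures", function(object)
  standardGeneric("selectedFeatures"))

#' @rdname mccit-generics
#' @export
setGeneric("mmpcTrace", function(object) standardGeneric("mmpcTrace"))

#' @rdname mccit-generics
#' @export
setGeneric("testsPerformed", function(object)
  standardGeneric("testsPerformed"))
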