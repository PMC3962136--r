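.checkPredictDims <- function(model, features) {
  features <- as.matrix(features)
  qReq <- length(model@regressors)
  if (ncol(features) != qReq)
    stop("feature matrix has ", ncol(features),
         " columns but the model was fitted on ", qReq, " regressors")
  kept <- setdiff(seq_len(qReq), model@dropped)
  features[, kept, drop = FALSE]
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "MultinomialLogitModel",
  function(model, features) {
    X <- .checkPredictDims(model, features)
    B <- model@coefficients                # (K-1) x (q+1)
    eta <- cbind(1, X) %*% t(B)            # m x (K-1)
    full <- cbind(eta, 0)                  # baseline column last
    full <- full - apply(full, 1L, max)
    P <- exp(full)
    P <- P / rowSums(P)
    colnames(P) <- model@classLabels
    P
  })

#' @rdname predictProba
#' @export
setMethod("predictProba", "OrderedLogitModel",
  function(model, features) {
    X <- .checkPredictDims(model, features)
    eta <- if (length(model@slope)) drop(X %*% model@slope)
           else rep(0, nrow(X))
    K <- length(model@classLabels)
    cutUp <- c(model@thresholds, Inf)
    cutLo <- c(-Inf, model@thresholds)
    P <- vapply(seq_len(K), function(k)
      plogis(cutUp[k] - eta) - plogis(cutLo[k] - eta), numeric(nrow(X)))
    P <- matrix(P, nrow = nrow(X), ncol = K,
                dimnames = list(NULL, model@classLabels))
    P <- pmax(P, 0)
    P / rowSums(P)
  })

#' Predict the most probable class
#'
#' Convenience wrapper around [predictProba()]: returns the integer class
#' code (0-based) with the highest fitted probability for each row; ties are
#' broken toward the lower class code.
#'
#' @inheritParams predictProba
#' @return integer vector of class codes.
#' @export
predictClass <- function(model, features) {
  P <- predictProba(model, features)
  max.col(P, ties.method = "first") - 1L
}
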