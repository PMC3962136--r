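#' Fisher Z conditional independence test
#'
#' The classical partial-correlation test, applied by encoding the outcome
#' as an integer variable: class codes `0..K-1` follow the declared order for
#' ordinal outcomes and the lexicographic label sort for nominal outcomes
#' (which imposes a possibly unnatural order — the known caveat of using this
#' test with multi-class outcomes). The partial correlation r of `x` and the
#' encoded outcome given `cond` is z-transformed,
#' \eqn{z = \tfrac12 \log\frac{1+r}{1-r}}, and
#' \eqn{\sqrt{n - |cond| - 3}\,|z|} is referred to the standard normal
#' (two-sided).
#'
#' @inheritParams citTest
#' @return a \linkS4class{CITResult} with `df = 1`. Non-assessable when
#'   `n - |cond| - 3 < 1`.
#' @export
fisherZCIT <- function(data, x, cond = integer(0)) {
  fm <- featureMatrix(data)
  .fisherZCore(fm, as.numeric(outcomeCodes(data)), as.integer(x),
               as.integer(cond))
}

.fisherZCore <- function(fm, yNum, x, cond) {
  if (x %in% cond) stop("x must not be part of the conditioning set")
  n <- length(yNum)
  dfree <- n - length(cond) - 3L
  if (dfree < 1L)
    return(CITResult(1, NA_real_, 1L, assessable = FALSE,
                     testName = "fisher_z", nUsed = n))

  xv <- fm[, x]
  if (length(cond)) {
    Z <- cbind(1, fm[, cond, drop = FALSE])
    rx <- xv - Z %*% qr.coef(qr(Z), xv)
    ry <- yNum - Z %*% qr.coef(qr(Z), yNum)
    rx[is.na(rx)] <- 0; ry[is.na(ry)] <- 0
  } else {
    rx <- xv - mean(xv)
    ry <- yNum - mean(yNum)
  }
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  if (sx < 1e-12 || sy < 1e-12)
    return(CITResult(1, 0, 1L, TRUE, "fisher_z", n))
  r <- sum(rx * ry) / (sx * sy)
  if (abs(r) >= 1 - 1e-12) {
    stat <- sqrt(dfree) * 18.7  # |z| clipped at atanh(1 - 1e-16)
    return(CITResult(0, stat, 1L, TRUE, "fisher_z", n))
  }
  z <- 0.5 * log((1 + r) / (1 - r))
  stat <- sqrt(dfree) * abs(z)
  CITResult(2 * pnorm(stat, lower.tail = FALSE), stat, 1L, TRUE,
            "fisher_z", n)
}
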