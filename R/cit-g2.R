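#' Three-bin discretization around the mean
#'
#' Assigns each value to `low` (code 0), `medium` (code 1) or `high`
#' (code 2) according to whether it falls below, within, or above one sample
#' standard deviation (n-1 denominator) of the mean: low iff
#' `v < mean - sd`, high iff `v > mean + sd`, medium otherwise. A constant
#' vector (sd = 0) is entirely medium.
#'
#' @param values numeric vector.
#' @return integer vector of codes in `{0, 1, 2}` of the same length.
#' @examples
#' discretizeThreeBins(c(0, 0, 0, 0, 10))
#' @export
discretizeThreeBins <- function(values) {
  if (!length(values)) stop("empty vector")
  m <- mean(values)
  s <- sd(values)
  if (is.na(s)) s <- 0
  codes <- rep(1L, length(values))
  codes[values < m - s] <- 0L
  codes[values > m + s] <- 2L
  codes
}

#' G-squared conditional independence test on discretized features
#'
#' The asymptotic likelihood-ratio test for discrete variables on stratified
#' contingency tables. Continuous features are first discretized with the
#' three-bin mean +/- sd scheme (set `discretize = FALSE` if the feature
#' columns already hold integer codes); the outcome keeps its native
#' classes. Within every stratum of the conditioning variables,
#' \eqn{G^2 = 2 \sum O \log(O/E)} accumulates over the x-by-outcome table
#' with expectations from the stratum margins (0 log 0 = 0); empty strata
#' are skipped and their degrees of freedom subtracted.
#'
#' Nominal degrees of freedom are
#' \eqn{(L_x - 1)(K - 1) \prod_z L_z} over the observed level counts. The
#' power heuristic forgoes the test (non-assessable, p-value 1) when
#' `n < g2Hpa * df`, so that on average at least `g2Hpa` samples back each
#' degree of freedom.
#'
#' @inheritParams citTest
#' @param discretize apply [discretizeThreeBins()] to the feature columns
#'   (default) or treat them as integer codes.
#' @return a \linkS4class{CITResult}.
#' @export
g2CIT <- function(data, x, cond = integer(0), config = citConfig("g2"),
                  discretize = TRUE) {
  fm <- featureMatrix(data)
  disc <- if (discretize) NULL else fm
  .g2Core(fm, outcomeCodes(data), as.integer(x), as.integer(cond),
          config$g2Hpa, disc = disc)
}

# disc: optional pre-discretized matrix (integer codes); columns of `fm` are
# discretized on demand when disc is NULL.
.g2Core <- function(fm, y, x, cond, hpa = 5L, disc = NULL) {
  if (x %in% cond) stop("x must not be part of the conditioning set")
  n <- length(y)
  col <- function(j) if (is.null(disc)) discretizeThreeBins(fm[, j])
                     else as.integer(disc[, j])
  xv <- col(x)
  Lx <- length(unique(xv))
  Ky <- length(unique(y))
  if (Lx < 2L || Ky < 2L)
    return(CITResult(1, 0, 1L, assessable = FALSE, testName = "g2",
                     nUsed = n))
  Lz <- integer(0)
  if (length(cond)) {
    zcols <- lapply(cond, col)
    Lz <- vapply(zcols, function(v) length(unique(v)), integer(1))
    stratum <- interaction(as.data.frame(zcols), drop = FALSE)
  } else {
    stratum <- factor(rep(1L, n))
  }
  dfNominal <- (Lx - 1L) * (Ky - 1L) * prod(Lz)
  if (n < hpa * dfNominal)
    return(CITResult(1, NA_real_, as.integer(dfNominal),
                     assessable = FALSE, testName = "g2", nUsed = n))

  g2 <- 0
  dfAdj <- dfNominal
  for (lev in levels(stratum)) {
    idx <- stratum == lev
    if (!any(idx)) {
      dfAdj <- dfAdj - (Lx - 1L) * (Ky - 1L)
      next
    }
    tab <- table(xv[idx], y[idx])
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    O <- as.numeric(tab)
    Ev <- as.numeric(E)
    pos <- O > 0
    g2 <- g2 + 2 * sum(O[pos] * log(O[pos] / Ev[pos]))
  }
  if (dfAdj < 1L)
    return(CITResult(1, g2, 1L, assessable = FALSE, testName = "g2",
                     nUsed = n))
  CITResult(pchisq(g2, dfAdj, lower.tail = FALSE), g2, as.integer(dfAdj),
            assessable = TRUE, testName = "g2", nUsed = n)
}
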