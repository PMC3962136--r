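#' @export
setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@relevantFeatures),
      "relevant feature(s)\n")
  if (length(object@relevantFeatures))
    cat("  indices:", paste(object@relevantFeatures, collapse = ", "), "\n")
  if (length(object@pcSet))
    cat("  PC set:", paste(object@pcSet, collapse = ", "), "\n")
})

# Draw class codes 0..K-1 from per-sample probability rows.
.sampleClasses <- function(P) {
  u <- runif(nrow(P))
  cs <- t(apply(P, 1L, cumsum))
  codes <- rowSums(u > cs)
  as.integer(pmin(codes, ncol(P) - 1L))
}

# Regenerate with an incremented sub-seed until all K classes appear
# (guaranteed quickly for n >= 50 K under the default marginals).
.drawAllClasses <- function(K, draw, seed, maxTries = 25L) {
  for (t in seq_len(maxTries)) {
    out <- .withSeed(.subSeed(seed, (t - 1L) * 1000003L), draw())
    if (all((seq_len(K) - 1L) %in% out$y)) {
      if (t > 1L)
        message("resampled ", t - 1L,
                " time(s) to cover all outcome classes")
      return(out)
    }
  }
  stop("could not generate a dataset covering all ", K, " classes")
}

#' Generate a categorical-outcome dataset from the multinomial-logit law
#'
#' Features are i.i.d. standard normal (emulating normalised expression
#' values); the outcome is drawn from the multinomial-logit model whose
#' nonzero coefficients — magnitude `effectSize`, signs alternating across
#' relevant features and outcome classes — sit only on `nRelevant` randomly
#' placed relevant features. With `effectSize = 0` the outcome is uniform
#' and independent of every feature. Fully reproducible from `seed`.
#'
#' @param n number of samples.
#' @param p number of features.
#' @param K number of outcome classes (>= 2).
#' @param nRelevant number of features carrying signal (<= p).
#' @param effectSize coefficient magnitude on relevant features.
#' @param seed integer seed.
#' @return list with `data` (a \linkS4class{MulticlassExperiment}) and
#'   `truth` (a \linkS4class{GroundTruth}).
#' @export
genCategoricalDataset <- function(n, p, K = 3L, nRelevant = 2L,
                                  effectSize = 1, seed = 1L) {
  if (nRelevant > p) stop("nRelevant must not exceed p")
  if (K < 2L) stop("K must be at least 2")
  draw <- function() {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("F", seq_len(p))))
    rel <- sort(sample.int(p, nRelevant))
    B <- matrix(0, K - 1L, nRelevant)
    for (k in seq_len(K - 1L))
      for (j in seq_len(nRelevant))
        B[k, j] <- effectSize * (-1)^(k + j)
    eta <- if (nRelevant) X[, rel, drop = FALSE] %*% t(B)
           else matrix(0, n, K - 1L)
    full <- cbind(eta, 0)
    full <- full - apply(full, 1L, max)
    P <- exp(full) / rowSums(exp(full))
    list(X = X, y = .sampleClasses(P), rel = rel, B = B)
  }
  out <- .drawAllClasses(K, draw, seed)
  data <- MulticlassExperiment(out$X, out$y, "nominal",
                               classOrder = paste0("C", seq_len(K) - 1L))
  truth <- new("GroundTruth",
               relevantFeatures = as.integer(out$rel),
               params = list(coefficients = out$B,
                             effectSize = effectSize),
               graph = matrix(0, 0, 0), pcSet = as.integer(out$rel))
  list(data = data, truth = truth)
}

#' Generate an ordinal-outcome dataset from the latent-threshold mechanism
#'
#' Features are i.i.d. standard normal; the latent score is
#' `X[, relevant] %*% beta` plus standard-logistic noise, with
#' `beta = effectSize * (-1)^(j+1)` over relevant features, and the observed
#' class is the interval of the latent score between consecutive
#' `thresholds`. Default thresholds are equally spaced and centred at zero
#' (`(k - K/2)` for k = 1..K-1), giving a unimodal class distribution;
#' supplying thresholds at logistic quantiles yields chosen marginals under
#' `effectSize = 0`.
#'
#' @inheritParams genCategoricalDataset
#' @param thresholds optional strictly increasing numeric vector of length
#'   K-1 replacing the equally spaced default.
#' @return as [genCategoricalDataset()]; the outcome is declared ordinal.
#' @export
genOrdinalDataset <- function(n, p, K = 3L, nRelevant = 2L, effectSize = 1,
                              seed = 1L, thresholds = NULL) {
  if (nRelevant > p) stop("nRelevant must not exceed p")
  if (K < 2L) stop("K must be at least 2")
  if (is.null(thresholds))
    thresholds <- seq_len(K - 1L) - K / 2
  if (length(thresholds) != K - 1L || any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing of length K-1")
  draw <- function() {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("F", seq_len(p))))
    rel <- sort(sample.int(p, nRelevant))
    beta <- effectSize * (-1)^(seq_len(nRelevant) + 1)
    latent <- (if (nRelevant) drop(X[, rel, drop = FALSE] %*% beta)
               else rep(0, n)) + rlogis(n)
    y <- rowSums(outer(latent, thresholds, ">"))
    list(X = X, y = as.integer(y), rel = rel, beta = beta)
  }
  out <- .drawAllClasses(K, draw, seed)
  data <- MulticlassExperiment(out$X, out$y, "ordinal",
                               classOrder = paste0("S", seq_len(K)))
  truth <- new("GroundTruth",
               relevantFeatures = as.integer(out$rel),
               params = list(beta = out$beta, thresholds = thresholds,
                             effectSize = effectSize),
               graph = matrix(0, 0, 0), pcSet = as.integer(out$rel))
  list(data = data, truth = truth)
}

#' Generate a conditional-independence null triplet
#'
#' Calibration harness for the tests: `Z` (columns 2..zDim+1) is standard
#' normal, `X` (column 1) is `Z %*% w` plus unit Gaussian noise — so X is
#' marginally correlated with the outcome — and the outcome is drawn from a
#' multinomial-logit law over `Z` only. Hence X is independent of the
#' outcome given Z while being marginally dependent (for `w != 0`).
#'
#' @inheritParams genCategoricalDataset
#' @param zDim number of conditioning features (>= 1).
#' @param w weights of X on Z (recycled to length `zDim`, with alternating
#'   signs by default so that X loads on the same contrast of Z that drives
#'   the outcome and is therefore marginally dependent on it); `w = 0`
#'   makes X marginally independent of the outcome as well.
#' @param effectSize coefficient magnitude of the outcome on Z.
#' @return list with `data`, `truth`, and the designated indices `xIndex`
#'   (= 1) and `zIndices`.
#' @export
genNullTriplet <- function(n, K = 3L, zDim = 2L, seed = 1L,
                           w = 0.7 * (-1)^(seq_len(zDim) + 1),
                           effectSize = 1) {
  if (zDim < 1L) stop("zDim must be >= 1")
  w <- rep_len(w, zDim)
  draw <- function() {
    Z <- matrix(rnorm(n * zDim), n, zDim)
    x <- drop(Z %*% w) + rnorm(n)
    B <- matrix(0, K - 1L, zDim)
    for (k in seq_len(K - 1L))
      for (j in seq_len(zDim))
        B[k, j] <- effectSize * (-1)^(k + j)
    eta <- Z %*% t(B)
    full <- cbind(eta, 0)
    full <- full - apply(full, 1L, max)
    P <- exp(full) / rowSums(exp(full))
    X <- cbind(x, Z)
    colnames(X) <- c("X", paste0("Z", seq_len(zDim)))
    list(X = X, y = .sampleClasses(P), B = B)
  }
  out <- .drawAllClasses(K, draw, seed)
  data <- MulticlassExperiment(out$X, out$y, "nominal",
                               classOrder = paste0("C", seq_len(K) - 1L))
  truth <- new("GroundTruth",
               relevantFeatures = as.integer(1L + seq_len(zDim)),
               params = list(w = w, coefficients = out$B),
               graph = matrix(0, 0, 0),
               pcSet = as.integer(1L + seq_len(zDim)))
  list(data = data, truth = truth, xIndex = 1L,
       zIndices = 1L + seq_len(zDim))
}

#' Generate a random sparse Bayesian-network fixture with an exact oracle
#'
#' Builds a random sparse DAG (expected total degree about 3, mirroring the
#' sparsity believed to hold for gene regulatory networks) with a designated
#' outcome node, and returns an exact d-separation oracle obeying the
#' uniform test contract — p-value 0 when d-connected, 1 when d-separated —
#' plus the outcome's true parents-and-children set and a small sampled
#' dataset (linear-Gaussian among features, multinomial-logistic link into
#' the outcome, outcome codes fed numerically into its children).
#'
#' Parents-and-children selection without the symmetry correction is known
#' to admit false positives on graphs where some non-neighbour of the
#' outcome is d-separated from it only by conditioning sets that reach
#' outside the outcome's parents-and-children set (a spouse-side descendant
#' reached through a conditioned child collider). Such graphs are valid
#' Bayesian networks but not instances on which plain parents-children
#' recovery can be exact, so by default (`pcIdentifiable = TRUE`) the
#' generator rejects them: it checks, by exhaustive d-separation
#' enumeration, that every non-PC node is separable from the outcome by
#' some subset of the PC set of size at most `kMaxCheck`, and redraws
#' otherwise. Set `pcIdentifiable = FALSE` to sample the unconstrained
#' graph distribution.
#'
#' @param nNodes number of nodes (>= 3).
#' @param seed integer seed.
#' @param n samples to draw for the bundled dataset.
#' @param K classes of the outcome node.
#' @param outcomeNode optional node index to use as the outcome (default:
#'   drawn at random).
#' @param edgeDegree expected total degree of the DAG.
#' @param pcIdentifiable only emit graphs whose PC set is exactly
#'   recoverable by within-PC subset separation (default).
#' @param kMaxCheck conditioning-set size bound used by the
#'   identifiability check.
#' @return list with `graph` (adjacency over all nodes, row -> column),
#'   `outcomeNode`, `pcSet` (feature indices, i.e. positions among the
#'   non-outcome nodes), `oracle` (a test function
#'   `function(data, x, cond) -> CITResult`), `dsep` (predicate on feature
#'   indices), `data`, and `nodeNames`.
#' @export
genBNFixture <- function(nNodes, seed = 1L, n = 60L, K = 3L,
                         outcomeNode = NULL, edgeDegree = 3,
                         pcIdentifiable = TRUE, kMaxCheck = 3L) {
  if (nNodes < 3L) stop("nNodes must be >= 3")
  for (try in seq_len(100L)) {
    fx <- .genBNFixtureOnce(nNodes, .subSeed(seed, (try - 1L) * 7919L), n,
                            K, outcomeNode, edgeDegree)
    if (!pcIdentifiable ||
        .pcIsIdentifiable(fx$graph, fx$outcomeNode, kMaxCheck))
      return(fx)
  }
  stop("no PC-identifiable graph found in 100 draws")
}

# Every non-PC node must be d-separable from the outcome by some subset of
# the PC set (sizes 0..kMax), enumerated exhaustively.
.pcIsIdentifiable <- function(adj, yNode, kMax = 3L) {
  nN <- nrow(adj)
  pc <- which(adj[, yNode] > 0 | adj[yNode, ] > 0)
  for (v in setdiff(seq_len(nN), c(yNode, pc))) {
    sep <- FALSE
    for (s in 0:min(kMax, length(pc))) {
      for (Z in (if (s == 0L) list(integer(0))
                 else .subsetsOfSize(pc, s))) {
        if (.dsep(adj, v, yNode, as.integer(Z))) { sep <- TRUE; break }
      }
      if (sep) break
    }
    if (!sep) return(FALSE)
  }
  TRUE
}

.genBNFixtureOnce <- function(nNodes, seed, n, K, outcomeNode, edgeDegree) {
  out <- .withSeed(seed, {
    adj <- matrix(0L, nNodes, nNodes)
    for (i in 2:nNodes) {
      pe <- min(1, (edgeDegree / 2) / (i - 1))
      adj[seq_len(i - 1L), i] <- as.integer(runif(i - 1L) < pe)
    }
    yNode <- if (is.null(outcomeNode)) sample.int(nNodes, 1L)
             else as.integer(outcomeNode)
    wts <- matrix(runif(nNodes * nNodes, 0.5, 1.5) *
                    sign(runif(nNodes * nNodes) - 0.5), nNodes) * adj
    vals <- matrix(0, n, nNodes)
    for (v in seq_len(nNodes)) {
      pa <- which(adj[, v] > 0)
      base <- if (length(pa)) vals[, pa, drop = FALSE] %*% wts[pa, v]
              else rep(0, n)
      if (v == yNode) {
        B <- matrix(0, K - 1L, 1L)
        B[, 1L] <- (-1)^seq_len(K - 1L)
        eta <- cbind(as.numeric(base)) %*% t(B)
        full <- cbind(eta, 0)
        full <- full - apply(full, 1L, max)
        P <- exp(full) / rowSums(exp(full))
        vals[, v] <- .sampleClasses(P)
      } else {
        vals[, v] <- drop(base) + rnorm(n)
      }
    }
    list(adj = adj, yNode = yNode, vals = vals)
  })
  adj <- out$adj
  yNode <- out$yNode
  featNodes <- setdiff(seq_len(nNodes), yNode)
  nodeNames <- paste0("N", seq_len(nNodes))
  pcNodes <- which(adj[, yNode] > 0 | adj[yNode, ] > 0)
  pcSet <- match(pcNodes, featNodes)

  dsepFeature <- function(x, cond = integer(0)) {
    .dsep(adj, featNodes[x], yNode, featNodes[as.integer(cond)])
  }
  oracle <- function(data, x, cond = integer(0)) {
    sep <- dsepFeature(x, cond)
    CITResult(pValue = as.numeric(sep), statistic = as.numeric(!sep),
              df = 1L, assessable = TRUE, testName = "dsep_oracle",
              nUsed = NA_integer_)
  }

  y <- as.integer(out$vals[, yNode])
  if (!all((seq_len(K) - 1L) %in% y)) {
    miss <- setdiff(seq_len(K) - 1L, unique(y))
    y[seq_along(miss)] <- miss  # tiny-n fallback keeps the container valid
  }
  X <- out$vals[, featNodes, drop = FALSE]
  colnames(X) <- nodeNames[featNodes]
  data <- MulticlassExperiment(X, y, "nominal",
                               classOrder = paste0("C", seq_len(K) - 1L))
  list(graph = adj, outcomeNode = yNode, pcSet = as.integer(sort(pcSet)),
       oracle = oracle, dsep = dsepFeature, data = data,
       nodeNames = nodeNames)
}
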