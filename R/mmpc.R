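#' Configuration for the MMPC algorithm
#'
#' @param alpha significance threshold in (0, 1) for rejecting conditional
#'   independence. Comparative evaluations conventionally use 0.01 and 0.05.
#' @param kMax maximal conditioning-set size (>= 0). Values of 3 and 4 are
#'   conventional, reflecting the sparsity of gene regulatory networks.
#' @param test the conditional independence test: one of `"mc_cit"`,
#'   `"fisher_z"`, `"g2"`, or a function `function(data, x, cond)` returning
#'   a \linkS4class{CITResult} (e.g. a d-separation oracle from
#'   [genBNFixture()]).
#' @param cit a [citConfig()] with test options (df convention, G-squared
#'   power threshold).
#' @param maxCpc optional cap on the selected-set size (default unlimited).
#' @return a list of class `"MMPCConfig"`.
#' @export
mmpcConfig <- function(alpha = 0.05, kMax = 3L, test = "mc_cit",
                       cit = citConfig(), maxCpc = Inf) {
  stopifnot(alpha > 0, alpha < 1, kMax >= 0)
  if (is.character(test)) {
    test <- match.arg(test, c("mc_cit", "fisher_z", "g2"))
    cit$testKind <- test
  } else if (!is.function(test)) {
    stop("'test' must be a test name or a function")
  }
  structure(list(alpha = alpha, kMax = as.integer(kMax), test = test,
                 cit = cit, maxCpc = maxCpc),
            class = "MMPCConfig")
}

# Shared evaluation context: plain-matrix fast paths for the built-in tests,
# a memo cache keyed by (feature, unordered conditioning set), and a counter
# of tests actually performed.
.mmpcContext <- function(data, config) {
  fm <- featureMatrix(data)
  y <- outcomeCodes(data)
  K <- nClasses(data)
  kind <- outcomeKind(data)
  ctx <- new.env(parent = emptyenv())
  ctx$p <- ncol(fm)
  ctx$cache <- new.env(parent = emptyenv())
  ctx$nTests <- 0L

  test <- config$test
  if (is.function(test)) {
    raw <- function(x, cond) {
      r <- test(data, x, cond)
      list(p = r@pValue, stat = r@statistic, assessable = r@assessable)
    }
  } else if (test == "mc_cit") {
    dfTest <- if (config$cit$dfConvention == "single_df") 1L
              else if (kind == "ordinal") 1L else K - 1L
    altCache <- new.env(parent = emptyenv())
    if (kind == "ordinal") {
      raw <- function(x, cond) {
        key <- .condKey(cond)
        alt <- altCache[[key]]
        if (is.null(alt)) {
          alt <- .olFitRaw(fm, y, K, cond)
          altCache[[key]] <- alt
        }
        full <- .olFitRaw(fm, y, K, c(cond, x))
        stat <- max(0, 2 * (full$loglik - alt$loglik))
        if (!full$converged && !alt$converged)
          return(list(p = 1, stat = stat, assessable = FALSE))
        list(p = pchisq(stat, dfTest, lower.tail = FALSE), stat = stat,
             assessable = TRUE)
      }
    } else {
      # nominal: C++ Newton fits, warm-started from the nested model
      yInt <- as.integer(y)
      raw <- function(x, cond) {
        key <- .condKey(cond)
        alt <- altCache[[key]]
        if (is.null(alt)) {
          alt <- if (length(cond))
            cpp_fit_mnl_idx(fm, yInt, K, as.integer(cond) - 1L)
          else {
            counts <- tabulate(yInt + 1L, nbins = K)
            ph <- counts / length(yInt)
            list(coefficients = matrix(log(ph[-K] / ph[K]), nrow = 1L),
                 loglik = sum(counts[counts > 0] * log(ph[counts > 0])),
                 converged = TRUE)
          }
          altCache[[key]] <- alt
        }
        full <- cpp_fit_mnl_idx(fm, yInt, K,
                                as.integer(c(cond, x)) - 1L,
                                warm = alt$coefficients)
        stat <- max(0, 2 * (full$loglik - alt$loglik))
        if (!full$converged && !alt$converged)
          return(list(p = 1, stat = stat, assessable = FALSE))
        list(p = pchisq(stat, dfTest, lower.tail = FALSE), stat = stat,
             assessable = TRUE)
      }
    }
  } else if (test == "fisher_z") {
    yNum <- as.numeric(y)
    raw <- function(x, cond) {
      r <- .fisherZCore(fm, yNum, x, cond)
      list(p = r@pValue, stat = r@statistic, assessable = r@assessable)
    }
  } else {  # g2
    disc <- apply(fm, 2L, discretizeThreeBins)
    hpa <- config$cit$g2Hpa
    raw <- function(x, cond) {
      r <- .g2Core(fm, y, x, cond, hpa, disc = disc)
      list(p = r@pValue, stat = r@statistic, assessable = r@assessable)
    }
  }

  # zkey: precomputed .condKey(cond), shared across candidates in a sweep
  ctx$test <- function(x, cond, zkey = .condKey(cond)) {
    key <- paste0(x, "|", zkey)
    res <- ctx$cache[[key]]
    if (is.null(res)) {
      res <- raw(x, cond)
      ctx$nTests <- ctx$nTests + 1L
      ctx$cache[[key]] <- res
    }
    res
  }
  ctx
}

# Enumerate conditioning subsets of `cpc` (|Z| <= kMax, empty set first,
# increasing size, lexicographic within size) and track the maximum p-value
# over assessable tests. Non-assessable tests are skipped: the
# procedure forgoes tests whose expected power is too low rather than
# letting them decide. A candidate none of whose tests are assessable gets
# pMax = 1 (its association cannot be assessed, so it is never selected).
.minAssocCore <- function(ctx, x, cpc, kMax, alpha = NULL,
                          earlyExit = FALSE) {
  pool <- sort(as.integer(cpc))
  pMax <- -Inf
  witness <- integer(0)
  statAt <- NA_real_
  anyAssess <- FALSE
  for (s in 0:min(kMax, length(pool))) {
    sets <- if (s == 0L) list(integer(0))
            else .subsetsOfSize(pool, s)
    for (Z in sets) {
      res <- ctx$test(x, as.integer(Z))
      if (!res$assessable) next
      anyAssess <- TRUE
      if (res$p > pMax) {
        pMax <- res$p
        witness <- as.integer(Z)
        statAt <- res$stat
      }
      if (earlyExit && !is.null(alpha) && pMax > alpha)
        return(list(pMax = pMax, witness = witness, stat = statAt,
                    assessable = TRUE))
    }
  }
  if (!anyAssess)
    return(list(pMax = 1, witness = integer(0), stat = NA_real_,
                assessable = FALSE))
  list(pMax = pMax, witness = witness, stat = statAt, assessable = TRUE)
}

#' Minimum association of a candidate with the outcome
#'
#' The max-min heuristic's inner quantity: the maximum p-value of
#' `test(x, Y | Z)` over all conditioning subsets `Z` of the current
#' candidate set (`|Z| <= kMax`, always including the empty set), together
#' with the subset attaining it. A small value means no examined subset can
#' explain the association away.
#'
#' @inheritParams citTest
#' @param cpc integer indices of the current candidate parents-children set.
#' @param config an [mmpcConfig()].
#' @return list with elements `pMax`, `witness` (the attaining subset),
#'   `stat` (test statistic at the witness), and `assessable`.
#' @export
minAssoc <- function(data, x, cpc = integer(0), config = mmpcConfig()) {
  if (x %in% cpc) stop("x must not be part of the candidate set")
  ctx <- .mmpcContext(data, config)
  .minAssocCore(ctx, as.integer(x), cpc, config$kMax)
}

# larger statistic wins ties on pMax; remaining ties go to the lower index
.betterCandidate <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$pMax != b$pMax) return(a$pMax < b$pMax)
  sa <- if (is.na(a$stat)) -Inf else a$stat
  sb <- if (is.na(b$stat)) -Inf else b$stat
  if (sa != sb) return(sa > sb)
  a$x < b$x
}

.traceRow <- function(phase, feature, condSet, pValue, action) {
  data.frame(phase = phase, feature = feature,
             condSet = .condKey(condSet), pValue = pValue, action = action,
             stringsAsFactors = FALSE)
}

# The per-candidate maximum p-value is non-decreasing as the CPC grows, so
# each sweep only needs the subsets containing the newest CPC member; the
# running maximum over earlier subsets is carried in the candidate state.
# Result-identical to full re-enumeration (which minAssoc() still does).
.mmpcForwardCore <- function(ctx, config) {
  p <- ctx$p
  remaining <- seq_len(p)
  cpc <- integer(0)
  trace <- list()
  pMaxV <- rep(-Inf, p)
  statV <- rep(NA_real_, p)
  witV <- vector("list", p)
  assessV <- logical(p)
  newMember <- NULL
  repeat {
    if (!length(remaining) || length(cpc) >= config$maxCpc) break
    if (is.null(newMember)) {
      sweepSets <- list(integer(0))
    } else if (config$kMax < 1L) {
      sweepSets <- list()  # no conditioning allowed beyond the empty set
    } else {
      base <- sort(setdiff(cpc, newMember))
      sweepSets <- list()
      for (s in 0:min(config$kMax - 1L, length(base)))
        sweepSets <- c(sweepSets,
                       lapply(if (s == 0L) list(integer(0))
                              else .subsetsOfSize(base, s),
                              function(Z) c(Z, newMember)))
    }
    sweepKeys <- vapply(sweepSets, .condKey, character(1))
    best <- NULL
    discard <- integer(0)
    for (x in remaining) {
      doomed <- FALSE
      for (si in seq_along(sweepSets)) {
        Z <- sweepSets[[si]]
        res <- ctx$test(x, Z, sweepKeys[[si]])
        if (!res$assessable) next
        assessV[x] <- TRUE
        if (res$p > pMaxV[x]) {
          pMaxV[x] <- res$p
          statV[x] <- res$stat
          witV[[x]] <- as.integer(Z)
        }
        if (pMaxV[x] > config$alpha) { doomed <- TRUE; break }
      }
      if (doomed || !assessV[x]) {
        discard <- c(discard, x)
        if (doomed)
          trace[[length(trace) + 1L]] <-
            .traceRow("forward", x, witV[[x]], pMaxV[x], "rejected")
      } else {
        cand <- list(x = x, pMax = pMaxV[x], stat = statV[x],
                     witness = witV[[x]])
        if (.betterCandidate(cand, best)) best <- cand
      }
    }
    remaining <- setdiff(remaining, discard)
    if (is.null(best)) break
    cpc <- c(cpc, best$x)
    remaining <- setdiff(remaining, best$x)
    newMember <- best$x
    trace[[length(trace) + 1L]] <-
      .traceRow("forward", best$x, best$witness, best$pMax, "added")
  }
  list(cpc = cpc, trace = trace)
}

.mmpcBackwardCore <- function(ctx, cpc, config) {
  trace <- list()
  for (x in rev(cpc)) {
    others <- setdiff(cpc, x)
    pool <- sort(others)
    removed <- FALSE
    for (s in 0:min(config$kMax, length(pool))) {
      sets <- if (s == 0L) list(integer(0))
              else .subsetsOfSize(pool, s)
      for (Z in sets) {
        res <- ctx$test(x, as.integer(Z))
        if (res$assessable && res$p > config$alpha) {
          trace[[length(trace) + 1L]] <-
            .traceRow("backward", x, Z, res$p, "removed")
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (removed) cpc <- setdiff(cpc, x)
  }
  list(cpc = cpc, trace = trace)
}

#' Forward (inclusion) phase of MMPC
#'
#' Repeatedly computes every remaining candidate's minimum association
#' ([minAssoc()]) against the current candidate set and admits the candidate
#' with the smallest maximum p-value (the max-min step), stopping when that
#' p-value exceeds `alpha`. Candidates whose maximum p-value ever exceeds
#' `alpha` are permanently discarded (the standard MMPC pruning). Ties are
#' broken toward the larger test statistic, then the lower feature index.
#'
#' @inheritParams minAssoc
#' @return list with `cpc` (selected indices, insertion order) and `trace`.
#' @export
mmpcForward <- function(data, config = mmpcConfig()) {
  ctx <- .mmpcContext(data, config)
  fw <- .mmpcForwardCore(ctx, config)
  empty <- .traceRow("forward", NA_integer_, integer(0), NA_real_,
                     "added")[0, ]
  list(cpc = fw$cpc, trace = do.call(rbind, c(fw$trace, list(empty))))
}

#' Backward (conditioning) phase of MMPC
#'
#' Re-tests every member of the candidate set against all conditioning
#' subsets of the other members (`|Z| <= kMax`); a member is removed as soon
#' as some subset fails to refute independence (p > alpha). Removals are
#' processed in reverse insertion order and are reflected in subsequent
#' subset enumeration.
#'
#' @inheritParams minAssoc
#' @return integer vector: the pruned candidate set.
#' @export
mmpcBackward <- function(data, cpc, config = mmpcConfig()) {
  ctx <- .mmpcContext(data, config)
  .mmpcBackwardCore(ctx, as.integer(cpc), config)$cpc
}

#' Max-Min Parents-and-Children feature selection
#'
#' Runs the MMPC constraint-based selection algorithm against the outcome of
#' `data`: a forward max-min inclusion phase followed by a backward
#' conditioning phase (see [mmpcForward()] and [mmpcBackward()]). Under a
#' faithful Bayesian-network distribution and error-free tests the result is
#' the outcome's parents-and-children set — the core of its Markov blanket
#' and, in practice, a minimal highly predictive signature.
#'
#' The run is deterministic given `data` and `config`; all test results are
#' memoised, so repeated queries of the same (feature, conditioning set)
#' pair are evaluated once.
#'
#' @inheritParams minAssoc
#' @return an \linkS4class{MMPCResult}.
#' @examples
#' sim <- genCategoricalDataset(n = 200, p = 30, K = 3, nRelevant = 3,
#'                              effectSize = 1.2, seed = 11)
#' res <- mmpc(sim$data, mmpcConfig(alpha = 0.05, kMax = 3))
#' selectedFeatures(res)
#' sim$truth@relevantFeatures
#' @export
mmpc <- function(data, config = mmpcConfig()) {
  ctx <- .mmpcContext(data, config)
  fw <- .mmpcForwardCore(ctx, config)
  bw <- .mmpcBackwardCore(ctx, fw$cpc, config)
  trace <- do.call(rbind, c(fw$trace, bw$trace))
  if (is.null(trace))
    trace <- .traceRow("forward", NA_integer_, integer(0), NA_real_,
                       "added")[0, ]
  fnames <- rownames(assay(data))
  new("MMPCResult",
      selected = as.integer(bw$cpc),
      selectedNames = fnames[bw$cpc],
      trace = trace,
      testsPerformed = ctx$nTests,
      config = list(alpha = config$alpha, kMax = config$kMax,
                    test = if (is.function(config$test)) "custom"
                           else config$test,
                    dfConvention = config$cit$dfConvention,
                    g2Hpa = config$cit$g2Hpa))
}

#' @rdname mccit-generics
#' @export
setMethod("selectedFeatures", "MMPCResult", function(object)
  object@selected)

#' @rdname mccit-generics
#' @export
setMethod("mmpcTrace", "MMPCResult", function(object) object@trace)

#' @rdname mccit-generics
#' @export
setMethod("testsPerformed", "MMPCResult", function(object)
  object@testsPerformed)

#' @export
setMethod("show", "MMPCResult", function(object) {
  cat("MMPCResult: ", length(object@selected), " feature(s) selected (",
      object@config$test, ", alpha = ", object@config$alpha,
      ", k-max = ", object@config$kMax, ")\n", sep = "")
  if (length(object@selected))
    cat("  ", paste0(object@selectedNames, " [", object@selected, "]",
                     collapse = ", "), "\n", sep = "")
  cat("  tests performed:", object@testsPerformed, "\n")
})

#' Serialize an MMPC result to JSON
#'
#' @param result an \linkS4class{MMPCResult}.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
mmpcResultJSON <- function(result, path = NULL) {
  obj <- list(selected = result@selected,
              selectedNames = result@selectedNames,
              testsPerformed = result@testsPerformed,
              config = result@config,
              trace = result@trace)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
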