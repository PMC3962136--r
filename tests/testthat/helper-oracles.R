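# Independent oracles used across the suite. These deliberately avoid the
# package's fitting code paths: plain R log-likelihoods maximised with a
# generic optimizer, residual regressions for partial correlations, and
# exhaustive path enumeration for d-separation.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Multinomial-logit log-likelihood (baseline = last class) for coefficient
# vector theta laid out column-wise per non-baseline class.
mnlNegLogLik <- function(theta, X1, y, K) {
  d <- ncol(X1)
  B <- matrix(theta, d, K - 1L)
  eta <- cbind(X1 %*% B, 0)
  lse <- log(rowSums(exp(eta - apply(eta, 1, max)))) + apply(eta, 1, max)
  -sum(eta[cbind(seq_along(y), y + 1L)] - lse)
}

mnlNegGrad <- function(theta, X1, y, K) {
  d <- ncol(X1)
  B <- matrix(theta, d, K - 1L)
  eta <- cbind(X1 %*% B, 0)
  P <- exp(eta - apply(eta, 1, max))
  P <- P / rowSums(P)
  Yind <- outer(y, 0:(K - 2L), "==") + 0
  -as.numeric(crossprod(X1, Yind - P[, seq_len(K - 1L), drop = FALSE]))
}

# Brute-force maximised multinomial log-likelihood by a generic optimizer.
bruteMnlLogLik <- function(X, y, K) {
  X1 <- cbind(1, X)
  d <- ncol(X1) * (K - 1L)
  opt <- optim(rep(0, d), mnlNegLogLik, mnlNegGrad, X1 = X1, y = y, K = K,
               method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  -opt$value
}

# Partial correlation of a and b given the columns of Z, via residuals of
# the two ordinary regressions.
partialCorOracle <- function(a, b, Z) {
  if (is.null(Z) || NCOL(Z) == 0) return(cor(a, b))
  ra <- residuals(lm(a ~ Z))
  rb <- residuals(lm(b ~ Z))
  cor(ra, rb)
}

# d-separation by exhaustive enumeration of simple undirected paths: a path
# is active given Z iff every collider on it has a descendant in Z and no
# non-collider lies in Z.
bruteDsep <- function(adj, x, y, Z) {
  nN <- nrow(adj)
  und <- (adj + t(adj)) > 0
  desc <- function(v) {
    out <- logical(nN); stack <- v
    while (length(stack)) {
      w <- stack[[1]]; stack <- stack[-1]
      ch <- which(adj[w, ] > 0)
      newc <- ch[!out[ch]]; out[newc] <- TRUE; stack <- c(stack, newc)
    }
    which(out)
  }
  active <- function(path) {
    if (length(path) <= 2) return(TRUE)
    for (i in 2:(length(path) - 1)) {
      v <- path[i]
      collider <- adj[path[i - 1], v] > 0 && adj[path[i + 1], v] > 0
      if (collider) {
        if (!(v %in% Z) && !any(desc(v) %in% Z)) return(FALSE)
      } else {
        if (v %in% Z) return(FALSE)
      }
    }
    TRUE
  }
  found <- FALSE
  dfs <- function(path) {
    if (found) return()
    v <- path[length(path)]
    if (v == y) { if (active(path)) found <<- TRUE; return() }
    for (w in which(und[v, ])) {
      if (!(w %in% path)) dfs(c(path, w))
    }
  }
  dfs(x)
  !found
}

# Features whose sample correlation with an integer encoding is fixed
# exactly, for closed-form Fisher Z checks.
makeExactCorrData <- function(n0, n1, r) {
  yc <- c(rep(0, n0), rep(1, n1))
  ys <- (yc - mean(yc)) / sqrt(sum((yc - mean(yc))^2))
  e <- rnorm(n0 + n1)
  e <- e - mean(e) - ys * sum(ys * (e - mean(e)))
  e <- e / sqrt(sum(e^2))
  x <- r * ys + sqrt(1 - r^2) * e
  list(x = x, y = as.integer(yc))
}

# Small labelled dataset straight from matrices, bypassing generators.
makeDataset <- function(X, y, kind = "nominal") {
  MulticlassExperiment(X, as.integer(y), kind,
                       classOrder = paste0("C", seq_len(max(y) + 1L) - 1L))
}
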