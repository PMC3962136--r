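# Run an expression under a fixed RNG state, restoring the caller's state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(expr)
}

# Derive a reproducible sub-seed that stays inside the 32-bit integer range.
.subSeed <- function(seed, i, stride = 1009L) {
  as.integer((as.double(seed) * stride + i) %% (.Machine$integer.max - 1L)) + 1L
}

# Keep a design matrix full rank: returns the indices (within `cols`) of
# regressor columns retained after dropping zero-variance and linearly
# dependent columns (the intercept is always kept).
.keepFullRank <- function(X) {
  q <- ncol(X)
  if (q == 0L) return(integer(0))
  keep <- which(apply(X, 2L, function(v) {
    r <- range(v)
    (r[2] - r[1]) > 1e-12
  }))
  if (!length(keep)) return(integer(0))
  qrd <- qr(cbind(1, X[, keep, drop = FALSE]))
  used <- qrd$pivot[seq_len(qrd$rank)]
  keep[sort(used[used > 1L] - 1L)]
}

# Format a conditioning set for trace records and cache keys ("()" for the
# empty set, so the key is never an empty string).
.condKey <- function(z) {
  if (!length(z)) return("()")
  paste(sort(as.integer(z)), collapse = ",")
}

# All size-s subsets of an index pool, lexicographic; combn() would expand a
# singleton pool into seq_len(pool).
.subsetsOfSize <- function(pool, s) {
  if (length(pool) == 1L) return(if (s == 1L) list(pool) else list())
  asplit(combn(pool, s), 2L)
}
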