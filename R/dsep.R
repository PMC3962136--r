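# d-separation on a DAG given as an adjacency matrix (adj[i, j] = 1 means
# i -> j), via the standard reachability (Bayes-ball) procedure: y is
# d-separated from x given Z iff no active trail reaches it.
.ancestorsOf <- function(adj, nodes) {
  anc <- logical(nrow(adj))
  stack <- nodes
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    pa <- which(adj[, v] > 0)
    newp <- pa[!anc[pa]]
    anc[newp] <- TRUE
    stack <- c(stack, newp)
  }
  anc
}

.dsep <- function(adj, x, y, Z) {
  if (x == y) return(FALSE)
  if (y %in% Z || x %in% Z) return(TRUE)
  nN <- nrow(adj)
  inZ <- logical(nN)
  inZ[Z] <- TRUE
  # ancestors of Z (inclusive): conditioning opens colliders whose
  # descendants are observed
  ancZ <- .ancestorsOf(adj, as.list(Z))
  ancZ[Z] <- TRUE

  visited <- matrix(FALSE, nN, 2L)  # columns: entered going up / going down
  queue <- list(c(x, 1L))           # leave x towards its parents ("up")
  queue[[2L]] <- c(x, 2L)           # and towards its children ("down")
  while (length(queue)) {
    el <- queue[[1L]]
    queue <- queue[-1L]
    v <- el[1L]; dir <- el[2L]
    if (visited[v, dir]) next
    visited[v, dir] <- TRUE
    if (dir == 1L && !inZ[v]) {
      # trail arrives from a child: may continue to parents and children
      for (p in which(adj[, v] > 0)) queue[[length(queue) + 1L]] <- c(p, 1L)
      for (ch in which(adj[v, ] > 0)) queue[[length(queue) + 1L]] <- c(ch, 2L)
    } else if (dir == 2L) {
      # trail arrives from a parent
      if (!inZ[v])
        for (ch in which(adj[v, ] > 0))
          queue[[length(queue) + 1L]] <- c(ch, 2L)
      if (ancZ[v])  # collider open when v has an observed descendant
        for (p in which(adj[, v] > 0))
          queue[[length(queue) + 1L]] <- c(p, 1L)
    }
  }
  reached <- visited[, 1L] | visited[, 2L]
  reached[x] <- FALSE
  !reached[y]
}
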