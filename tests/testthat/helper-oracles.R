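# Independent oracles used to validate the analytic implementations.

# First-visit probability of every node for the walk from `start`, by
# exhaustive enumeration of all walks of length <= steps (probability-
# weighted depth-first traversal; independent of the matrix propagation in
# the package).
enumVisitProbs <- function(net, start, steps) {
  N <- nNodes(net)
  a <- arcs(net)
  outn <- lapply(seq_len(N) - 1L, function(u) a[a[, 1L] == u, 2L])
  q <- numeric(N)
  names(q) <- seq_len(N) - 1L
  # probability-weighted DFS; each node is credited at its first visit only
  recurseStep <- function(node, prob, depth, visited) {
    if (!(node %in% visited)) {
      q[as.character(node)] <<- q[as.character(node)] + prob
      visited <- c(visited, node)
    }
    if (depth == steps) return(invisible(NULL))
    nb <- outn[[node + 1L]]
    if (length(nb) == 0L) return(invisible(NULL))
    for (v in nb) recurseStep(v, prob / length(nb), depth + 1L, visited)
  }
  recurseStep(start, 1, 0L, integer(0))
  q
}

# eating profile from the enumeration oracle (inclusion-exclusion across
# hunters, like the model definition but with oracle walk probabilities)
enumEatingProbs <- function(net, ph, F) {
  qs <- vapply(hunters(net), enumVisitProbs, numeric(nNodes(net)),
               net = net, steps = F - 1L)
  1 - apply(1 - ph * qs, 1L, prod)
}

# exact pmf of the number of maximal runs of >= k successes in n trials,
# by exhaustive enumeration of all 2^n outcome sequences (success = no
# food, probability q)
enumRunCountPmf <- function(n, k, q) {
  gmax <- (n + 1L) %/% (k + 1L)
  pmf <- numeric(gmax + 1L)
  for (mask in 0:(2^n - 1L)) {
    bits <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))))
    r <- rle(bits)
    g <- sum(r$values & r$lengths >= k)
    pmf[g + 1L] <- pmf[g + 1L] + prod(ifelse(bits, q, 1 - q))
  }
  pmf
}

# quadratic pairwise non-dominated filter (mask of kept rows)
pairwiseNondominated <- function(m) {
  n <- nrow(m)
  vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && all(m[j, ] <= m[i, ]) && any(m[j, ] < m[i, ])
    }, logical(1L)))
  }, logical(1L))
}

# all set partitions of 1..n (Bell-number enumeration) as membership vectors
allPartitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPartitions(n - 1L)) {
    for (b in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, b)
  }
  out
}

# 2-D hypervolume (minimization) dominated by `front` up to reference `ref`
hypervolume2d <- function(front, ref) {
  f <- front[front[, 1L] <= ref[1L] & front[, 2L] <= ref[2L], , drop = FALSE]
  if (nrow(f) == 0L) return(0)
  f <- f[order(f[, 1L], f[, 2L]), , drop = FALSE]
  hv <- 0
  prev2 <- ref[2L]
  for (i in seq_len(nrow(f))) {
    if (f[i, 2L] < prev2) {
      hv <- hv + (ref[1L] - f[i, 1L]) * (prev2 - f[i, 2L])
      prev2 <- f[i, 2L]
    }
  }
  hv
}
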