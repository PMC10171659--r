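# Numeric core of the sharing protocol. All functions here operate on the
# light-weight representation (.asCore): 0/1 adjacency matrix with 1-based
# indices. The S4 methods below are thin wrappers.

# row-stochastic transition matrix of the sharing walk; nodes with no
# out-neighbour hold the walk (the remaining food is lost there)
.transition <- function(adj) {
  outdeg <- rowSums(adj)
  Tm <- adj / pmax(outdeg, 1)
  stuck <- which(outdeg == 0)
  if (length(stuck)) Tm[cbind(stuck, stuck)] <- 1
  Tm
}

# P(walk started at h visits v within `steps` transfer steps), exactly, by
# making v absorbing and propagating the step-t occupation distribution
.visitCore <- function(adj, huntersIdx, steps) {
  N <- nrow(adj)
  q <- matrix(0, length(huntersIdx), N,
              dimnames = list(huntersIdx - 1L, seq_len(N) - 1L))
  Tm <- .transition(adj)
  for (i in seq_along(huntersIdx)) {
    h <- huntersIdx[i]
    q[i, h] <- 1  # the hunter eats its own prey at step 0
    if (steps < 1L) next
    for (v in seq_len(N)) {
      if (v == h) next
      m <- numeric(N)
      m[h] <- 1
      acc <- 0
      for (t in seq_len(steps)) {
        m <- as.vector(m %*% Tm)
        acc <- acc + m[v]
        m[v] <- 0  # first visit only: absorb
        if (acc >= 1 - 1e-15 || sum(m) < 1e-15) break
      }
      q[i, v] <- acc
    }
  }
  q
}

# per-node probability of eating: independent Bernoulli(ph) hunts combined
# by inclusion-exclusion, pe(v) = 1 - prod_h (1 - ph * q[h, v])
.peCore <- function(adj, huntersIdx, ph, F) {
  q <- .visitCore(adj, huntersIdx, F - 1L)
  1 - apply(1 - ph * q, 2L, prod)
}

#' First-visit probabilities of the sharing walk
#'
#' For every hunter `h` and node `v`, the probability that the food package
#' started at `h` reaches `v` within `F - 1` transfer steps. The walk moves
#' to a uniformly chosen out-neighbour at each step (halting early at nodes
#' with no out-neighbour), every receipt consumes one unit of food (revisits
#' included), and only the first visit matters: the probability of eating
#' counts distinct supply events, not quantity. Nodes at directed distance
#' greater than `F - 1` from every hunter can never receive food.
#'
#' @param net a [SharingNetwork-class].
#' @param params a [ModelParams-class]; only `F` is used.
#' @return A numeric matrix with one row per hunter and one column per node,
#'   dimnames carrying the 0-based ids; entries in `[0, 1]`, and 1 on each
#'   hunter's own column.
#' @examples
#' q <- visitProbabilities(fixtureSevenNode(), ModelParams(0.2, 4))
#' q["4", "5"]  # node 5 is surely fed by hunter 4
#' @rdname visitProbabilities
#' @export
setMethod("visitProbabilities", c("SharingNetwork", "ModelParams"),
  function(net, params) {
    validObject(net)
    core <- .asCore(net)
    .visitCore(core$adj, core$hunters, params@F - 1L)
  })

#' Exact probabilities of eating
#'
#' The probability that each node receives food at least once in a single
#' time step. Hunters hunt independently with probability `ph`; a node fed
#' by several hunters' walks combines them by inclusion-exclusion:
#' `pe(v) = 1 - prod_h (1 - ph * q[h, v])` where `q` are the first-visit
#' walk probabilities of [visitProbabilities()].
#'
#' @param net a [SharingNetwork-class].
#' @param params a [ModelParams-class].
#' @return Named numeric vector of length `nNodes(net)` (names are 0-based
#'   node ids): the eating profile.
#' @examples
#' eatingProbabilities(fixtureSevenNode(), ModelParams(0.2, 4))
#' @rdname eatingProbabilities
#' @export
setMethod("eatingProbabilities", c("SharingNetwork", "ModelParams"),
  function(net, params) {
    validObject(net)
    core <- .asCore(net)
    pe <- .peCore(core$adj, core$hunters, params@ph, params@F)
    names(pe) <- seq_len(net@nNodes) - 1L
    pe
  })

#' Monte-Carlo simulation of the sharing protocol
#'
#' Simulates the literal protocol: in each of `nEvents` independent time
#' steps every hunter hunts with probability `ph`; a successful hunt spawns
#' `F` units of food that travel node to node, the holder eating one unit
#' per receipt and passing the remainder to a uniformly chosen out-neighbour
#' until the units are exhausted or the holder has no out-neighbour. The
#' empirical probability of eating is the fraction of events in which each
#' node was fed at least once.
#'
#' @param net a [SharingNetwork-class].
#' @param params a [ModelParams-class].
#' @param nEvents positive integer, number of simulated time steps.
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @return Named numeric vector: the empirical eating profile.
#' @examples
#' simulateEvents(fixtureHunterStar(), ModelParams(0.08, 4), 1e4, seed = 7)
#' @rdname simulateEvents
#' @export
setMethod("simulateEvents", c("SharingNetwork", "ModelParams"),
  function(net, params, nEvents, seed = 1L) {
    nEvents <- as.integer(nEvents)
    if (is.na(nEvents) || nEvents < 1L)
      stop("invalid argument: 'nEvents' must be a positive integer")
    validObject(net)
    core <- .asCore(net)
    adj <- core$adj
    N <- nrow(adj)
    outn <- lapply(seq_len(N), function(u) which(adj[u, ] == 1L))
    fed <- matrix(FALSE, nEvents, N)
    steps <- params@F - 1L
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    for (h in core$hunters) {
      hunt <- runif(nEvents) < params@ph
      ev <- which(hunt)
      if (!length(ev)) next
      fed[ev, h] <- TRUE
      pos <- rep.int(h, length(ev))  # walk positions, advanced jointly
      alive <- seq_along(ev)
      for (t in seq_len(steps)) {
        if (!length(alive)) break
        cur <- pos[alive]
        nxt <- integer(length(cur))
        for (u in unique(cur)) {
          sel <- which(cur == u)
          nb <- outn[[u]]
          nxt[sel] <- if (length(nb) == 0L) 0L
                      else if (length(nb) == 1L) nb
                      else nb[sample.int(length(nb), length(sel),
                                         replace = TRUE)]
        }
        halted <- nxt == 0L
        keep <- alive[!halted]
        pos[keep] <- nxt[!halted]
        fed[cbind(ev[keep], pos[keep])] <- TRUE
        alive <- keep
      }
    }
    pe <- colMeans(fed)
    names(pe) <- seq_len(N) - 1L
    pe
  })
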