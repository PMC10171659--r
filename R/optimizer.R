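# Evolutionary search over sharing networks. The search operates internally
# on 0/1 adjacency matrices with a fixed hunter set (nodes 1..nh in 1-based
# indexing); S4 SharingNetwork objects are materialized only at the
# boundaries.

# all ordered node pairs (u, v), u != v, as a 2-column matrix
.orderedPairs <- function(N) {
  u <- rep(seq_len(N), each = N)
  v <- rep.int(seq_len(N), N)
  keep <- u != v
  cbind(u[keep], v[keep])
}

.toggle <- function(adj, u, v) {
  adj[u, v] <- 1L - adj[u, v]
  adj
}

# single-criterion evaluation on the core representation
.evalCrit <- function(adj, huntersIdx, params, criterion) {
  pe <- .peCore(adj, huntersIdx, params@ph, params@F)
  if (criterion == "wef") wefCost(pe) else rvCost(pe, params@n, params@k)
}

.evalCosts <- function(adj, huntersIdx, params) {
  pe <- .peCore(adj, huntersIdx, params@ph, params@F)
  c(rv = rvCost(pe, params@n, params@k), wef = wefCost(pe))
}

#' Mutate a network by one arc toggle
#'
#' The move set of the optimization: a uniformly chosen ordered pair
#' `(u, v)`, `u != v`, has its arc toggled (added if absent, removed if
#' present). The hunter set is unchanged and the result is always loop-free
#' and simple. Uses the current RNG stream; seed externally for
#' reproducibility.
#'
#' @param net a [SharingNetwork-class].
#' @return A mutated [SharingNetwork-class].
#' @examples
#' set.seed(1)
#' mutateNetwork(fixtureHunterStar())
#' @export
mutateNetwork <- function(net) {
  core <- .asCore(net)
  pairs <- .orderedPairs(net@nNodes)
  i <- sample.int(nrow(pairs), 1L)
  .fromCore(.toggle(core$adj, pairs[i, 1L], pairs[i, 2L]), core$hunters)
}

# nodes reachable from any hunter within `depth` directed steps (including
# the hunters themselves at depth 0)
.reachableWithin <- function(adj, huntersIdx, depth) {
  reach <- logical(nrow(adj))
  reach[huntersIdx] <- TRUE
  frontier <- huntersIdx
  d <- 0L
  while (d < depth && length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0L & !reach)
    reach[nxt] <- TRUE
    frontier <- nxt
    d <- d + 1L
  }
  reach
}

.reduceAdj <- function(adj, huntersIdx, F) {
  if (F <= 1L) return(adj * 0L)  # walks have length 0: no arc carries food
  # an arc can carry food only if its source can hold >= 2 units, i.e. the
  # source is a hunter or at directed distance <= F - 2 from one
  feasible <- .reachableWithin(adj, huntersIdx, F - 2L)
  adj * as.integer(feasible)
}

#' Cost-preserving canonical reduction
#'
#' Removes every arc whose source is neither a hunter nor reachable from a
#' hunter within `F - 2` steps: such a source can never hold more than one
#' unit of food, so the arc lies on no feasible food walk and contributes
#' nothing to either criterion. The node set is unchanged and
#' [costVector()] is identical before and after. This reduction (plus
#' deduplication on the eating profile) is the package's stand-in for
#' quotienting networks by cost-preserving equivalence.
#'
#' @param net a [SharingNetwork-class].
#' @param params a [ModelParams-class]; only `F` matters.
#' @return A reduced [SharingNetwork-class].
#' @examples
#' canonicalReduce(fixtureSevenNode(), ModelParams(0.2, 5))  # unchanged
#' @rdname canonicalReduce
#' @export
setMethod("canonicalReduce", c("SharingNetwork", "ModelParams"),
  function(net, params) {
    core <- .asCore(net)
    .fromCore(.reduceAdj(core$adj, core$hunters, params@F), core$hunters)
  })

# deduplication key: eating profile split by role (sorted within role) plus
# the rounded cost pair, on the canonically reduced network
.signature <- function(adj, huntersIdx, params) {
  radj <- .reduceAdj(adj, huntersIdx, params@F)
  pe <- .peCore(radj, huntersIdx, params@ph, params@F)
  costs <- c(rvCost(pe, params@n, params@k), wefCost(pe))
  paste(
    paste(sprintf("%.12f", sort(pe[huntersIdx])), collapse = ","),
    paste(sprintf("%.12f", sort(pe[-huntersIdx])), collapse = ","),
    paste(sprintf("%.9f", costs), collapse = ","),
    sep = "|")
}

#' Test whether a network is a single-arc local minimum
#'
#' A network is a local minimum for a criterion when no toggle of a single
#' ordered pair among all `N(N-1)` candidates strictly decreases the
#' criterion value (strict decrease beyond a 1e-12 guard).
#'
#' @param net a [SharingNetwork-class].
#' @param params a [ModelParams-class].
#' @param criterion `"rv"` or `"wef"`.
#' @return Logical scalar; when `FALSE`, the attribute `improvingToggle`
#'   carries one improving ordered pair `(from, to)` (0-based).
#' @examples
#' isLocalMinimum(SharingNetwork(3, hunters = 0:2),
#'                ModelParams(0.3, 2), "wef")  # TRUE: WEF = 0
#' @export
isLocalMinimum <- function(net, params, criterion = c("rv", "wef")) {
  criterion <- match.arg(criterion)
  core <- .asCore(net)
  .isLocalMinAdj(core$adj, core$hunters, params, criterion)
}

.isLocalMinAdj <- function(adj, huntersIdx, params, criterion) {
  cur <- .evalCrit(adj, huntersIdx, params, criterion)
  pairs <- .orderedPairs(nrow(adj))
  for (i in seq_len(nrow(pairs))) {
    u <- pairs[i, 1L]; v <- pairs[i, 2L]
    val <- .evalCrit(.toggle(adj, u, v), huntersIdx, params, criterion)
    if (val < cur - 1e-12) {
      out <- FALSE
      attr(out, "improvingToggle") <- c(from = u - 1L, to = v - 1L)
      return(out)
    }
  }
  TRUE
}

# seeded initial population: uniform random digraphs whose arc probability
# is drawn per individual from [0.05, 0.5] for diverse starting densities
.initPopulation <- function(mu, N) {
  lapply(seq_len(mu), function(i) {
    p <- runif(1L, 0.05, 0.5)
    adj <- matrix(as.integer(runif(N * N) < p), N, N)
    diag(adj) <- 0L
    adj
  })
}

.makeOffspring <- function(parents, lambdaRatio, pairs) {
  npairs <- nrow(pairs)
  offspring <- vector("list", length(parents) * lambdaRatio)
  idx <- 1L
  for (p in parents) {
    for (j in seq_len(lambdaRatio)) {
      i <- sample.int(npairs, 1L)
      offspring[[idx]] <- .toggle(p, pairs[i, 1L], pairs[i, 2L])
      idx <- idx + 1L
    }
  }
  offspring
}

#' Evolve networks that minimize a single criterion
#'
#' A comma-selection `(mu, lambda)` evolution strategy: each generation
#' every parent yields `lambdaRatio` offspring by one arc toggle, and the
#' next generation of `mu` parents is chosen from the offspring pool only,
#' by size-`t` tournaments (with replacement; ties broken by lower cost,
#' then insertion order). After the final generation the surviving
#' individuals are deduplicated by their cost-equivalence signature and
#' filtered to single-arc local minima.
#'
#' @param params a [ModelParams-class].
#' @param config an [EvolutionConfig-class]; hunters are nodes
#'   `0..config@nh - 1`.
#' @param criterion `"rv"` or `"wef"`.
#' @return A list of individuals, each a list with elements `network`
#'   (canonically reduced [SharingNetwork-class]), `costs` (named
#'   `c(rv, wef)`) and `criterionValue`.
#' @examples
#' \donttest{
#' cfg <- EvolutionConfig(mu = 20, generations = 20, N = 4, nh = 1, seed = 3)
#' evolveSingle(ModelParams(0.3, 3), cfg, "wef")
#' }
#' @export
evolveSingle <- function(params, config, criterion = c("rv", "wef")) {
  criterion <- match.arg(criterion)
  validObject(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)
  N <- config@N
  huntersIdx <- seq_len(config@nh)
  pairs <- .orderedPairs(N)
  parents <- .initPopulation(config@mu, N)
  t <- config@tournamentSize
  for (gen in seq_len(config@generations)) {
    offspring <- .makeOffspring(parents, config@lambdaRatio, pairs)
    costs <- vapply(offspring, .evalCrit, numeric(1L),
                    huntersIdx = huntersIdx, params = params,
                    criterion = criterion)
    winners <- vapply(seq_len(config@mu), function(i) {
      cand <- sample.int(length(offspring), t, replace = TRUE)
      cand[order(costs[cand], cand)][1L]
    }, integer(1L))
    parents <- offspring[winners]
  }
  sigs <- vapply(parents, .signature, character(1L),
                 huntersIdx = huntersIdx, params = params)
  keep <- !duplicated(sigs)
  out <- list()
  for (i in which(keep)) {
    adj <- parents[[i]]
    if (!isTRUE(.isLocalMinAdj(adj, huntersIdx, params, criterion))) next
    radj <- .reduceAdj(adj, huntersIdx, params@F)
    cv <- .evalCosts(radj, huntersIdx, params)
    out[[length(out) + 1L]] <- list(
      network = .fromCore(radj, huntersIdx),
      costs = cv,
      criterionValue = unname(cv[criterion]))
  }
  out[order(vapply(out, `[[`, numeric(1L), "criterionValue"))]
}

#' Fast non-dominated sorting
#'
#' Partitions cost vectors into Pareto fronts: front 1 is the non-dominated
#' set, front 2 the non-dominated set once front 1 is removed, and so on.
#'
#' @param costs numeric matrix, one row per item, columns are objectives.
#' @return A list of integer vectors of row indices, one per front.
#' @examples
#' nondominatedSort(rbind(c(1, 1), c(2, 2), c(3, 3)))
#' @export
nondominatedSort <- function(costs) {
  m <- as.matrix(costs)
  if (nrow(m) == 0L) stop("invalid argument: empty cost collection")
  remaining <- seq_len(nrow(m))
  fronts <- list()
  while (length(remaining)) {
    mask <- .dominatedMask(m[remaining, , drop = FALSE])
    fronts[[length(fronts) + 1L]] <- remaining[!mask]
    remaining <- remaining[mask]
  }
  fronts
}

# NSGA-II crowding distance within one front (rows of `m`)
.crowdingDistance <- function(m) {
  n <- nrow(m)
  d <- numeric(n)
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    rng <- m[o[n], j] - m[o[1L], j]
    d[o[c(1L, n)]] <- Inf
    if (n > 2L && rng > 0)
      d[o[2:(n - 1L)]] <- d[o[2:(n - 1L)]] +
        (m[o[3:n], j] - m[o[1:(n - 2L)], j]) / rng
  }
  d
}

# NSGA-II environmental selection of `mu` indices from a cost matrix
.nsga2Select <- function(costs, mu) {
  fronts <- nondominatedSort(costs)
  chosen <- integer(0)
  for (f in fronts) {
    if (length(chosen) + length(f) <= mu) {
      chosen <- c(chosen, f)
      if (length(chosen) == mu) break
    } else {
      cd <- .crowdingDistance(costs[f, , drop = FALSE])
      # deterministic tie-break: crowding desc, then cost lexicographic,
      # then insertion order
      o <- order(-cd, costs[f, 1L], costs[f, 2L], f)
      chosen <- c(chosen, f[o][seq_len(mu - length(chosen))])
      break
    }
  }
  chosen
}

#' Evolve an approximate Pareto front for both criteria
#'
#' The same comma-selection `(mu, lambda)` scheme as [evolveSingle()], with
#' NSGA-II environmental selection (non-dominated rank, then crowding
#' distance, with deterministic tie-breaking) applied to the offspring pool.
#' Returns the first front of the final population after canonical
#' reduction and signature deduplication.
#'
#' @param params a [ModelParams-class].
#' @param config an [EvolutionConfig-class].
#' @return A list with `individuals` (list of `network` / `costs` pairs on
#'   the first front) and `front` (their cost matrix, columns `rv`, `wef`).
#' @examples
#' \donttest{
#' cfg <- EvolutionConfig(mu = 20, generations = 20, N = 4, nh = 1, seed = 3)
#' evolveMulti(ModelParams(0.08, 4), cfg)$front
#' }
#' @export
evolveMulti <- function(params, config) {
  validObject(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)
  N <- config@N
  huntersIdx <- seq_len(config@nh)
  pairs <- .orderedPairs(N)
  parents <- .initPopulation(config@mu, N)
  for (gen in seq_len(config@generations)) {
    offspring <- .makeOffspring(parents, config@lambdaRatio, pairs)
    costs <- t(vapply(offspring, .evalCosts, numeric(2L),
                      huntersIdx = huntersIdx, params = params))
    parents <- offspring[.nsga2Select(costs, config@mu)]
  }
  costs <- t(vapply(parents, .evalCosts, numeric(2L),
                    huntersIdx = huntersIdx, params = params))
  f1 <- nondominatedSort(costs)[[1L]]
  sigs <- vapply(parents[f1], .signature, character(1L),
                 huntersIdx = huntersIdx, params = params)
  f1 <- f1[!duplicated(sigs)]
  individuals <- lapply(f1, function(i) {
    radj <- .reduceAdj(parents[[i]], huntersIdx, params@F)
    list(network = .fromCore(radj, huntersIdx),
         costs = c(rv = costs[i, 1L], wef = costs[i, 2L]))
  })
  o <- order(costs[f1, 1L], costs[f1, 2L])
  individuals <- individuals[o]
  front <- costs[f1[o], , drop = FALSE]
  colnames(front) <- c("rv", "wef")
  list(individuals = individuals, front = front)
}

#' Exhaustive optimization oracle for tiny networks
#'
#' Enumerates all `2^(N(N-1))` loop-free simple digraphs on `N` nodes with
#' the given fixed hunter set, and returns the exact global minima of both
#' criteria and the exact Pareto front. Only feasible at desk scale;
#' refuses `N > 5`.
#'
#' @param N number of nodes, `<= 5`.
#' @param hunters hunter node ids (0-based).
#' @param params a [ModelParams-class].
#' @return A list with elements `rvMin` and `wefMin` (each a list of
#'   `value` and one optimal `network`), `front` (exact Pareto front cost
#'   matrix, deduplicated, sorted by rv) and `frontNetworks` (one example
#'   network per front point).
#' @examples
#' \donttest{bruteForceOptima(3, 0, ModelParams(0.5, 2))$front}
#' @export
bruteForceOptima <- function(N, hunters, params) {
  N <- as.integer(N)
  if (N > 5L)
    stop("refused: exhaustive enumeration is limited to N <= 5 (2^(N(N-1)) digraphs)")
  huntersIdx <- as.integer(hunters) + 1L
  if (length(huntersIdx) < 1L || any(huntersIdx < 1L | huntersIdx > N))
    stop("invalid model: hunter ids must lie in 0..N-1")
  pairs <- .orderedPairs(N)
  P <- nrow(pairs)
  nNets <- 2^P
  powers <- bitwShiftL(1L, 0:(P - 1L))
  template <- matrix(0L, N, N)
  maskAdj <- function(mask) {
    adj <- template
    bits <- which(bitwAnd(mask, powers) != 0L)
    if (length(bits)) adj[pairs[bits, , drop = FALSE]] <- 1L
    adj
  }
  costs <- matrix(NA_real_, nNets, 2L)
  for (mask in 0:(nNets - 1L))
    costs[mask + 1L, ] <- .evalCosts(maskAdj(mask), huntersIdx, params)
  colnames(costs) <- c("rv", "wef")
  iRv <- which.min(costs[, 1L])
  iWef <- which.min(costs[, 2L])
  nd <- which(!.dominatedMask(costs))
  key <- paste(sprintf("%.9f", costs[nd, 1L]),
               sprintf("%.9f", costs[nd, 2L]))
  nd <- nd[!duplicated(key)]
  nd <- nd[order(costs[nd, 1L], costs[nd, 2L])]
  list(
    rvMin = list(value = unname(costs[iRv, 1L]),
                 network = .fromCore(maskAdj(iRv - 1L), huntersIdx)),
    wefMin = list(value = unname(costs[iWef, 2L]),
                  network = .fromCore(maskAdj(iWef - 1L), huntersIdx)),
    front = costs[nd, , drop = FALSE],
    frontNetworks = lapply(nd - 1L, function(mask)
      .fromCore(maskAdj(mask), huntersIdx)))
}
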