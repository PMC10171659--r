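#' Model parameters for the food-sharing protocol
#'
#' Container for the four parameters governing the sharing protocol and the
#' survival window: `ph`, the probability that each hunter hunts in a time
#' step; `F`, the number of units of food per prey (agents fed per hunt,
#' including the hunter); `n`, the life span in time steps; and `k`, the
#' critical fasting-window length (a run of `k` consecutive steps without
#' food is lethal).
#'
#' @slot ph numeric scalar in `[0, 1]`.
#' @slot F integer scalar, `>= 1`.
#' @slot n integer scalar, `>= 2`; default 1000.
#' @slot k integer scalar, `1 <= k < n`; default 10.
#'
#' @seealso [ModelParams()] for the constructor.
#' @name ModelParams-class
#' @rdname ModelParams-class
#' @exportClass ModelParams
setClass("ModelParams",
  representation(ph = "numeric", F = "integer", n = "integer", k = "integer"))

setValidity("ModelParams", function(object) {
  msg <- character()
  if (length(object@ph) != 1L || is.na(object@ph) ||
      object@ph < 0 || object@ph > 1)
    msg <- c(msg, "'ph' must be a single probability in [0, 1]")
  if (length(object@F) != 1L || is.na(object@F) || object@F < 1L)
    msg <- c(msg, "'F' must be a single integer >= 1")
  if (length(object@n) != 1L || is.na(object@n) || object@n < 2L)
    msg <- c(msg, "'n' must be a single integer >= 2")
  if (length(object@k) != 1L || is.na(object@k) ||
      object@k < 1L || object@k >= object@n)
    msg <- c(msg, "'k' must satisfy 1 <= k < n")
  if (length(msg)) msg else TRUE
})

#' Construct model parameters
#'
#' @param ph probability that a hunter hunts per time step, in `[0, 1]`.
#' @param F units of food per prey (agents fed per hunt), integer `>= 1`.
#' @param n life span in time steps; the default 1000 is the model's working
#'   regime.
#' @param k critical fasting-window length, `1 <= k < n`; default 10.
#'
#' @return A [ModelParams-class] object.
#' @examples
#' ModelParams(ph = 0.2, F = 4)
#' @export
ModelParams <- function(ph, F, n = 1000L, k = 10L) {
  new("ModelParams", ph = as.numeric(ph), F = as.integer(F),
      n = as.integer(n), k = as.integer(k))
}

#' Directed food-sharing network with a hunter subset
#'
#' A loop-free simple directed network over nodes `0, ..., N-1` together with
#' a non-empty subset of hunter nodes. Isolated nodes are permitted (they are
#' required for the every-man-for-himself regime, where non-hunters receive
#' no food at all).
#'
#' Node ids are 0-based throughout, matching the on-disk formats.
#'
#' @slot nNodes integer, number of nodes `N >= 1`.
#' @slot arcs integer matrix with columns `from`, `to`; one row per directed
#'   arc; no self-loops, no duplicates.
#' @slot hunters integer vector of hunter node ids (0-based), non-empty.
#'
#' @seealso [SharingNetwork()] for the constructor, [validateNetwork()].
#' @name SharingNetwork-class
#' @rdname SharingNetwork-class
#' @exportClass SharingNetwork
setClass("SharingNetwork",
  representation(nNodes = "integer", arcs = "matrix", hunters = "integer"))

setValidity("SharingNetwork", function(object) {
  msg <- character()
  N <- object@nNodes
  a <- object@arcs
  if (length(N) != 1L || is.na(N) || N < 1L)
    msg <- c(msg, "'nNodes' must be a single integer >= 1")
  if (!is.numeric(a) || ncol(a) != 2L)
    return("'arcs' must be a two-column integer matrix")
  if (nrow(a) > 0L) {
    if (any(is.na(a)) || any(a < 0L) || any(a >= N))
      msg <- c(msg, "arc endpoints must be node ids in 0..N-1")
    else {
      if (any(a[, 1L] == a[, 2L]))
        msg <- c(msg, "invalid structure: self-loops are not allowed")
      if (anyDuplicated(paste(a[, 1L], a[, 2L])))
        msg <- c(msg, "invalid structure: parallel (duplicate) arcs are not allowed")
    }
  }
  h <- object@hunters
  if (length(h) == 0L)
    msg <- c(msg, "invalid model: the hunter set must be non-empty")
  else if (any(is.na(h)) || any(h < 0L) || any(h >= N))
    msg <- c(msg, "invalid model: hunter ids must lie in 0..N-1")
  else if (anyDuplicated(h))
    msg <- c(msg, "invalid model: duplicated hunter ids")
  if (length(msg)) msg else TRUE
})

#' Construct a sharing network
#'
#' @param nNodes number of nodes `N`; nodes are labelled `0, ..., N-1`.
#' @param arcs two-column matrix (or data.frame) of directed arcs
#'   `(from, to)`, 0-based ids; may have zero rows.
#' @param hunters vector of hunter node ids (0-based), non-empty.
#'
#' @return A validated [SharingNetwork-class] object.
#' @examples
#' net <- SharingNetwork(3, rbind(c(0, 1), c(1, 2)), hunters = 0)
#' net
#' @export
SharingNetwork <- function(nNodes, arcs = matrix(integer(), 0L, 2L),
                           hunters) {
  if (is.null(arcs) || length(arcs) == 0L) arcs <- matrix(integer(), 0L, 2L)
  arcs <- as.matrix(arcs)
  storage.mode(arcs) <- "integer"
  colnames(arcs) <- c("from", "to")
  new("SharingNetwork", nNodes = as.integer(nNodes), arcs = arcs,
      hunters = as.integer(sort(unique(as.integer(hunters)))))
}

#' Exact distribution of the number of lethal fasting runs
#'
#' The law of `G`, the number of maximal runs of at least `k` consecutive
#' foodless steps in `n` i.i.d. steps when the per-step probability of
#' eating is `pe` (so a "success", i.e. a foodless step, has probability
#' `1 - pe`). Support is `0..gmax` with `gmax = floor((n+1)/(k+1))`.
#'
#' @slot n integer, number of trials (life span).
#' @slot k integer, minimal lethal run length.
#' @slot pe numeric, per-step probability of eating.
#' @slot pmf numeric vector of length `gmax + 1`; `pmf[g + 1] = P(G = g)`.
#'
#' @seealso [runCountDistribution()], [runCountMoments()], [rvFunction()].
#' @name RunCountDistribution-class
#' @rdname RunCountDistribution-class
#' @exportClass RunCountDistribution
setClass("RunCountDistribution",
  representation(n = "integer", k = "integer", pe = "numeric",
                 pmf = "numeric"))

setValidity("RunCountDistribution", function(object) {
  msg <- character()
  gmax <- (object@n + 1L) %/% (object@k + 1L)
  if (length(object@pmf) != gmax + 1L)
    msg <- c(msg, "pmf must have length gmax + 1")
  if (any(object@pmf < -1e-12))
    msg <- c(msg, "pmf entries must be non-negative")
  if (abs(sum(object@pmf) - 1) > 1e-9)
    msg <- c(msg, "pmf must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Configuration of the evolutionary searches
#'
#' Defaults follow the model's published working regime: population
#' `mu = 1000`, offspring ratio `lambda/mu = 8` and tournament size `t = 12`
#' to increase selective pressure, on networks of `N = 12` nodes.
#'
#' @slot mu integer, parent population size (`>= 2`).
#' @slot lambdaRatio integer, offspring per parent (`lambda / mu >= 1`).
#' @slot tournamentSize integer, tournament size for single-criterion
#'   selection, `2 <= t <= mu * lambdaRatio`.
#' @slot generations integer, fixed generation budget.
#' @slot seed integer, seed for all randomness in the run.
#' @slot N integer, network size.
#' @slot nh integer, number of hunters (nodes `0..nh-1`).
#'
#' @seealso [EvolutionConfig()], [evolveSingle()], [evolveMulti()].
#' @name EvolutionConfig-class
#' @rdname EvolutionConfig-class
#' @exportClass EvolutionConfig
setClass("EvolutionConfig",
  representation(mu = "integer", lambdaRatio = "integer",
                 tournamentSize = "integer", generations = "integer",
                 seed = "integer", N = "integer", nh = "integer"))

setValidity("EvolutionConfig", function(object) {
  msg <- character()
  if (object@mu < 2L) msg <- c(msg, "'mu' must be >= 2")
  if (object@lambdaRatio < 1L) msg <- c(msg, "'lambdaRatio' must be >= 1")
  if (object@tournamentSize < 2L ||
      object@tournamentSize > object@mu * object@lambdaRatio)
    msg <- c(msg, "'tournamentSize' must lie in [2, mu * lambdaRatio]")
  if (object@generations < 1L) msg <- c(msg, "'generations' must be >= 1")
  if (object@N < 1L) msg <- c(msg, "'N' must be >= 1")
  if (object@nh < 1L || object@nh > object@N)
    msg <- c(msg, "'nh' must satisfy 1 <= nh <= N")
  if (length(msg)) msg else TRUE
})

#' Construct an evolution configuration
#'
#' @param mu parent population size (default 1000).
#' @param lambdaRatio offspring per parent, `lambda / mu` (default 8).
#' @param tournamentSize tournament size for single-criterion selection
#'   (default 12).
#' @param generations generation budget (default 200).
#' @param seed integer seed (default 1).
#' @param N network size (default 12).
#' @param nh number of hunters; hunters are nodes `0..nh-1`.
#'
#' @return An [EvolutionConfig-class] object.
#' @examples
#' EvolutionConfig(mu = 50, generations = 60, N = 4, nh = 1)
#' @export
EvolutionConfig <- function(mu = 1000L, lambdaRatio = 8L,
                            tournamentSize = 12L, generations = 200L,
                            seed = 1L, N = 12L, nh = 1L) {
  new("EvolutionConfig", mu = as.integer(mu),
      lambdaRatio = as.integer(lambdaRatio),
      tournamentSize = as.integer(tournamentSize),
      generations = as.integer(generations), seed = as.integer(seed),
      N = as.integer(N), nh = as.integer(nh))
}
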