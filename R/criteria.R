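#' Welfare (WEF) cost of an eating profile
#'
#' The welfare criterion for minimization: the population standard deviation
#' (divide by `N`, not `N - 1`) of the probability of eating over all nodes,
#' hunters included. Zero means perfectly egalitarian access to food; the
#' largest possible value for probabilities in `[0, 1]` is 0.5.
#'
#' @param pe numeric vector: eating profile over all nodes.
#' @return Non-negative numeric scalar.
#' @examples
#' wefCost(c(0.08, 0.02, 0.02, 0.02, 0.02))  # 0.024
#' @export
wefCost <- function(pe) {
  if (length(pe) == 0L)
    stop("invalid argument: empty eating profile")
  sqrt(mean((pe - mean(pe))^2))
}

#' RV cost of an eating profile
#'
#' The individual starvation-risk criterion for minimization: the mean over
#' all nodes (hunters included) of the RV function evaluated at each node's
#' probability of eating.
#'
#' @param pe numeric vector: eating profile over all nodes.
#' @param n life span in steps (default 1000).
#' @param k lethal run length (default 10).
#' @return Non-negative numeric scalar.
#' @examples
#' rvCost(c(0.08, 0.02, 0.02, 0.02, 0.02))  # 0.261 to 3 decimals
#' @export
rvCost <- function(pe, n = 1000L, k = 10L) {
  if (length(pe) == 0L)
    stop("invalid argument: empty eating profile")
  mean(rvFunction(pe, n, k))
}

#' Cost vector (RV, WEF) of a network
#'
#' Composes [eatingProbabilities()] with [rvCost()] and [wefCost()]: the
#' point in the two-objective space where dominance and Pareto optimality
#' live.
#'
#' @param net a [SharingNetwork-class].
#' @param params a [ModelParams-class].
#' @return Named numeric vector `c(rv = ..., wef = ...)`.
#' @examples
#' costVector(fixtureHunterStar(), ModelParams(0.08, 4))  # c(0.261, 0.024)
#' @rdname costVector
#' @export
setMethod("costVector", c("SharingNetwork", "ModelParams"),
  function(net, params) {
    pe <- eatingProbabilities(net, params)
    c(rv = rvCost(pe, params@n, params@k), wef = wefCost(pe))
  })

#' Pareto dominance between cost vectors
#'
#' `u` dominates `v` when `u` is no worse in every coordinate and strictly
#' better in at least one (minimization). The relation is a strict partial
#' order: irreflexive, antisymmetric and transitive.
#'
#' @param u,v numeric cost vectors of equal length (typically `(rv, wef)`).
#' @return Logical scalar.
#' @examples
#' dominates(c(1, 2), c(2, 2))          # TRUE
#' dominates(c(0.261, 0.024), c(0.315, 0.02))  # FALSE: a trade-off
#' @export
dominates <- function(u, v) {
  stopifnot(length(u) == length(v), is.finite(u), is.finite(v))
  all(u <= v) && any(u < v)
}

#' Non-dominated (Pareto) filter
#'
#' Keeps the cost vectors not dominated by any other in the collection.
#' Input order is preserved and exact duplicates are all retained (identical
#' vectors never dominate one another).
#'
#' @param costs a numeric matrix with one row per item (columns are
#'   objectives), or a list of equal-length numeric vectors.
#' @return An object of the same kind as the input, restricted to the
#'   non-dominated items.
#' @examples
#' paretoFilter(rbind(c(1, 1), c(2, 2)))  # keeps only (1, 1)
#' @export
paretoFilter <- function(costs) {
  wasList <- is.list(costs)
  m <- if (wasList) do.call(rbind, costs) else as.matrix(costs)
  if (nrow(m) == 0L)
    stop("invalid argument: empty cost collection")
  keep <- !.dominatedMask(m)
  if (wasList) costs[keep] else m[keep, , drop = FALSE]
}

# logical mask: row i TRUE iff some other row dominates row i.
# Exact two-objective sweep: process groups of equal f1 in ascending order;
# within a group only the minimal-f2 members (duplicates included) can
# survive, and any earlier group with strictly smaller f1 dominates them
# whenever its best f2 is <= theirs.
.dominatedMask <- function(m) {
  n <- nrow(m)
  dominated <- logical(n)
  o <- order(m[, 1L], m[, 2L])
  best2 <- Inf
  i <- 1L
  while (i <= n) {
    f1 <- m[o[i], 1L]
    j <- i
    while (j <= n && m[o[j], 1L] == f1) j <- j + 1L
    grp <- o[i:(j - 1L)]
    gmin <- m[grp[1L], 2L]
    dominated[grp] <- m[grp, 2L] > gmin | best2 <= m[grp, 2L]
    best2 <- min(best2, gmin)
    i <- j
  }
  dominated
}
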