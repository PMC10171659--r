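# Descriptive features used to characterize optimal networks: degree
# statistics, strongly connected components, clustering, reciprocity,
# assortativity, directed modularity and eating-probability summaries.

#' Pair reciprocity of a directed network
#'
#' The proportion of connected unordered node pairs that are connected in
#' both directions. `NA` when the network has no arcs (the measure is
#' undefined).
#'
#' @param net a [SharingNetwork-class].
#' @return Numeric in `[0, 1]`, or `NA` for an arcless network.
#' @examples
#' reciprocity(fixtureSevenNode())  # 0: no bidirectional pair
#' @export
reciprocity <- function(net) {
  adj <- .asCore(net)$adj
  both <- adj == 1L & t(adj) == 1L
  any1 <- adj == 1L | t(adj) == 1L
  nPairs <- sum(any1[upper.tri(any1)] | t(any1)[upper.tri(any1)])
  if (nPairs == 0L) return(NA_real_)
  nBoth <- sum(both[upper.tri(both)])
  nBoth / nPairs
}

#' Counts of arcs by endpoint roles
#'
#' Classifies every directed arc, ignoring direction, by whether it joins
#' two hunters (`intra_h`), two non-hunters (`intra_nonh`) or a hunter and
#' a non-hunter (`inter_h_nonh`). Arcs are counted individually, so the
#' three counts always sum to the number of arcs.
#'
#' @param net a [SharingNetwork-class].
#' @return Named integer vector
#'   `c(intra_h = ..., intra_nonh = ..., inter_h_nonh = ...)`.
#' @examples
#' arcTypeCounts(fixtureSevenNode())  # (0, 5, 3)
#' @export
arcTypeCounts <- function(net) {
  isH <- (seq_len(net@nNodes) - 1L) %in% net@hunters
  a <- net@arcs
  fromH <- isH[a[, 1L] + 1L]
  toH <- isH[a[, 2L] + 1L]
  c(intra_h = sum(fromH & toH),
    intra_nonh = sum(!fromH & !toH),
    inter_h_nonh = sum(xor(fromH, toH)))
}

# directed Newman-Leicht modularity of a membership vector (1-based labels)
.dirModularity <- function(adj, membership) {
  m <- sum(adj)
  if (m == 0) return(NA_real_)
  within <- sum(adj[outer(membership, membership, "==")])
  kout <- tapply(rowSums(adj), membership, sum)
  kin <- tapply(colSums(adj), membership, sum)
  within / m - sum(kout * kin) / m^2
}

#' Directed modularity of a given partition
#'
#' Newman-Leicht modularity for directed networks:
#' `Q = (1/m) * sum_{(u,v) in E, same block} 1 - sum_b kout_b * kin_b / m^2`
#' where `m` is the number of arcs and `kout_b`, `kin_b` the total out- and
#' in-degree of block `b`.
#'
#' @param net a [SharingNetwork-class] with at least one arc.
#' @param blocks either an integer membership vector of length `N`
#'   (arbitrary labels) or a list of disjoint 0-based node-id vectors
#'   covering all nodes.
#' @return Numeric modularity `Q` in `[-1, 1]`.
#' @examples
#' cyc <- SharingNetwork(6, rbind(c(0,1),c(1,2),c(2,0),
#'                                c(3,4),c(4,5),c(5,3)), hunters = 0)
#' partitionModularity(cyc, list(0:2, 3:5))  # 0.5
#' @export
partitionModularity <- function(net, blocks) {
  adj <- .asCore(net)$adj
  if (sum(adj) == 0L)
    stop("invalid argument: modularity is undefined on an arcless network")
  membership <- .asMembership(blocks, net@nNodes)
  .dirModularity(adj, membership)
}

.asMembership <- function(blocks, N) {
  if (is.list(blocks)) {
    ids <- sort(unlist(blocks))
    if (length(ids) != N || any(ids != seq_len(N) - 1L))
      stop("invalid argument: blocks must partition the node set 0..N-1")
    membership <- integer(N)
    for (b in seq_along(blocks)) membership[blocks[[b]] + 1L] <- b
    membership
  } else {
    if (length(blocks) != N || any(is.na(blocks)))
      stop("invalid argument: membership must cover all N nodes")
    as.integer(factor(blocks))
  }
}

#' Stochastic search for a modularity-maximizing partition
#'
#' Seeded multi-restart maximization of directed modularity: greedy
#' agglomeration from singleton blocks (merging the connected block pair
#' with the best modularity gain) followed by single-node move refinement,
#' repeated over `restarts` shuffled restarts; the best partition found is
#' returned. Deterministic for a fixed seed.
#'
#' @param net a [SharingNetwork-class].
#' @param restarts number of seeded restarts (default 20).
#' @param seed integer seed.
#' @return A list with `blocks` (list of 0-based node-id vectors),
#'   `membership`, `modularity` (`NA` for an arcless network),
#'   `restartsUsed` and `seed`.
#' @examples
#' cyc <- SharingNetwork(6, rbind(c(0,1),c(1,2),c(2,0),
#'                                c(3,4),c(4,5),c(5,3)), hunters = 0)
#' modularitySearch(cyc)$modularity  # 0.5
#' @export
modularitySearch <- function(net, restarts = 20L, seed = 1L) {
  adj <- .asCore(net)$adj
  N <- nrow(adj)
  if (sum(adj) == 0L)
    return(list(blocks = as.list(seq_len(N) - 1L),
                membership = seq_len(N), modularity = NA_real_,
                restartsUsed = 0L, seed = as.integer(seed)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  und <- (adj + t(adj)) > 0L  # block adjacency ignores direction
  bestQ <- -Inf
  bestMem <- seq_len(N)
  for (r in seq_len(restarts)) {
    mem <- sample.int(N)  # shuffled singleton labels randomize tie-breaks
    mem <- .greedyAgglomerate(adj, und, mem)
    mem <- .nodeMoveRefine(adj, und, mem)
    q <- .dirModularity(adj, mem)
    if (q > bestQ + 1e-12) {
      bestQ <- q
      bestMem <- mem
    }
  }
  bestMem <- as.integer(factor(bestMem))
  blocks <- lapply(split(seq_len(N) - 1L, bestMem), as.integer)
  names(blocks) <- NULL
  list(blocks = blocks, membership = bestMem, modularity = bestQ,
       restartsUsed = as.integer(restarts), seed = as.integer(seed))
}

.greedyAgglomerate <- function(adj, und, mem) {
  repeat {
    labs <- unique(mem)
    if (length(labs) == 1L) break
    curQ <- .dirModularity(adj, mem)
    bestGain <- 1e-12
    bestPair <- NULL
    for (i in seq_along(labs)) {
      for (j in seq_along(labs)) {
        if (j <= i) next
        a <- mem == labs[i]; b <- mem == labs[j]
        if (!any(und[a, b, drop = FALSE])) next  # only connected blocks
        cand <- mem
        cand[b] <- labs[i]
        gain <- .dirModularity(adj, cand) - curQ
        if (gain > bestGain) {
          bestGain <- gain
          bestPair <- c(labs[i], labs[j])
        }
      }
    }
    if (is.null(bestPair)) break
    mem[mem == bestPair[2L]] <- bestPair[1L]
  }
  mem
}

.nodeMoveRefine <- function(adj, und, mem, maxPasses = 10L) {
  N <- nrow(adj)
  for (pass in seq_len(maxPasses)) {
    moved <- FALSE
    for (v in sample.int(N)) {
      curQ <- .dirModularity(adj, mem)
      nbBlocks <- unique(mem[und[v, ] | und[, v]])
      nbBlocks <- setdiff(nbBlocks, mem[v])
      for (b in nbBlocks) {
        cand <- mem
        cand[v] <- b
        if (.dirModularity(adj, cand) > curQ + 1e-12) {
          mem <- cand
          moved <- TRUE
          break
        }
      }
    }
    if (!moved) break
  }
  mem
}

#' Average intra-partition clustering (AIC)
#'
#' The mean local clustering coefficient of each block's induced
#' subnetwork (undirected projection; nodes of degree below 2 contribute
#' 0), averaged across blocks: a cohesiveness score for a partition,
#' typically the modularity-maximizing one.
#'
#' @param net a [SharingNetwork-class].
#' @param blocks partition as in [partitionModularity()].
#' @return Numeric in `[0, 1]`.
#' @examples
#' intraPartitionClustering(fixtureSevenNode(), list(0:6))
#' @export
intraPartitionClustering <- function(net, blocks) {
  membership <- .asMembership(blocks, net@nNodes)
  g <- igraph::as_undirected(asIgraph(net), mode = "collapse")
  vals <- vapply(unique(membership), function(b) {
    sub <- igraph::induced_subgraph(g, which(membership == b))
    if (igraph::vcount(sub) == 0L) return(0)
    lc <- igraph::transitivity(sub, type = "local", isolates = "zero")
    lc[is.na(lc)] <- 0  # degree < 2 contributes 0
    mean(lc)
  }, numeric(1L))
  mean(vals)
}

.sdPop <- function(x) sqrt(mean((x - mean(x))^2))

#' Descriptive feature battery of a sharing network
#'
#' Computes the full set of features used to characterize optima: degree
#' statistics (population standard deviations), strongly connected
#' component count (singletons included), mean local clustering on the
#' undirected projection, pair reciprocity, in-/out-degree assortativity
#' (Pearson correlation of endpoint in-degrees resp. out-degrees across
#' arcs; `NA` on zero variance), directed modularity and average
#' intra-partition clustering from [modularitySearch()], arc-type counts,
#' eating-probability summaries and the two costs.
#'
#' @param net a [SharingNetwork-class].
#' @param params a [ModelParams-class].
#' @param restarts restarts for the modularity search.
#' @param seed seed for the modularity search.
#' @return A one-row `data.frame` with columns `std_out_degree`,
#'   `std_in_degree`, `mean_out_degree`, `mean_in_degree_hunters`,
#'   `scc_count`, `mean_local_clustering`, `reciprocity`,
#'   `in_assortativity`, `out_assortativity`, `modularity`,
#'   `avg_intra_partition_clustering`, `intra_h_arcs`, `intra_nonh_arcs`,
#'   `inter_h_nonh_arcs`, `mean_pe`, `median_pe`,
#'   `hunter_nonhunter_pe_gap`, `rv_cost`, `wef_cost`.
#' @examples
#' networkFeatures(fixtureSevenNode(), ModelParams(0.2, 4))
#' @export
networkFeatures <- function(net, params, restarts = 20L, seed = 1L) {
  core <- .asCore(net)
  adj <- core$adj
  kout <- rowSums(adj)
  kin <- colSums(adj)
  g <- asIgraph(net)
  und <- igraph::as_undirected(g, mode = "collapse")
  lc <- igraph::transitivity(und, type = "local", isolates = "zero")
  lc[is.na(lc)] <- 0
  a <- net@arcs + 1L
  assort <- function(deg) {
    if (nrow(a) < 2L) return(NA_real_)
    suppressWarnings(cor(deg[a[, 1L]], deg[a[, 2L]]))
  }
  ms <- modularitySearch(net, restarts = restarts, seed = seed)
  aic <- if (is.na(ms$modularity)) 0 else
    intraPartitionClustering(net, ms$blocks)
  atc <- arcTypeCounts(net)
  pe <- eatingProbabilities(net, params)
  isH <- (seq_len(net@nNodes) - 1L) %in% net@hunters
  gap <- if (all(isH)) NA_real_ else mean(pe[isH]) - mean(pe[!isH])
  data.frame(
    std_out_degree = .sdPop(kout),
    std_in_degree = .sdPop(kin),
    mean_out_degree = mean(kout),
    mean_in_degree_hunters = mean(kin[core$hunters]),
    scc_count = igraph::components(g, mode = "strong")$no,
    mean_local_clustering = mean(lc),
    reciprocity = reciprocity(net),
    in_assortativity = assort(kin),
    out_assortativity = assort(kout),
    modularity = ms$modularity,
    avg_intra_partition_clustering = aic,
    intra_h_arcs = atc[["intra_h"]],
    intra_nonh_arcs = atc[["intra_nonh"]],
    inter_h_nonh_arcs = atc[["inter_h_nonh"]],
    mean_pe = mean(pe),
    median_pe = median(pe),
    hunter_nonhunter_pe_gap = gap,
    rv_cost = rvCost(pe, params@n, params@k),
    wef_cost = wefCost(pe))
}

#' Feature table for a collection of networks
#'
#' @param nets list of [SharingNetwork-class] objects.
#' @param params a [ModelParams-class].
#' @param ... passed to [networkFeatures()].
#' @return A `data.frame` with one row per network.
#' @examples
#' featureTable(list(fixtureSevenNode(), fixtureHunterStar()), ModelParams(0.2, 4))
#' @export
featureTable <- function(nets, params, ...) {
  do.call(rbind, lapply(nets, networkFeatures, params = params, ...))
}
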