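p33 <- ModelParams(0.3, 3)

test_that("mutation toggles exactly one ordered pair", {
  empty <- SharingNetwork(3, hunters = 0)
  set.seed(1)
  expect_equal(nrow(arcs(mutateNetwork(empty))), 1L)
  full <- randomNetwork(4, 1, nh = 1, seed = 1)  # complete loop-free digraph
  expect_equal(nrow(arcs(full)), 12L)
  set.seed(2)
  expect_equal(nrow(arcs(mutateNetwork(full))), 11L)
  set.seed(9); a <- mutateNetwork(full)
  set.seed(9); b <- mutateNetwork(full)
  expect_identical(arcs(a), arcs(b))
})

test_that("canonical reduction preserves the cost vector", {
  # an arc between nodes unreachable from the hunter is pruned
  net <- SharingNetwork(5, rbind(c(0, 1), c(3, 4)), hunters = 0)
  p <- ModelParams(0.3, 3)
  red <- canonicalReduce(net, p)
  expect_equal(nrow(arcs(red)), 1L)
  expect_equal(costVector(red, p), costVector(net, p), tolerance = 1e-12)
  # the worked 7-node example is fully feasible at F = 5
  fig1 <- fixtureSevenNode()
  expect_identical(arcs(canonicalReduce(fig1, ModelParams(0.2, 5))),
                   arcs(fig1))
  # F = 1: no food is ever shared, every arc is inert
  expect_equal(nrow(arcs(canonicalReduce(fig1, ModelParams(0.2, 1)))), 0L)
  # randomized invariance check
  for (s in 1:8) {
    rnet <- randomNetwork(7, 0.25, nh = 2, seed = s)
    pr <- ModelParams(0.15, 3)
    expect_equal(costVector(canonicalReduce(rnet, pr), pr),
                 costVector(rnet, pr), tolerance = 1e-12)
  }
})

test_that("the local-minimum test agrees with its definition", {
  solo <- SharingNetwork(3, hunters = 0:2)
  expect_true(isLocalMinimum(solo, p33, "wef"))  # WEF = 0 is global
  # a network with a known improving toggle reports it
  net <- SharingNetwork(2, hunters = 0)  # adding 0->1 improves WEF
  res <- isLocalMinimum(net, ModelParams(0.5, 2), "wef")
  expect_false(isTRUE(res))
  tog <- attr(res, "improvingToggle")
  improved <- SharingNetwork(2, rbind(tog), hunters = 0)
  expect_lt(wefCost(eatingProbabilities(improved, ModelParams(0.5, 2))),
            wefCost(eatingProbabilities(net, ModelParams(0.5, 2))))
  # exhaustive neighbourhood audit on random small networks
  for (s in 1:4) {
    rnet <- randomNetwork(4, 0.4, nh = 1, seed = s + 3)
    cur <- unname(costVector(rnet, p33)["rv"])
    nbr <- vapply(seq_len(12), function(i) {
      pairs <- expand.grid(u = 0:3, v = 0:3)
      pairs <- pairs[pairs$u != pairs$v, ]
      u <- pairs$u[i]; v <- pairs$v[i]
      a <- arcs(rnet)
      hit <- a[, 1] == u & a[, 2] == v
      a2 <- if (any(hit)) a[!hit, , drop = FALSE] else rbind(a, c(u, v))
      unname(costVector(SharingNetwork(4, a2, hunters(rnet)), p33)["rv"])
    }, numeric(1))
    expect_equal(isTRUE(isLocalMinimum(rnet, p33, "rv")),
                 all(nbr >= cur - 1e-12))
  }
})

test_that("non-dominated sorting partitions into successive fronts", {
  expect_equal(nondominatedSort(rbind(c(1, 1), c(2, 2), c(3, 3))),
               list(1L, 2L, 3L))
  trio <- rbind(c(0.261, 0.024), c(0.315, 0.02), c(0.332, 0.018))
  expect_equal(nondominatedSort(trio), list(1:3))
  # oracle: repeated Pareto-filter peeling
  set.seed(10)
  m <- matrix(round(runif(120), 1), ncol = 2)
  fronts <- nondominatedSort(m)
  rest <- seq_len(nrow(m))
  for (f in fronts) {
    expect_setequal(f, rest[pairwiseNondominated(m[rest, , drop = FALSE])])
    rest <- setdiff(rest, f)
  }
  expect_length(rest, 0)
})

test_that("single-criterion evolution returns deduplicated local minima", {
  cfg <- EvolutionConfig(mu = 20, lambdaRatio = 8, tournamentSize = 12,
                         generations = 25, seed = 5, N = 4, nh = 4)
  res <- evolveSingle(p33, cfg, "wef")
  expect_gt(length(res), 0)
  # with every node a hunter, WEF = 0 is attainable and attained
  expect_equal(res[[1]]$criterionValue, 0, tolerance = 1e-12)
  # determinism: identical output for identical seed
  cfg2 <- EvolutionConfig(mu = 10, lambdaRatio = 4, tournamentSize = 6,
                          generations = 10, seed = 77, N = 4, nh = 1)
  a <- evolveSingle(p33, cfg2, "rv")
  b <- evolveSingle(p33, cfg2, "rv")
  expect_identical(lapply(a, `[[`, "costs"), lapply(b, `[[`, "costs"))
  expect_identical(lapply(a, function(x) arcs(x$network)),
                   lapply(b, function(x) arcs(x$network)))
  # every returned individual is a certified local minimum
  for (ind in a)
    expect_true(isTRUE(isLocalMinimum(ind$network, p33, "rv")))
})

test_that("multi-objective evolution returns a non-dominated front", {
  p <- ModelParams(0.08, 4)
  cfg <- EvolutionConfig(mu = 20, lambdaRatio = 8, tournamentSize = 12,
                         generations = 25, seed = 3, N = 4, nh = 1)
  em <- evolveMulti(p, cfg)
  expect_gt(nrow(em$front), 0)
  expect_true(all(pairwiseNondominated(em$front)))
  # stored costs re-derive from the stored networks
  for (ind in em$individuals)
    expect_equal(unname(costVector(ind$network, p)), unname(ind$costs),
                 tolerance = 1e-12)
  em2 <- evolveMulti(p, cfg)
  expect_equal(em$front, em2$front)
  # beats a random-search baseline of equal evaluation count on
  # hypervolume; run at N = 6 (about 10^9 digraphs) so the baseline cannot
  # come close to enumerating the search space — at enumerable sizes an
  # unbounded random archive is trivially competitive
  p6 <- ModelParams(0.08, 4)
  cfg6 <- EvolutionConfig(mu = 20, lambdaRatio = 8, tournamentSize = 12,
                          generations = 25, seed = 3, N = 6, nh = 1)
  em6 <- evolveMulti(p6, cfg6)
  evals <- 20 * 8 * 25
  set.seed(21)
  dens <- runif(evals, 0.05, 0.5)
  rnd <- t(vapply(seq_len(evals), function(s)
    costVector(randomNetwork(6, dens[s], 1, seed = s), p6), numeric(2)))
  ref <- c(max(rnd[, 1], em6$front[, 1]) + 0.01,
           max(rnd[, 2], em6$front[, 2]) + 0.01)
  expect_gte(hypervolume2d(em6$front, ref),
             hypervolume2d(paretoFilter(rnd), ref))
})

test_that("exhaustive enumeration matches hand computation at N = 2", {
  p <- ModelParams(0.5, 2)
  bf <- bruteForceOptima(2, 0, p)
  # four digraphs; arc 0->1 feeds the consumer surely: pe = (0.5, 0.5)
  expect_equal(bf$wefMin$value, 0, tolerance = 1e-12)
  expect_equal(unname(eatingProbabilities(bf$wefMin$network, p)),
               c(0.5, 0.5))
  # hand computation: the only profiles are (0.5, 0) (no useful arc,
  # wef 0.25, rv = mean(RV(0.5), RV(0))) and (0.5, 0.5) (arc 0->1 present,
  # wef 0, rv = RV(0.5)); RV(0.5) > RV(0) at n = 1000, k = 10, so the two
  # trade off and the exact front has both points
  expect_equal(nrow(bf$front), 2L)
  expect_equal(unname(bf$front[order(bf$front[, "wef"]), ]),
               rbind(c(rvFunction(0.5), 0),
                     c(mean(rvFunction(c(0.5, 0))), 0.25)),
               tolerance = 1e-12)
  expect_error(bruteForceOptima(6, 0, p), "N <= 5")
  bf2 <- bruteForceOptima(2, 0, p)
  expect_identical(bf$front, bf2$front)  # deterministic
})
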