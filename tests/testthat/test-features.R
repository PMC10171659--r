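twoCycles <- SharingNetwork(6, rbind(c(0, 1), c(1, 2), c(2, 0),
                                     c(3, 4), c(4, 5), c(5, 3)),
                            hunters = 0)

test_that("reciprocity counts bidirectional pairs among connected pairs", {
  expect_equal(reciprocity(fixtureSevenNode()), 0)
  expect_equal(reciprocity(SharingNetwork(2, rbind(c(0, 1), c(1, 0)), 0)), 1)
  expect_true(is.na(reciprocity(SharingNetwork(3, hunters = 0))))
  # one mutual pair out of two connected pairs
  net <- SharingNetwork(3, rbind(c(0, 1), c(1, 0), c(1, 2)), 0)
  expect_equal(reciprocity(net), 0.5)
})

test_that("arc types classify endpoints ignoring direction", {
  expect_equal(arcTypeCounts(fixtureSevenNode()),
               c(intra_h = 0L, intra_nonh = 5L, inter_h_nonh = 3L))
  allH <- SharingNetwork(3, rbind(c(0, 1), c(2, 0)), hunters = 0:2)
  expect_equal(unname(arcTypeCounts(allH)), c(2L, 0L, 0L))
  expect_equal(unname(arcTypeCounts(SharingNetwork(3, hunters = 0))),
               c(0L, 0L, 0L))
  for (s in 1:5) {
    rnet <- randomNetwork(8, 0.3, 3, seed = s)
    expect_equal(sum(arcTypeCounts(rnet)), nrow(arcs(rnet)))
  }
})

test_that("directed modularity evaluates partitions exactly", {
  expect_equal(partitionModularity(twoCycles, list(0:2, 3:5)), 0.5)
  # all nodes in one block: 1 - sum(kout*kin)/m^2 with uniform degrees
  expect_equal(partitionModularity(twoCycles, rep(1, 6)), 1 - 36 / 36)
  # single arc, endpoints in distinct blocks: no within-block arcs and a
  # vanishing degree-product term, so Q = 0
  oneArc <- SharingNetwork(2, rbind(c(0, 1)), 0)
  expect_equal(partitionModularity(oneArc, c(1, 2)), 0)
  # a split 2-cycle is genuinely negative
  cyc2 <- SharingNetwork(2, rbind(c(0, 1), c(1, 0)), 0)
  expect_equal(partitionModularity(cyc2, c(1, 2)), -0.5)
  expect_error(partitionModularity(twoCycles, list(0:2)), "partition")
  expect_error(partitionModularity(SharingNetwork(2, hunters = 0), c(1, 2)),
               "arcless")
})

test_that("the modularity search recovers planted partitions", {
  res <- modularitySearch(twoCycles, restarts = 10, seed = 2)
  expect_equal(res$modularity, 0.5, tolerance = 1e-12)
  expect_setequal(lapply(res$blocks, sort), list(0:2, 3:5))
  # complete digraph: no community structure beats the trivial bound
  full <- randomNetwork(5, 1, 1, seed = 1)
  expect_lt(modularitySearch(full, restarts = 5, seed = 1)$modularity, 0.05)
  # arcless network: undefined marker
  expect_true(is.na(modularitySearch(SharingNetwork(3, hunters = 0))$modularity))
  # deterministic for a fixed seed
  a <- modularitySearch(twoCycles, restarts = 5, seed = 9)
  b <- modularitySearch(twoCycles, restarts = 5, seed = 9)
  expect_identical(a, b)
})

test_that("the search matches exhaustive partition enumeration at small N", {
  for (s in c(1, 4)) {
    rnet <- randomNetwork(6, 0.3, 2, seed = s)
    if (nrow(arcs(rnet)) == 0) next
    parts <- allPartitions(6)
    best <- max(vapply(parts, function(mem)
      partitionModularity(rnet, mem), numeric(1)))
    found <- modularitySearch(rnet, restarts = 50, seed = 3)$modularity
    expect_equal(found, best, tolerance = 1e-12)
  }
})

test_that("intra-partition clustering averages block cohesion", {
  # a 3-clique block plus an arcless block: (1 + 0) / 2
  cl <- SharingNetwork(5, rbind(c(0, 1), c(1, 2), c(2, 0),
                                c(1, 0), c(2, 1), c(0, 2)), hunters = 0)
  expect_equal(intraPartitionClustering(cl, list(0:2, 3:4)), 0.5)
  # singleton blocks carry no triangles
  expect_equal(intraPartitionClustering(cl, as.list(0:4)), 0)
  # forests have no triangles under any partition
  tree <- SharingNetwork(4, rbind(c(0, 1), c(0, 2), c(2, 3)), 0)
  expect_equal(intraPartitionClustering(tree, list(0:3)), 0)
})

test_that("the feature battery reproduces hand-derived values", {
  p <- ModelParams(0.2, 4)
  fv <- networkFeatures(fixtureSevenNode(), p, restarts = 5, seed = 1)
  expect_equal(fv$scc_count, 5)  # {1,2,3} plus four singletons
  expect_equal(fv$mean_pe, 1.56 / 7, tolerance = 1e-12)
  expect_equal(fv$hunter_nonhunter_pe_gap, 0.2 - 1.16 / 5,
               tolerance = 1e-12)
  expect_equal(fv$intra_nonh_arcs, 5)
  expect_equal(fv$reciprocity, 0)
  solo <- SharingNetwork(4, hunters = 0:3)
  fs <- networkFeatures(solo, ModelParams(0.3, 2))
  expect_equal(fs$std_out_degree, 0)
  expect_equal(fs$std_in_degree, 0)
  expect_true(is.na(fs$reciprocity))
  expect_equal(fs$wef_cost, 0)
})

test_that("role-preserving relabeling leaves the battery invariant", {
  p <- ModelParams(0.15, 3)
  net <- randomNetwork(7, 0.3, 2, seed = 6)
  # relabel by a permutation fixing the hunter set
  set.seed(14)
  perm <- c(hunters(net), sample(setdiff(0:6, hunters(net))))
  map <- integer(7); map[perm + 1L] <- 0:6
  relab <- SharingNetwork(7, cbind(map[arcs(net)[, 1] + 1L],
                                   map[arcs(net)[, 2] + 1L]),
                          map[hunters(net) + 1L])
  stable <- c("std_out_degree", "std_in_degree", "mean_out_degree",
              "mean_in_degree_hunters", "scc_count",
              "mean_local_clustering", "reciprocity", "in_assortativity",
              "out_assortativity", "intra_h_arcs", "intra_nonh_arcs",
              "inter_h_nonh_arcs", "mean_pe", "median_pe",
              "hunter_nonhunter_pe_gap", "rv_cost", "wef_cost")
  a <- networkFeatures(net, p, restarts = 5, seed = 1)
  b <- networkFeatures(relab, p, restarts = 5, seed = 1)
  expect_equal(a[stable], b[stable], tolerance = 1e-12)
})
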