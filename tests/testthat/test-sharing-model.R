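params24 <- ModelParams(0.2, 4)

test_that("network validation enforces the structural invariants", {
  expect_s4_class(validateNetwork(fixtureSevenNode()), "SharingNetwork")
  expect_s4_class(SharingNetwork(1, hunters = 0), "SharingNetwork")
  expect_error(SharingNetwork(4, rbind(c(3, 3)), hunters = 0), "self-loop")
  expect_error(SharingNetwork(4, rbind(c(0, 1), c(0, 1)), hunters = 0),
               "parallel")
  expect_error(SharingNetwork(4, rbind(c(0, 1)), hunters = integer(0)),
               "non-empty")
  expect_error(SharingNetwork(4, rbind(c(0, 1)), hunters = 7), "0..N-1")
})

test_that("visit probabilities match exhaustive walk enumeration", {
  net <- fixtureSevenNode()
  q <- visitProbabilities(net, params24)
  expect_equal(q["4", "5"], 1)        # 5 surely fed by 4
  expect_equal(unname(diag(q[, as.character(hunters(net))])), c(1, 1))
  expect_equal(q["0", "6"], 0)        # 6 unreachable from 0
  for (F in 2:5) {
    qF <- visitProbabilities(net, ModelParams(0.2, F))
    for (h in hunters(net)) {
      expect_equal(qF[as.character(h), ],
                   enumVisitProbs(net, h, F - 1L), tolerance = 1e-12)
    }
  }
  # randomized cross-check
  for (s in 1:5) {
    rnet <- randomNetwork(6, 0.35, nh = 2, seed = s)
    qR <- visitProbabilities(rnet, ModelParams(0.3, 4))
    for (h in hunters(rnet))
      expect_equal(qR[as.character(h), ], enumVisitProbs(rnet, h, 3L),
                   tolerance = 1e-12)
  }
})

test_that("visit probabilities are non-decreasing in F", {
  net <- randomNetwork(7, 0.3, nh = 2, seed = 11)
  prev <- visitProbabilities(net, ModelParams(0.2, 2))
  for (F in 3:6) {
    cur <- visitProbabilities(net, ModelParams(0.2, F))
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("eating probabilities compose hunts by inclusion-exclusion", {
  pe <- eatingProbabilities(fixtureSevenNode(), params24)
  expect_equal(unname(pe), c(0.2, 0.36, 0.2, 0.2, 0.2, 0.2, 0.2),
               tolerance = 1e-12)
  # all-hunter arcless network: only self-feeding
  solo <- SharingNetwork(4, hunters = 0:3)
  expect_equal(unname(eatingProbabilities(solo, ModelParams(0.37, 3))),
               rep(0.37, 4))
  # hunters always eat at least with probability ph
  rnet <- randomNetwork(8, 0.4, nh = 3, seed = 2)
  pe <- eatingProbabilities(rnet, ModelParams(0.25, 3))
  expect_true(all(pe[as.character(hunters(rnet))] >= 0.25 - 1e-12))
})

test_that("total eating probability is bounded by the food supply", {
  # sum_v pe(v) <= nh * ph * F, equality when walks never halt, revisit or
  # overlap (the worked example at F = 2)
  pe2 <- eatingProbabilities(fixtureSevenNode(), ModelParams(0.2, 2))
  expect_equal(sum(pe2), 2 * 0.2 * 2, tolerance = 1e-12)
  for (s in 1:5) {
    rnet <- randomNetwork(7, 0.3, nh = 2, seed = s + 20)
    p <- ModelParams(0.3, 4)
    expect_lte(sum(eatingProbabilities(rnet, p)), 2 * 0.3 * 4 + 1e-12)
  }
})

test_that("nodes outside every feasible walk do not disturb the profile", {
  net <- fixtureSevenNode()
  aug <- SharingNetwork(8, arcs(net), hunters(net))  # extra isolated node
  pe <- eatingProbabilities(net, params24)
  peAug <- eatingProbabilities(aug, params24)
  expect_equal(unname(peAug[1:7]), unname(pe), tolerance = 1e-15)
  expect_equal(unname(peAug[8]), 0)
})

test_that("analytic profile agrees with the protocol simulator", {
  rnet <- randomNetwork(8, 0.3, nh = 2, seed = 5)
  p <- ModelParams(0.3, 3)
  pe <- eatingProbabilities(rnet, p)
  nEv <- 1e5
  emp <- simulateEvents(rnet, p, nEv, seed = 99)
  se <- sqrt(pmax(pe * (1 - pe), 1e-12) / nEv)
  expect_true(all(abs(emp - pe) <= 3 * se + 1e-9))
})

test_that("the simulator respects its edge cases and is reproducible", {
  net <- fixtureHunterStar()
  expect_error(simulateEvents(net, params24, 0), "positive")
  p0 <- ModelParams(0, 4)
  expect_equal(unname(simulateEvents(net, p0, 100, seed = 1)), rep(0, 5))
  a <- simulateEvents(net, ModelParams(0.08, 4), 5000, seed = 42)
  b <- simulateEvents(net, ModelParams(0.08, 4), 5000, seed = 42)
  expect_identical(a, b)
  # star network: each non-hunter eats about ph/4 = 0.02
  nEv <- 2e5
  emp <- simulateEvents(net, ModelParams(0.08, 4), nEv, seed = 7)
  se <- sqrt(0.02 * 0.98 / nEv)
  expect_true(all(abs(emp[2:5] - 0.02) <= 3 * se))
})
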