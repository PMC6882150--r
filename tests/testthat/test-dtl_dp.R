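# The maximum-parsimony dynamic program and the reconciliation graph,
# cross-checked against the brute-force mapping oracle.

test_that("worked examples: single leaf, forced duplication, toy3", {
  expect_equal(optCost(computeDPTables(dtlFixture("leaf1"))), 0)

  dup1 <- dtlFixture("dup1")
  expect_equal(optCost(computeDPTables(dup1)), 1)
  expect_equal(enumerateReconciliations(dup1)$minCost, 1)

  toy3 <- dtlFixture("toy3")
  expect_equal(optCost(computeDPTables(toy3)), 1)
  expect_equal(enumerateReconciliations(toy3)$minCost, 1)
})

test_that("DP tables satisfy their defining inequalities", {
  for (seed in c(1, 9, 27)) {
    inst <- randomDTLInstance(seed, 4, 4)
    tb <- computeDPTables(inst)
    # a loss chain can only help: descend <= placement cost everywhere
    expect_true(all(tb@descendCost <= tb@eventCost + 1e-12))
    # gene leaves place freely only at their mapped species leaf
    gt <- geneTree(inst); st <- speciesTree(inst)
    for (gl in which(gt$isLeaf)) {
      target <- which(st$label == leafMapping(inst)[[gt$label[gl]]])
      expect_equal(tb@eventCost[gl, target], 0)
      expect_true(all(is.infinite(tb@eventCost[gl, -target])))
    }
    expect_equal(tb@optCost, min(tb@eventCost[1L, ]))
  }
})

test_that("DP cost equals the brute-force minimum on random instances", {
  for (seed in 1:60) {
    inst <- randomDTLInstance(seed,
                              nSpeciesLeaves = 1L + seed %% 4L,
                              nGeneLeaves = 1L + (seed * 7L) %% 4L)
    expect_equal(optCost(computeDPTables(inst)),
                 enumerateReconciliations(inst)$minCost,
                 info = paste("seed", seed))
  }
})

test_that("graph traversals biject with the optimal mapping event sets", {
  for (seed in 1:40) {
    inst <- randomDTLInstance(seed + 1000L,
                              nSpeciesLeaves = 2L + seed %% 3L,
                              nGeneLeaves = 2L + (seed * 5L) %% 3L)
    g <- reconcile(inst)
    expect_identical(traversalEventSets(g), oracleOptimalEventSets(inst, g),
                     info = paste("seed", seed))
  }
})

test_that("single-leaf instance yields the one-node, one-C-event graph", {
  g <- reconcile(dtlFixture("leaf1"))
  expect_length(g@mapG, 1L)
  expect_length(g@evType, 1L)
  expect_equal(dtlclust:::.EVTYPES[g@evType], "C")
  expect_length(g@sources, 1L)
})

test_that("graph structure invariants hold on generated instances", {
  for (seed in c(3, 8, 21, 34, 55)) {
    inst <- randomDTLInstance(seed, 5, 5)
    g <- reconcile(inst)
    n <- speciesTree(inst)$nv
    m <- geneTree(inst)$nv
    # every event node's child arity matches its type
    arity <- (g@evC1 > 0L) + (g@evC2 > 0L)
    expect_true(all(arity[g@evType %in% c(1L, 2L, 3L)] == 2L))
    expect_true(all(arity[g@evType == 4L] == 1L))
    expect_true(all(arity[g@evType == 5L] == 0L))
    # every non-C mapping node has at least one event child, and the
    # topological order covers every node (all reachable from sources)
    nEvChildren <- diff(g@mapEvPtr)
    expect_true(all(nEvChildren >= 1L))
    expect_equal(sort(g@mapOrder), seq_along(g@mapG))
    # node and edge counts within a fixed small multiple of n^2 m
    nNodes <- length(g@mapG) + length(g@evType)
    nEdges <- length(g@mapEvIdx) + sum(g@evC1 > 0L) + sum(g@evC2 > 0L)
    expect_lt(nNodes, 4 * n^2 * m)
    expect_lt(nEdges, 4 * n^2 * m)
    # every traversal costs the optimum
    if (mprCount(g) <= 200) {
      costs <- vapply(enumerateTraversals(g, limit = 200), traversalCost,
                      numeric(1))
      expect_true(all(abs(costs - optCost(g)) < 1e-9))
    }
  }
})

test_that("results are invariant to child order in either tree", {
  for (seed in c(2, 6, 17)) {
    inst <- randomDTLInstance(seed, 4, 4)
    g <- reconcile(inst)
    st <- speciesTree(inst)
    gt <- geneTree(inst)
    swappedS <- dtlclust:::.swapChildren(st, which(!st$isLeaf))
    swappedG <- dtlclust:::.swapChildren(gt, which(!gt$isLeaf))
    inst2 <- DTLInstance(swappedS, swappedG, leafMapping(inst),
                         eventCosts(inst))
    g2 <- reconcile(inst2)
    expect_equal(optCost(g2), optCost(g))
    expect_equal(mprCount(g2), mprCount(g))
    expect_identical(graphEventKeys(g2, canonical = TRUE),
                     graphEventKeys(g, canonical = TRUE))
  }
})

test_that("inferEvents applies the event definitions directly", {
  toy3 <- dtlFixture("toy3")
  # species preorder: 1 = root, 2 = (A,B), 3 = A, 4 = B, 5 = C
  # gene preorder:    1 = root, 2 = a, 3 = c
  spec <- inferEvents(toy3, c(1L, 3L, 5L))
  expect_equal(spec$cost, 1) # one loss at the (A,B) vertex
  expect_setequal(dtlclust:::.EVTYPES[spec$events$type], c("S", "L", "C"))
  expect_equal(sum(spec$events$type == 4L), 1L)
  expect_equal(spec$events$s[spec$events$type == 4L], 2L)

  trans <- inferEvents(toy3, c(5L, 3L, 5L))
  expect_equal(trans$cost, 1)
  expect_setequal(dtlclust:::.EVTYPES[trans$events$type], c("T", "C"))

  leaf1 <- dtlFixture("leaf1")
  sc <- inferEvents(leaf1, 1L)
  expect_equal(sc$cost, 0)
  expect_true(all(sc$events$type == 5L))

  # phi with no child image at or below the root placement is invalid
  expect_error(inferEvents(toy3, c(4L, 3L, 5L)), "invalid")
})
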