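# Counting, supports, distances, medians, sampling, enumeration, closure and
# union over reconciliation subgraphs, all against the enumeration oracle.

test_that("toy3 statistics match the enumeration oracle exactly", {
  g <- reconcile(dtlFixture("toy3"))
  stats <- subgraphStats(g)
  oracle <- enumeratedStats(g)
  # three co-optimal reconciliations: speciation + loss, and a transfer from
  # either side of the donor/recipient tie
  expect_equal(stats@mprCount, 3)
  expect_equal(oracle$T, 3)
  nonC <- g@evType != 5L
  expect_equal(stats@support[nonC], oracle$support[nonC])
  expect_true(all(abs(stats@support[nonC] - 1 / 3) < 1e-12))
  expect_equal(stats@meanSupport, 1 / 3)
  expect_equal(stats@meanPairDist, 8 / 3)
  expect_equal(oracle$mu, 8 / 3)
  # C events sit in every MPR
  expect_true(all(stats@support[!nonC] == 1))
})

test_that("count, supports, distance and median match enumeration on random instances", {
  cases <- oracleInstances(25)
  expect_gte(length(cases), 25)
  for (cs in cases) {
    g <- cs$graph
    stats <- subgraphStats(g)
    oracle <- enumeratedStats(g)
    expect_identical(stats@mprCount, as.numeric(oracle$T))
    member <- !is.na(oracle$support)
    expect_equal(stats@eventCount[member], oracle$count[member])
    expect_equal(stats@support[member], oracle$support[member])
    expect_equal(stats@meanSupport, oracle$sigma, tolerance = 1e-12)
    expect_equal(stats@meanPairDist, oracle$mu, tolerance = 1e-9)
    med <- medianTraversal(g, stats = stats)
    pairDist <- function(a, b) length(a) + length(b) - 2 * sum(a %in% b)
    sets <- lapply(enumerateTraversals(g, limit = 500), function(t) t@eventNodes)
    medTotal <- sum(vapply(sets, function(b) pairDist(med@eventNodes, b),
                           numeric(1)))
    expect_equal(medTotal, oracle$medianTotal)
  }
})

test_that("supports stay in (0,1], below counts sum to T, costs are constant", {
  for (cs in oracleInstances(10)) {
    g <- cs$graph
    stats <- subgraphStats(g)
    sup <- stats@support[!is.na(stats@support)]
    expect_true(all(sup > 0 & sup <= 1))
    expect_equal(sum(stats@belowMap[g@sources]), stats@mprCount)
    set.seed(99)
    for (t in sampleTraversals(g, 20, stats = stats)) {
      expect_equal(traversalCost(t), optCost(g))
    }
  }
})

test_that("degenerate subgraphs: T = 1 means support 1, distance 0", {
  g <- reconcile(dtlFixture("dup1"))
  stats <- subgraphStats(g)
  expect_equal(stats@mprCount, 1)
  expect_true(all(stats@support[!is.na(stats@support)] == 1))
  expect_equal(stats@meanPairDist, 0)
  expect_equal(stats@meanSupport, 1)
  med <- medianTraversal(g)
  expect_identical(sort(med@eventNodes), which(fullSubgraph(g)@evMember))
  # leaf-only space: sigma defined as 1
  leafStats <- subgraphStats(reconcile(dtlFixture("leaf1")))
  expect_equal(leafStats@meanSupport, 1)
})

test_that("median tie-breaking is deterministic toward the smallest source", {
  g <- reconcile(dtlFixture("toy3"))
  med1 <- medianTraversal(g)
  med2 <- medianTraversal(g)
  expect_identical(med1@eventNodes, med2@eventNodes)
  # both transfer MPRs tie at total distance 5; the winner's root is the
  # canonically smallest source among the argmax
  expect_equal(med1@rootNode, min(g@sources[g@mapS[g@sources] != 1L]))
})

test_that("uniform sampling reproduces exact probabilities", {
  g <- reconcile(dtlFixture("dup1"))
  set.seed(5)
  s <- sampleTraversals(g, 10)
  expect_true(all(vapply(s, function(t)
    identical(t@eventNodes, s[[1]]@eventNodes), logical(1))))

  toyg <- reconcile(dtlFixture("toy3"))
  set.seed(11)
  draws <- sampleTraversals(toyg, 4000)
  ids <- vapply(draws, function(t) paste(t@eventNodes, collapse = ","),
                character(1))
  freq <- table(ids) / length(ids)
  expect_length(freq, 3L)
  # 99.99% binomial band around 1/3 at n = 4000
  band <- 3.89 * sqrt((1 / 3) * (2 / 3) / 4000)
  expect_true(all(abs(freq - 1 / 3) < band))
  expect_error(sampleTraversals(toyg, 0), "positive")
})

test_that("sampling is reproducible under a seed", {
  g <- reconcile(dtlFixture("toy3"))
  set.seed(123); a <- sampleTraversals(g, 50)
  set.seed(123); b <- sampleTraversals(g, 50)
  expect_identical(lapply(a, function(t) t@eventNodes),
                   lapply(b, function(t) t@eventNodes))
})

test_that("enumeration refuses above its limit and reports the count", {
  g <- reconcile(dtlFixture("toy3"))
  expect_length(enumerateTraversals(g), 3L)
  expect_error(enumerateTraversals(g, limit = 1), "3")
})

test_that("closure reconstructs the full graph from its sources", {
  g <- reconcile(dtlFixture("toy3"))
  full <- closureFrom(g, frontier = g@sources)
  expect_true(all(full@mapMember))
  expect_true(all(full@evMember))
  expect_equal(mprCount(full), 3)

  # prefix = one source plus its transfer event; only that traversal survives
  src <- g@sources[g@mapS[g@sources] == 5L] # the (root, C) source
  ev <- dtlclust:::.evChildrenOf(g, src)
  kids <- c(g@evC1[ev], g@evC2[ev])
  kids <- kids[kids > 0L]
  sub <- closureFrom(g, frontier = kids, prefixMap = src, prefixEv = ev)
  expect_equal(mprCount(sub), 1)
})

test_that("union preserves traversals of both parts and is idempotent", {
  cases <- oracleInstances(6, lo = 2, hi = 60)
  for (cs in cases) {
    g <- cs$graph
    init <- initialClusters(g, minClusters = 2L)
    cls <- clusters(init)
    if (length(cls) < 2L) next
    a <- cls[[1]]@subgraph
    b <- cls[[2]]@subgraph
    u <- graphUnion(a, b)
    expect_identical(graphUnion(a, a)@evMember, a@evMember)
    expect_gte(mprCount(u), max(mprCount(a), mprCount(b)))
    for (t in c(enumerateTraversals(a, limit = 100),
                enumerateTraversals(b, limit = 100))) {
      expect_true(containsTraversal(u, t))
    }
  }
  # subgraphs of different instances refuse to merge
  g1 <- reconcile(dtlFixture("toy3"))
  g2 <- reconcile(dtlFixture("dup1"))
  expect_error(graphUnion(fullSubgraph(g1), fullSubgraph(g2)), "different")
})
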