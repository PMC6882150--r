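# Subtraversal initialization, WAS/WAD linkage, agglomeration and the
# improvement diagnostics.

test_that("subtraversal levels grow from sources to complete traversals", {
  g <- reconcile(dtlFixture("toy3"))
  l0 <- subtraversalsAtLevel(g, 0L)
  expect_length(l0, length(g@sources))
  # deep enough levels hold exactly one complete traversal per MPR
  deep <- subtraversalsAtLevel(g, 5L)
  expect_length(deep, mprCount(g))
  expect_true(all(lengths(lapply(deep, `[[`, "frontier")) == 0L))

  single <- reconcile(dtlFixture("leaf1"))
  for (L in 0:3) expect_length(subtraversalsAtLevel(single, L), 1L)
})

test_that("initial clusters partition MPR space at every feasible level", {
  for (cs in oracleInstances(10, lo = 2, hi = 200)) {
    g <- cs$graph
    T <- mprCount(g)
    L <- 0L
    repeat {
      subs <- subtraversalsAtLevel(g, L)
      sizes <- vapply(subs, function(st)
        mprCount(closureFrom(g, st$frontier, st$map, st$ev)), numeric(1))
      expect_equal(sum(sizes), T, info = paste("level", L))
      if (length(subs) >= T || L > 15L) break
      L <- L + 1L
    }
  }
})

test_that("initialClusters finds the smallest level meeting the request", {
  g <- reconcile(dtlFixture("toy3"))
  init <- initialClusters(g, minClusters = 2L)
  expect_equal(init@level, 0L)
  expect_length(clusters(init), 3L) # one per source
  expect_true(all(vapply(clusters(init), mprCount, numeric(1)) == 1))

  # a single-source space gives one whole-space cluster for minClusters = 1
  gd <- reconcile(dtlFixture("dup1"))
  init1 <- initialClusters(gd, minClusters = 1L)
  expect_length(clusters(init1), 1L)
  expect_equal(mprCount(clusters(init1)[[1]]), mprCount(gd))

  # the strict cap refuses explosive levels and reports the counts
  big <- reconcile(dtlFixture("tie_grid")[[3]])
  expect_error(initialClusters(big, minClusters = 10L, cap = 10L,
                               strict = TRUE), "cap")
  fallback <- initialClusters(big, minClusters = 10L, cap = 10L)
  expect_lte(length(clusters(fallback)), 10L)
})

test_that("WAS and WAD follow their weighted-average definitions", {
  g <- reconcile(dtlFixture("toy3"))
  whole <- initialClusters(g, minClusters = 1L)
  # toy3 has 3 sources, so even minClusters = 1 yields singleton clusters;
  # build the one-cluster clustering explicitly
  full <- new("MPRCluster", subgraph = fullSubgraph(g),
              stats = subgraphStats(g))
  expect_equal(was(list(full)), 1 / 3)
  expect_equal(wad(list(full)), 8 / 3)

  singles <- clusters(initialClusters(g, minClusters = 3L))
  expect_equal(was(singles), 1.0)
  expect_equal(wad(singles), 0.0)
  # duplicating a cluster leaves the ratios unchanged
  expect_equal(was(c(singles, singles[1])), 1.0)
  expect_equal(wad(c(singles, singles[1])), 0.0)
})

test_that("candidate merges are evaluated on the union graph", {
  for (cs in oracleInstances(5, lo = 3, hi = 80)) {
    g <- cs$graph
    cls <- clusters(initialClusters(g, minClusters = 3L))
    if (length(cls) < 2L) next
    for (i in 1:(length(cls) - 1)) {
      for (j in (i + 1):length(cls)) {
        u <- graphUnion(cls[[i]], cls[[j]])
        st <- subgraphStats(u)
        oracle <- enumeratedStats(u)
        expect_equal(st@mprCount, as.numeric(oracle$T))
        expect_equal(st@meanSupport, oracle$sigma, tolerance = 1e-12)
        expect_equal(st@meanPairDist, oracle$mu, tolerance = 1e-9)
      }
    }
  }
})

test_that("agglomeration on toy3 reproduces the hand-checked trajectory", {
  g <- reconcile(dtlFixture("toy3"))
  init <- initialClusters(g, minClusters = 2L)
  h <- agglomerate(init, criterion = "support", keepK = 2L)
  expect_s4_class(h, "MergeHistory")
  expect_equal(h@initialN, 3L)
  expect_equal(nrow(h@merges), 2L)
  expect_equal(h@perK$was[h@perK$k == 3], 1.0)
  expect_equal(h@perK$was[h@perK$k == 2], 2 / 3)
  expect_equal(h@perK$was[h@perK$k == 1], 1 / 3)
  expect_equal(improvement(h, 1), 1.0)
  expect_equal(improvement(h, 2), 2.0)
  expect_equal(localImprovement(h, 2), 2.0)
  expect_equal(localImprovement(h, 3), 2.0)
  # singleton-heavy clusterings have WAD 0, so distance improvement is Inf
  expect_equal(improvement(h, 3, criterion = "distance"), Inf)
  # retained k = 2 snapshot is consistent with the recorded statistics
  kept <- h@kept[["2"]]
  expect_length(clusters(kept), 2L)
  expect_equal(was(kept), 2 / 3)
})

test_that("a two-cluster clustering merges once into a superset", {
  g <- reconcile(dtlFixture("tie_grid")[[2]])
  init <- initialClusters(g, minClusters = 2L)
  expect_length(clusters(init), 2L)
  h <- agglomerate(init, criterion = "distance", keepK = 1L)
  expect_equal(nrow(h@merges), 1L)
  final <- clusters(h@kept[["1"]])[[1]]
  for (cl in clusters(init)) {
    for (t in enumerateTraversals(cl, limit = 50)) {
      expect_true(containsTraversal(final, t))
    }
  }
})

test_that("agglomeration is deterministic and respects timeouts", {
  inst <- randomDTLInstance(6, 4, 4, costGrid = list(c(1, 1, 1)))
  g <- reconcile(inst)
  init <- initialClusters(g, minClusters = 4L)
  h1 <- agglomerate(init, "distance")
  h2 <- agglomerate(init, "distance")
  expect_identical(h1@merges, h2@merges)
  expect_identical(h1@perK, h2@perK)
  expect_true(h1@complete)

  ht <- agglomerate(init, "distance", timeout = 0)
  expect_false(ht@complete)
  expect_lt(nrow(ht@merges), length(clusters(init)) - 1L)
  expect_error(improvement(ht, 2), "incomplete")
})

test_that("local improvements are positive; identical merges give 1", {
  g <- reconcile(dtlFixture("toy3"))
  cls <- clusters(initialClusters(g, minClusters = 3L))
  # two copies of the same cluster: merging changes nothing
  h <- agglomerate(new("MPRClustering", clusters = c(cls[1], cls[1]),
                       level = 0L), criterion = "support")
  expect_equal(localImprovement(h, 2), 1.0)
  for (cs in oracleInstances(4, lo = 3, hi = 50)) {
    hh <- agglomerate(initialClusters(cs$graph, minClusters = 2L), "support")
    for (k in hh@merges$k) {
      expect_gt(localImprovement(hh, k), 0)
    }
  }
})

test_that("merge history serializes to JSON/CSV and parses back", {
  g <- reconcile(dtlFixture("toy3"))
  h <- agglomerate(initialClusters(g, minClusters = 2L), "support")
  jf <- tempfile(fileext = ".json")
  cf <- tempfile(fileext = ".csv")
  writeMergeHistory(h, jsonFile = jf, csvFile = cf)
  back <- readMergeHistory(jf)
  expect_equal(back@initialN, h@initialN)
  expect_equal(back@criterion, h@criterion)
  expect_equal(back@perK$was, h@perK$was)
  expect_equal(back@perK$wad, h@perK$wad)
  expect_equal(back@merges$localWAS, h@merges$localWAS)
  expect_equal(back@merges$localWAD, h@merges$localWAD)
  csv <- utils::read.csv(cf, stringsAsFactors = FALSE)
  expect_equal(csv$k, sort(h@perK$k, decreasing = TRUE))
  expect_equal(csv$WAS, h@perK$was[order(-h@perK$k)])
  # the all-singleton row has WAD 0 hence an "inf" distance improvement is
  # never emitted for the support criterion; improvements are numeric here
  expect_equal(as.numeric(csv$improvement[csv$k == 2]), 2.0)
})
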