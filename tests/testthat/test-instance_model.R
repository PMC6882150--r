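# Trees, leaf mappings and instance validation.

test_that("Newick parsing builds rooted binary trees and rejects others", {
  tr <- readNewickTree(text = "(A,B);")
  expect_equal(tr$nTips, 2L)
  expect_equal(tr$nv, 3L)
  expect_setequal(treeLeaves(tr), c("A", "B"))

  cat3 <- readNewickTree(text = "((A,B),C);")
  expect_equal(cat3$nTips, 3L)
  expect_equal(cat3$nv, 5L)
  # root children: the (A,B) clade and the leaf C
  rootKids <- cat3$children[1L, ]
  kidClades <- sort(cat3$clade[rootKids])
  expect_equal(kidClades, c("A|B", "C"))

  expect_error(readNewickTree(text = "(A,B,C);"), "not binary")
  expect_error(readNewickTree(text = "((A,B);"), "malformed")
  expect_error(readNewickTree(text = ""), "malformed")

  single <- readNewickTree(text = "A;")
  expect_equal(single$nv, 1L)
  expect_equal(treeLeaves(single), "A")
})

test_that("branch lengths are parsed and discarded", {
  tr <- readNewickTree(text = "((A:0.1,B:0.2):0.3,C:0.4);")
  expect_equal(tr$nTips, 3L)
  expect_equal(writeNewickTree(tr), "((A,B),C);")
})

test_that("Newick round-trip preserves topology and labels", {
  for (seed in 1:15) {
    inst <- randomDTLInstance(seed, nSpeciesLeaves = 2 + seed %% 7,
                              nGeneLeaves = 2 + (seed * 3) %% 7)
    for (tr in list(speciesTree(inst), geneTree(inst))) {
      back <- readNewickTree(text = writeNewickTree(tr))
      expect_equal(sort(back$clade), sort(tr$clade))
      expect_equal(back$nv, 2L * back$nTips - 1L)
    }
  }
})

test_that("leaf mappings parse, reject duplicates, allow non-injectivity", {
  expect_equal(readLeafMapping(text = "a\tA\nb\tB\n"),
               c(a = "A", b = "B"))
  expect_error(readLeafMapping(text = "a\tA\na\tB\n"), "duplicate gene leaf")
  # many-to-one is legitimate: the map need not be one-to-one nor onto
  expect_equal(readLeafMapping(text = "a\tA\nc\tA\n"), c(a = "A", c = "A"))
  # comments and blank lines ignored
  expect_equal(readLeafMapping(text = "# header\n\na\tA\n"), c(a = "A"))
  expect_error(readLeafMapping(text = "a A\n"), "tab-separated")
})

test_that("instance validation reports each violated invariant", {
  expect_silent(validateInstance(dtlFixture("toy3")))
  expect_error(
    DTLInstance("((A,B),C);", "(a,c);", c(a = "A"), c(1, 1, 1)),
    "missing gene leaf.*c")
  expect_error(
    DTLInstance("((A,B),C);", "(a,c);", c(a = "A", c = "Z"), c(1, 1, 1)),
    "not a species leaf.*Z")
  expect_error(
    DTLInstance("((A,B),C);", "(a,c);", c(a = "A", c = "C"), c(1, 1, -1)),
    "non-negative")
})

test_that("every parsed tree has 2L-1 vertices", {
  for (txt in c("(A,B);", "((A,B),C);", "(((A,B),(C,D)),E);", "A;")) {
    tr <- readNewickTree(text = txt)
    expect_equal(tr$nv, 2L * tr$nTips - 1L)
  }
})
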