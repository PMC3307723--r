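test_that("two-leaf trees score as the pairwise edit distance", {
  phy <- readNewick(text = "(a,b);")
  seqs <- c(a = "ACGTT", b = "AGT")
  for (m in c("lifted", "do", "exact")) {
    ta <- scoreFixedTree(phy, seqs, costPreset("affine"), method = m)
    expect_equal(
      treelength(ta),
      editDistance(seqs["a"], seqs["b"], costPreset("affine"))
    )
    expect_equal(recomputeTreelength(ta), treelength(ta))
  }
})

test_that("identical leaf sequences give treelength zero everywhere", {
  phy <- readNewick(text = "((a,b),(c,d),e);")
  seqs <- stats::setNames(rep("ACGTACGT", 5), letters[1:5])
  for (m in c("lifted", "do")) {
    ta <- scoreFixedTree(phy, seqs, costPreset("simple2"), method = m)
    expect_identical(treelength(ta), 0)
    expect_true(all(nodeSequences(ta) == "ACGTACGT"))
  }
})

test_that("lifted labelings use leaf sequences and are DP-optimal on stars", {
  sch <- costPreset("affine")
  withr::with_seed(211, {
    for (i in 1:10) {
      inst <- randomInstance(n = sample(4:8, 1), len = 12, seed = i)
      ta <- liftedAssignment(inst$tree, inst$seqs, sch)
      nt <- length(inst$seqs)
      internal <- nodeSequences(ta)[-seq_len(nt)]
      expect_true(all(internal %in% inst$seqs))
      expect_equal(recomputeTreelength(ta), treelength(ta))
    }
  })
  # 3-leaf star: the center is the leaf minimizing the distance sum
  star <- readNewick(text = "(a,b,c);")
  seqs <- c(a = "ACGT", b = "ACGA", c = "TTTT")
  ta <- liftedAssignment(star, seqs, sch)
  byHand <- min(vapply(seqs, function(s) {
    sum(vapply(seqs, function(t) editDistance(s, t, sch), numeric(1)))
  }, numeric(1)))
  expect_equal(treelength(ta), byHand)
})

test_that("direct-optimization pass is sound and competitive with lifted", {
  sch <- costPreset("affine")
  cherry <- readNewick(text = "((a,b),(c,d));")
  seqs <- c(a = "ACGT", b = "ACGT", c = "TTTT", d = "TTTT")
  ta <- doAssignment(cherry, seqs, sch)
  internal <- nodeSequences(ta)[-(1:4)]
  expect_true("ACGT" %in% internal && "TTTT" %in% internal)
  expect_equal(treelength(ta), editDistance("ACGT", "TTTT", sch))

  worse <- 0
  withr::with_seed(223, {
    for (i in 1:30) {
      inst <- randomInstance(n = sample(5:8, 1), len = 15, seed = 1000 + i)
      tl_do <- treelength(doAssignment(inst$tree, inst$seqs, sch))
      tl_lift <- treelength(liftedAssignment(inst$tree, inst$seqs, sch))
      expect_lte(tl_do, 1.1 * tl_lift)
      if (tl_do > tl_lift) worse <- worse + 1
      a <- doAssignment(inst$tree, inst$seqs, sch)
      expect_equal(recomputeTreelength(a), treelength(a))
    }
  })
})

test_that("exact enumeration dominates the heuristics on tiny instances", {
  sch <- costPreset("simple1")
  star <- readNewick(text = "(a,b,c);")
  te <- exactAssignment(star, c(a = "A", b = "A", c = "G"), sch, maxLen = 1)
  expect_identical(treelength(te), 1)
  expect_identical(unname(nodeSequences(te)[4]), "A")

  withr::with_seed(227, {
    for (i in 1:12) {
      inst <- randomInstance(n = sample(4:5, 1), len = sample(2:4, 1),
        seed = 2000 + i)
      for (sch in list(costPreset("simple1"), costPreset("affine"))) {
        tle <- treelength(exactAssignment(inst$tree, inst$seqs, sch))
        expect_lte(tle, treelength(liftedAssignment(inst$tree, inst$seqs, sch)))
        expect_lte(tle, treelength(doAssignment(inst$tree, inst$seqs, sch)))
      }
    }
  })
  expect_error(
    exactAssignment(
      randomBinaryTree(paste0("t", 1:7), seed = 1),
      randomSeqs(7, 3), costPreset("simple1")
    ),
    "at most"
  )
})

test_that("the gap-forbidden limit reproduces per-site Sankoff parsimony", {
  mp <- costPreset("mp")
  withr::with_seed(229, {
    for (i in 1:8) {
      n <- sample(4:5, 1)
      inst <- randomInstance(n = n, len = 3, seed = 3000 + i)
      tle <- treelength(exactAssignment(inst$tree, inst$seqs, mp, maxLen = 3))
      expect_identical(tle, sankoffParsimony(inst$tree, inst$seqs, mp))
    }
  })
})

test_that("the in-suite Sankoff oracle agrees with phangorn", {
  skip_if_not_installed("phangorn")
  withr::with_seed(233, {
    for (i in 1:5) {
      n <- sample(5:9, 1)
      inst <- randomInstance(n = n, len = 12, seed = 4000 + i)
      sch <- costPreset("mp")
      S <- outer(BASES, BASES, function(x, y) {
        mapply(function(a, b) substitutionCost(sch, a, b), x, y)
      })
      dimnames(S) <- list(tolower(BASES), tolower(BASES))
      dat <- phangorn::phyDat(
        do.call(rbind, strsplit(unname(inst$seqs[inst$tree$tip.label]), ""))
      )
      names(dat) <- inst$tree$tip.label
      ps <- phangorn::parsimony(inst$tree, dat, method = "sankoff", cost = S)
      expect_equal(sankoffParsimony(inst$tree, inst$seqs, sch), as.numeric(ps))
    }
  })
})

test_that("scoring validates its inputs", {
  phy <- readNewick(text = "((a,b),(c,d));")
  expect_error(
    scoreFixedTree(phy, c(a = "A", b = "A", c = "A"), costPreset("simple1")),
    "bijectively"
  )
  expect_error(
    scoreFixedTree(phy, c(a = "A-", b = "A", c = "A", d = "T"),
      costPreset("simple1")
    ),
    "illegal"
  )
})
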