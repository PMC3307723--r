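test_that("NJ starting trees are deterministic and recover additive signal", {
  sch <- costPreset("simple1")
  seqs3 <- c(a = "ACGT", b = "ACGA", c = "TTTT")
  expect_setequal(njStartTree(seqs3, sch)$tip.label, c("a", "b", "c"))
  expect_length(internalEdges(njStartTree(seqs3, sch)), 0L)

  # disjoint diagnostic sites make the quartet distances exactly additive
  seqs <- c(
    a = "AAAAAAAAAACCCCC",
    b = "AAAAAAAAAAGGGGG",
    c = "TTTTTTTTTTCCCCC",
    d = "TTTTTTTTTTGGGGG"
  )
  nj <- njStartTree(seqs, sch)
  expect_setequal(bipartitions(nj), bipartitions(readNewick(
    text = "((a,b),(c,d));"
  )))
  expect_identical(writeNewick(njStartTree(seqs, sch)), writeNewick(nj))
  expect_error(njStartTree(seqs3[1:2], sch), "at least 3")
})

test_that("the pool winner is minimal and never longer than any start", {
  sch <- costPreset("affine")
  withr::with_seed(521, {
    for (i in 1:10) {
      inst <- randomInstance(n = 7, len = 20, seed = 9000 + i)
      start <- randomBinaryTree(names(inst$seqs))
      res <- beetleSearch(inst$seqs, sch,
        startingTrees = list(start), seed = i
      )
      tl <- treelength(res$pool)
      expect_equal(treelength(res$best), min(tl))
      expect_lte(treelength(res$best), tl[1]) # the supplied start
      expect_length(tl, 21L) # 1 start + 20 neighbors
      expect_lte(normalizedScore(res$pool), 1)
    }
  })
})

test_that("search is a pure function of inputs and seed", {
  inst <- randomInstance(n = 6, len = 15, seed = 9501)
  sch <- costPreset("simple2")
  start <- randomBinaryTree(names(inst$seqs), seed = 4)
  r1 <- beetleSearch(inst$seqs, sch, list(start), seed = 99)
  r2 <- beetleSearch(inst$seqs, sch, list(start), seed = 99)
  expect_identical(poolSummary(r1$pool), poolSummary(r2$pool))
  expect_identical(
    writeNewick(r1$best@assignment@tree), writeNewick(r2$best@assignment@tree)
  )
})

test_that("enlarging the pool never increases the winning treelength", {
  inst <- randomInstance(n = 7, len = 18, seed = 9601)
  sch <- costPreset("simple1")
  start <- randomBinaryTree(names(inst$seqs), seed = 5)
  small <- beetleSearch(inst$seqs, sch, list(start), seed = 7)
  extra <- randomBinaryTree(names(inst$seqs), seed = 6)
  big <- beetleSearch(inst$seqs, sch, list(start, extra), seed = 7)
  expect_lte(treelength(big$best), treelength(small$best))
})

test_that("a supplied optimal tree is never degraded by the search", {
  # leaves built around two anchor haplotypes so the optimum is a lifted
  # labeling: the exact and lifted scores coincide on the generating tree
  sch <- costPreset("simple1")
  seqs <- c(a = "AAAA", b = "AAAT", c = "GGGG", d = "GGGC")
  gen <- readNewick(text = "((a,b),(c,d));")
  exact <- exactAssignment(gen, seqs, sch, maxLen = 4)
  lifted <- liftedAssignment(gen, seqs, sch)
  expect_equal(treelength(exact), treelength(lifted))
  res <- beetleSearch(seqs, sch, list(gen), seed = 11)
  expect_equal(treelength(res$best), treelength(exact))
})

test_that("normalized scores behave as ratios against the baseline", {
  inst <- randomInstance(n = 6, len = 12, seed = 9701)
  sch <- costPreset("affine")
  res <- beetleSearch(inst$seqs, sch,
    list(randomBinaryTree(names(inst$seqs), seed = 8)),
    seed = 12
  )
  base <- res$pool@scored[[res$pool@baselineIndex]]
  expect_identical(normalizedScore(res$pool, base), 1)
  expect_lte(normalizedScore(res$pool), 1)
  ps <- poolSummary(res$pool)
  expect_identical(
    ps$normalized_score, ps$treelength / ps$treelength[1]
  )

  same <- stats::setNames(rep("ACGT", 4), letters[1:4])
  rs <- beetleSearch(same, sch,
    list(randomBinaryTree(letters[1:4], seed = 9)),
    seed = 13
  )
  expect_warning(out <- normalizedScore(rs$pool), "baseline treelength is 0")
  expect_true(is.nan(out))
})
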