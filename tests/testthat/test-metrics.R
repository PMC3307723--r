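canonical <- function(sides, labs) {
  anchor <- min(labs)
  vapply(sides, function(s) {
    if (!(anchor %in% s)) s <- setdiff(labs, s)
    paste(sort(s), collapse = "|")
  }, character(1))
}

test_that("bipartition extraction matches manual enumeration", {
  expect_length(bipartitions(readNewick(text = "(a,b,c,d,e);")), 0L)
  phy <- randomBinaryTree(paste0("t", 1:11), seed = 31)
  expect_length(bipartitions(phy), 11L - 3L)
  expect_setequal(
    bipartitions(readNewick(text = "((a,b),(c,d),e);")),
    canonical(list(c("a", "b"), c("c", "d")), letters[1:5])
  )
})

test_that("missing branch rate reproduces the hand-enumerated cases", {
  ref <- readNewick(text = "((a,b),(c,d),e);")
  expect_identical(missingBranchRate(ref, ref), 0)
  expect_identical(
    missingBranchRate(ref, readNewick(text = "(a,b,c,d,e);")), 1
  )
  expect_identical(
    missingBranchRate(ref, readNewick(text = "((a,c),(b,d),e);")), 1
  )
  expect_identical(
    missingBranchRate(ref, readNewick(text = "((a,b),c,(d,e));")), 0.5
  )
  expect_error(
    missingBranchRate(ref, readNewick(text = "((a,b),(c,f),e);")),
    "leaf set"
  )
  expect_warning(
    out <- missingBranchRate(
      readNewick(text = "(a,b,c,d);"), readNewick(text = "((a,b),(c,d));")
    ),
    "no internal edges"
  )
  expect_true(is.nan(out))
})

test_that("for binary trees the FN rate equals the normalized RF distance", {
  skip_if_not_installed("phangorn")
  withr::with_seed(433, {
    for (i in 1:20) {
      n <- sample(5:25, 1)
      a <- randomBinaryTree(paste0("t", 1:n))
      b <- pEcr(a, sample(1:3, 1))
      fn <- length(setdiff(bipartitions(a), bipartitions(b)))
      fp <- length(setdiff(bipartitions(b), bipartitions(a)))
      expect_identical(fn, fp) # symmetric difference halves coincide
      expect_equal(rfDistance(a, b), as.numeric(phangorn::RF.dist(a, b)))
      expect_equal(missingBranchRate(a, b), fn / (n - 3))
    }
  })
})

test_that("SP-FN matches brute-force homology-pair enumeration", {
  ref <- alignmentMatrix(c("a", "b", "c"), c("ACG", "A-G", "ACG"))
  expect_identical(spFN(ref, ref), 0)

  est <- alignmentMatrix(c("a", "b", "c"), c("ACG-", "A--G", "ACG-"))
  want <- 1 - length(intersect(homologyPairSet(est), homologyPairSet(ref))) /
    length(homologyPairSet(ref))
  expect_equal(spFN(ref, est), want)

  # an estimate placing every residue in its own column shares no pairs
  lone <- alignmentMatrix(
    c("a", "b", "c"),
    c("ACG-----", "---AG---", "-----ACG")
  )
  expect_identical(spFN(ref, lone), 1)

  expect_error(
    spFN(ref, alignmentMatrix(c("a", "b", "c"), c("ACG", "AAG", "ACG"))),
    "identical sequences"
  )
  withr::with_seed(439, {
    for (i in 1:10) {
      inst <- randomInstance(n = 4, len = 8, seed = 8000 + i)
      ta <- scoreFixedTree(inst$tree, inst$seqs, costPreset("affine"))
      a1 <- impliedAlignment(ta)
      a2 <- impliedAlignment(
        scoreFixedTree(inst$tree, inst$seqs, costPreset("simple1"),
          method = "do")
      )
      want <- 1 -
        length(intersect(homologyPairSet(a2), homologyPairSet(a1))) /
          length(homologyPairSet(a1))
      expect_equal(spFN(a1, a2), want)
    }
  })
})

test_that("majority consensus keeps exactly the >50% splits", {
  t1 <- readNewick(text = "((a,b),(c,d),e);")
  expect_setequal(
    bipartitions(majorityConsensus(list(t1, t1, t1))), bipartitions(t1)
  )
  expect_setequal(
    bipartitions(majorityConsensus(list(t1))), bipartitions(t1)
  )
  t2 <- readNewick(text = "((a,b),c,(d,e));")
  t3 <- readNewick(text = "((a,b),(c,e),d);")
  cons <- majorityConsensus(list(t1, t2, t3))
  expect_identical(
    bipartitions(cons), canonical(list(c("a", "b")), letters[1:5])
  )
  expect_error(
    majorityConsensus(list(t1, readNewick(text = "((a,b),(c,f),e);"))),
    "leaf set"
  )
})

test_that("majority consensus agrees with ape on random tree sets", {
  withr::with_seed(443, {
    for (i in 1:8) {
      n <- sample(6:15, 1)
      base <- randomBinaryTree(paste0("t", 1:n))
      trees <- c(
        list(base),
        lapply(1:4, function(j) pEcr(base, sample(1:3, 1)))
      )
      mine <- majorityConsensus(trees)
      apecons <- ape::consensus(trees, p = 0.5)
      expect_setequal(bipartitions(mine), bipartitions(apecons))
      # consensus splits are realized jointly in one tree, hence compatible
      expect_length(
        setdiff(bipartitions(mine), bipartitions(mine)), 0L
      )
    }
  })
})
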