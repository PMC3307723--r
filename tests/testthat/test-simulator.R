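modelTree <- function(text = "((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1,e:0.3);") {
  readNewick(text = text)
}

test_that("degenerate rate settings produce the forced outcomes", {
  # no indels: gapless alignment, equal-length rows
  rec <- evolveSequences(
    modelTree(), simParams(rootLength = 200, indelRate = 0), seed = 1
  )
  expect_false(any(grepl("-", alnRows(rec@trueAlignment), fixed = TRUE)))
  expect_length(unique(nchar(rec@leafSeqs)), 1L)

  # zero-length branches: no events anywhere, star reference tree
  frozen <- evolveSequences(
    modelTree("((a:0,b:0):0,(c:0,d:0):0,e:0);"),
    simParams(rootLength = 100), seed = 2
  )
  expect_length(unique(frozen@leafSeqs), 1L)
  expect_true(all(frozen@branchEvents$substitutions == 0))
  expect_true(all(frozen@branchEvents$indels == 0))
  expect_length(bipartitions(frozen@referenceTree), 0L)
  expect_identical(empiricalStats(frozen)$resolution, 0)

  # indels without substitutions: gaps appear, residue columns are uniform
  pure <- evolveSequences(
    modelTree(),
    simParams(rootLength = 300, substitutionRate = 0, indelRate = 0.1),
    seed = 3
  )
  m <- as.matrix(pure@trueAlignment)
  expect_gt(mean(m == "-"), 0)
  uniform <- apply(m, 2, function(col) {
    r <- col[col != "-"]
    length(unique(r)) == 1
  })
  expect_true(all(uniform))
})

test_that("rows of the true alignment degap to the leaf sequences", {
  rec <- evolveSequences(
    modelTree(), simParams(rootLength = 150, preset = "long"), seed = 5
  )
  rows <- alnRows(rec@trueAlignment)
  expect_identical(gsub("-", "", rows[names(rec@leafSeqs)]), rec@leafSeqs)
  # and the true alignment is feasible for every leaf pair
  sch <- costPreset("affine")
  taxa <- alnTaxa(rec@trueAlignment)
  for (t2 in taxa[-1]) {
    pr <- projectRows(rec@trueAlignment, taxa[1], t2)
    expect_gte(
      alignmentCost(pr$a, pr$b, sch) + 1e-9,
      editDistance(rec@leafSeqs[[taxa[1]]], rec@leafSeqs[[t2]], sch)
    )
  }
})

test_that("reference trees only contract zero-event internal branches", {
  withr::with_seed(607, {
    for (i in 1:8) {
      tr <- randomBinaryTree(paste0("t", 1:8))
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.01, 0.3)
      rec <- evolveSequences(tr, simParams(rootLength = 60), seed = 700 + i)
      expect_true(
        all(bipartitions(rec@referenceTree) %in% bipartitions(rec@modelTree))
      )
      zero <- with(
        rec@branchEvents,
        substitutions == 0 & indels == 0 &
          rec@branchEvents$child > length(rec@modelTree$tip.label)
      )
      expect_length(
        bipartitions(rec@referenceTree),
        length(bipartitions(rec@modelTree)) - sum(zero)
      )
    }
  })
})

test_that("one zero-event internal edge yields one degree-4 polytomy", {
  tr <- readNewick(text = "(((a:1,b:1):1,c:1):1,(d:1,e:1):1);")
  phy <- ape::unroot(tr)
  ev <- data.frame(
    parent = phy$edge[, 1], child = phy$edge[, 2],
    substitutions = 1L, indels = 0L
  )
  internal <- internalEdges(phy)
  ev$substitutions[internal[1]] <- 0L
  ref <- contractZeroEventBranches(phy, ev)
  expect_length(bipartitions(ref), 1L)
  degrees <- tabulate(as.vector(ref$edge))
  expect_identical(max(degrees), 4L)
  n <- length(ref$tip.label)
  expect_equal(length(internalEdges(ref)) / (n - 3), 0.5)
})

test_that("observed gap lengths recover the geometric mean", {
  p <- 0.45
  rec <- evolveSequences(
    randomBinaryTree(paste0("t", 1:8), seed = 11) |>
      (\(t) {
        t$edge.length <- rep(0.25, nrow(t$edge))
        t
      })(),
    simParams(
      rootLength = 6000, substitutionRate = 0.2, indelRate = 0.03,
      gapLengthModel = gapLengthModel("geometric", p = p)
    ),
    seed = 12
  )
  m <- as.matrix(rec@trueAlignment) == "-"
  runs <- unlist(apply(m, 1, function(r) {
    rl <- rle(r)
    rl$lengths[rl$values]
  }), use.names = FALSE)
  expect_gt(length(runs), 1000L)
  se <- stats::sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - 1 / p), 3 * se)
})

test_that("gap-length presets are stochastically ordered short < medium < long", {
  meanGap <- function(preset, seed) {
    rec <- evolveSequences(
      modelTree(), simParams(rootLength = 800, preset = preset, indelRate = 0.05),
      seed = seed
    )
    empiricalStats(rec)$avg_gap_length
  }
  withr::with_seed(613, {
    s <- mean(vapply(1:4, function(i) meanGap("short", 800 + i), numeric(1)))
    m <- mean(vapply(1:4, function(i) meanGap("medium", 900 + i), numeric(1)))
    l <- mean(vapply(1:4, function(i) meanGap("long", 1000 + i), numeric(1)))
  })
  expect_lt(s, m)
  expect_lt(m, l)
})

test_that("empirical statistics match direct counts on a toy record", {
  tr <- readNewick(text = "(a:1,b:1);")
  rec <- new("SimulationRecord",
    modelTree = tr,
    leafSeqs = c(a = "ACG", b = "ACTG"),
    trueAlignment = alignmentMatrix(c("a", "b"), c("AC-G", "ACTG")),
    branchEvents = data.frame(
      parent = c(3L, 3L), child = c(1L, 2L),
      substitutions = c(0L, 1L), indels = c(1L, 0L),
      pdist = c(0, 0), sharedSites = c(3L, 4L)
    ),
    referenceTree = tr,
    params = simParams(rootLength = 4)
  )
  st <- empiricalStats(rec)
  expect_equal(st$gap_percent, 100 * 1 / 8)
  expect_identical(st$columns, 4L)
  expect_equal(st$avg_gap_length, 1)
  expect_equal(st$median_gap_length, 1)
  expect_equal(st$max_gap_length, 1)
  expect_equal(st$setwise_avg_pdist, 1 / 4) # T/- column counts as a mismatch
})

test_that("the simulator validates branch lengths and is seed-reproducible", {
  bad <- modelTree()
  bad$edge.length[1] <- -0.1
  expect_error(
    evolveSequences(bad, simParams(rootLength = 50), seed = 1), "nonnegative"
  )
  noLen <- readNewick(text = "((a,b),(c,d),e);")
  expect_error(
    evolveSequences(noLen, simParams(rootLength = 50), seed = 1),
    "branch length"
  )
  r1 <- evolveSequences(modelTree(), simParams(rootLength = 100), seed = 42)
  r2 <- evolveSequences(modelTree(), simParams(rootLength = 100), seed = 42)
  expect_identical(alnRows(r1@trueAlignment), alnRows(r2@trueAlignment))
  expect_identical(r1@branchEvents, r2@branchEvents)
})
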