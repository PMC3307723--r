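#' Neighbor-joining starting tree from edit distances
#'
#' Builds the all-pairs [editDistanceMatrix()] of the input sequences and
#' runs neighbor joining on it. Taxa are processed in sorted label order so
#' the result is deterministic. Serves as an internal baseline/starting
#' tree for [beetleSearch()] when no externally estimated tree is supplied.
#'
#' @param seqs named character vector of at least 3 gap-free sequences
#' @param scheme a [CostScheme-class]
#' @return a binary unrooted `phylo` object
#' @export
njStartTree <- function(seqs, scheme) {
  .validateSeqs(seqs, aligned = FALSE, ambiguity = TRUE)
  if (length(seqs) < 3) stop("need at least 3 sequences")
  seqs <- seqs[order(names(seqs))]
  D <- editDistanceMatrix(seqs, scheme = scheme)
  if (any(!is.finite(D))) {
    stop("edit distances are not all finite under this scheme")
  }
  if (length(seqs) == 3) {
    return(readNewick(text = paste0(
      "(", paste(names(seqs), collapse = ","), ");"
    )))
  }
  .asUnrooted(ape::nj(D))
}

#' Candidate-pool treelength search
#'
#' Assembles a candidate pool from the supplied starting trees (plus
#' optional internal baselines), augments each starting tree with `neighbors`
#' random p-ECR neighbors (`p` drawn uniformly from 1 to `min(pMax, n-3)`),
#' scores every pool member with [scoreFixedTree()], and returns the tree
#' with the shortest treelength together with the full scored pool. Because
#' every starting tree is itself in the pool, the winner's treelength is
#' never longer than any supplied starting tree's: seeding the search with
#' another method's tree guarantees a result at least as short.
#'
#' @param seqs named character vector of gap-free sequences
#' @param scheme a [CostScheme-class]
#' @param startingTrees list of `phylo` starting trees (may be empty when an
#'   internal baseline is requested)
#' @param seed integer seed for the p-ECR moves, or `NULL`
#' @param method pool scoring method, `"lifted"` (default) or `"do"`
#' @param neighbors p-ECR neighbors drawn per starting tree
#' @param pMax largest p-ECR move considered
#' @param njBaseline add the [njStartTree()] as an internal baseline
#' @param randomBaselines number of random binary trees to add as baselines
#' @param baselineIndex pool index used as the normalization baseline
#'   (default 1: the first starting tree plays the external reference's role)
#' @return list with elements `best` (a [ScoredTree-class]) and `pool`
#'   (a [CandidatePool-class])
#' @examples
#' seqs <- c(a = "ACGTACGT", b = "ACGTACGA", c = "TTGTACGT", d = "TTGTACGA")
#' res <- beetleSearch(seqs, costPreset("simple1"),
#'   njBaseline = TRUE, seed = 1
#' )
#' treelength(res$best)
#' @export
beetleSearch <- function(seqs, scheme, startingTrees = list(), seed = NULL,
                         method = c("lifted", "do"), neighbors = 20L,
                         pMax = 5L, njBaseline = FALSE, randomBaselines = 0L,
                         baselineIndex = 1L) {
  method <- match.arg(method)
  .validateSeqs(seqs, aligned = FALSE, ambiguity = TRUE)
  if (inherits(startingTrees, "phylo")) startingTrees <- list(startingTrees)
  starts <- list()
  origins <- character(0)
  for (t in startingTrees) {
    stopifnot(inherits(t, "phylo"))
    starts <- c(starts, list(t))
    origins <- c(origins, "supplied")
  }
  .withSeed(seed, {
    if (njBaseline) {
      starts <- c(starts, list(njStartTree(seqs, scheme)))
      origins <- c(origins, "nj_baseline")
    }
    if (randomBaselines > 0) {
      for (i in seq_len(randomBaselines)) {
        starts <- c(starts, list(.randomBinaryTreeImpl(names(seqs))))
        origins <- c(origins, "random_baseline")
      }
    }
    if (length(starts) == 0) {
      stop("no starting trees: supply trees or request a baseline")
    }
    for (t in starts) .checkLeafMatch(t, seqs)
    pool <- list()
    poolOrigins <- character(0)
    for (i in seq_along(starts)) {
      pool <- c(pool, list(starts[[i]]))
      poolOrigins <- c(poolOrigins, origins[i])
      start <- starts[[i]]
      if (!ape::is.binary(.asUnrooted(start))) {
        start <- .randomRefineImpl(start) # p-ECR needs a binary tree
      }
      nb <- ecrNeighborhood(start, count = neighbors, pMax = pMax)
      pool <- c(pool, nb)
      poolOrigins <- c(
        poolOrigins, rep(paste0("neighbor-of:", origins[i]), length(nb))
      )
    }
    scored <- vector("list", length(pool))
    for (k in seq_along(pool)) {
      scored[[k]] <- new("ScoredTree",
        assignment = scoreFixedTree(pool[[k]], seqs, scheme, method = method),
        origin = poolOrigins[k]
      )
    }
    cp <- new("CandidatePool",
      scored = scored, scheme = scheme,
      baselineIndex = as.integer(baselineIndex)
    )
    list(best = bestTree(cp), pool = cp)
  })
}

#' Best (shortest) tree of a candidate pool
#'
#' Ties are broken by insertion order, so starting trees win over their
#' neighbors at equal treelength.
#'
#' @param pool a [CandidatePool-class]
#' @return a [ScoredTree-class]
#' @export
bestTree <- function(pool) {
  stopifnot(is(pool, "CandidatePool"))
  pool@scored[[which.min(treelength(pool))]]
}

#' Treelength normalized by the pool baseline
#'
#' The target's treelength divided by the baseline candidate's treelength.
#' When the baseline is a supplied reference-method tree, values below 1
#' mean the search found a shorter tree than that method; the pool winner
#' always scores at most 1 against any in-pool baseline.
#'
#' @param pool a [CandidatePool-class]
#' @param target a [ScoredTree-class] (defaults to the pool's best tree)
#' @return positive numeric ratio; `NaN` with a warning when the baseline
#'   treelength is 0
#' @export
normalizedScore <- function(pool, target = bestTree(pool)) {
  stopifnot(is(pool, "CandidatePool"), is(target, "ScoredTree"))
  base <- treelength(pool@scored[[pool@baselineIndex]])
  if (base == 0) {
    warning("baseline treelength is 0; normalized score undefined")
    return(NaN)
  }
  treelength(target) / base
}

#' Summary table of a candidate pool
#'
#' @param pool a [CandidatePool-class]
#' @return data.frame with columns `origin`, `treelength`,
#'   `normalized_score`, one row per candidate in pool order
#' @export
poolSummary <- function(pool) {
  stopifnot(is(pool, "CandidatePool"))
  tl <- treelength(pool)
  base <- tl[pool@baselineIndex]
  data.frame(
    origin = origin(pool),
    treelength = tl,
    normalized_score = if (base > 0) tl / base else NaN,
    stringsAsFactors = FALSE
  )
}
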