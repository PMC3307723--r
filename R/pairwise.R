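#' Optimal pairwise alignment under an edit-cost scheme
#'
#' Aligns two gap-free sequences by affine-gap dynamic programming (Gotoh
#' three-state recurrence). The cost of an alignment is the sum of the
#' column-wise substitution costs plus, for every maximal run of `l` gap
#' columns in one row, `gapOpen + gapExtend * l`. Terminal gaps are charged
#' like internal gaps. The traceback is deterministic, breaking ties in the
#' order diagonal, then gap-in-b, then gap-in-a, so repeated calls (and the
#' implied alignments built from them) are reproducible.
#'
#' @param a,b gap-free sequences over A, C, G, T (N allowed)
#' @param scheme a [CostScheme-class]
#' @return list with elements `row_a`, `row_b` (equal-length aligned rows)
#'   and `cost`
#' @examples
#' alignPair("ACGT", "AT", costPreset("affine"))
#' @export
alignPair <- function(a, b, scheme) {
  .checkPairInput(a, b, scheme)
  res <- C_align_pair(a, b, .costVector(scheme))
  if (!is.finite(res$cost)) {
    stop(
      "no finite-cost alignment: the scheme forbids indels (gapOpen = Inf) ",
      "and the sequences have unequal length"
    )
  }
  res
}

#' Edit distance between two sequences
#'
#' The cost of the optimal pairwise alignment, computed without
#' materializing a traceback. Symmetric in its arguments. Under a scheme
#' with `gapOpen = Inf` and unequal-length inputs the distance is `Inf`
#' (no feasible alignment).
#'
#' @inheritParams alignPair
#' @return nonnegative numeric cost (possibly `Inf`)
#' @examples
#' editDistance("ACGT", "AT", costPreset("simple1"))
#' @export
editDistance <- function(a, b, scheme) {
  .checkPairInput(a, b, scheme)
  C_edit_distance(a, b, .costVector(scheme))
}

#' All-pairs edit distance matrix
#'
#' @param x,y character vectors of gap-free sequences; when `y` is omitted
#'   the symmetric all-pairs matrix of `x` is returned
#' @param scheme a [CostScheme-class]
#' @return numeric matrix of edit distances, dimnames taken from the input
#'   names when present
#' @export
editDistanceMatrix <- function(x, y = NULL, scheme) {
  stopifnot(is(scheme, "CostScheme"))
  symmetric <- is.null(y)
  if (symmetric) y <- x
  if (any(grepl("-", c(x, y), fixed = TRUE))) {
    stop("input sequences must be gap-free")
  }
  D <- C_edit_distance_matrix(x, y, .costVector(scheme), symmetric)
  dimnames(D) <- list(names(x), names(y))
  D
}

#' Exhaustive minimum alignment cost (testing oracle)
#'
#' Enumerates every monotone alignment of two short sequences by recursion
#' (no memoisation: the full alignment tree is explored) and returns the
#' minimum cost, with gap runs charged `gapOpen + gapExtend * l` per maximal
#' run. Intended as an independent brute-force check of [alignPair()]; inputs
#' are limited to length 8.
#'
#' @inheritParams alignPair
#' @return minimum alignment cost over the exhaustive enumeration
#' @export
enumerateAlignmentsCost <- function(a, b, scheme) {
  .checkPairInput(a, b, scheme)
  if (nchar(a) > 8 || nchar(b) > 8) {
    stop("enumeration oracle only accepts sequences of length <= 8")
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av)
  lb <- length(bv)
  open <- scheme@gapOpen
  ext <- scheme@gapExtend
  sub <- function(x, y) substitutionCost(scheme, x, y)
  # state: 0 = no open run, 1 = gap-in-b run, 2 = gap-in-a run
  rec <- function(i, j, state) {
    if (i == la && j == lb) return(0)
    best <- Inf
    if (i < la && j < lb) {
      best <- min(best, sub(av[i + 1], bv[j + 1]) + rec(i + 1, j + 1, 0L))
    }
    if (i < la) {
      step <- ext + if (state == 1L) 0 else open
      best <- min(best, step + rec(i + 1, j, 1L))
    }
    if (j < lb) {
      step <- ext + if (state == 2L) 0 else open
      best <- min(best, step + rec(i, j + 1, 2L))
    }
    best
  }
  rec(0L, 0L, 0L)
}

#' Recompute the cost of an alignment from its columns
#'
#' Sums the substitution costs of base/base columns and `gapCost(run)` over
#' maximal single-row gap runs. Used to verify that emitted alignments
#' realize their reported cost.
#'
#' @param row_a,row_b equal-length aligned rows
#' @param scheme a [CostScheme-class]
#' @return numeric cost
#' @export
alignmentCost <- function(row_a, row_b, scheme) {
  stopifnot(nchar(row_a) == nchar(row_b))
  if (nchar(row_a) == 0) return(0)
  A <- strsplit(row_a, "")[[1]]
  B <- strsplit(row_b, "")[[1]]
  if (any(A == "-" & B == "-")) stop("gap/gap columns are not allowed")
  cost <- 0
  both <- A != "-" & B != "-"
  if (any(both)) {
    cost <- sum(substitutionCost(scheme, A[both], B[both]))
  }
  for (gapv in list(A == "-", B == "-")) {
    runs <- rle(gapv)
    cost <- cost + sum(gapCost(scheme, runs$lengths[runs$values]))
  }
  cost
}

.checkPairInput <- function(a, b, scheme) {
  stopifnot(is(scheme, "CostScheme"))
  if (length(a) != 1 || length(b) != 1 || is.na(a) || is.na(b)) {
    stop("a and b must be single sequences")
  }
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE)) {
    stop("input sequences must be gap-free")
  }
  if (grepl("[^ACGTN]", a) || grepl("[^ACGTN]", b)) {
    stop("sequences may only contain A, C, G, T (or N)")
  }
  invisible(TRUE)
}
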