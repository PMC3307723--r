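#' Non-trivial bipartitions of a tree
#'
#' One split per internal edge of the unrooted tree (polytomies simply
#' yield fewer splits). Splits are canonicalized as the sorted labels of
#' the side containing the lexicographically smallest taxon, joined by
#' `|`; only non-trivial splits (both sides of size >= 2) are returned.
#'
#' @param tree an ape `phylo` object
#' @return character vector of canonical splits (empty for stars or < 4
#'   leaves)
#' @examples
#' bipartitions(readNewick(text = "((a,b),(c,d),e);"))
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  .splitSet(tree)
}

#' Missing branch rate (false-negative rate) between two trees
#'
#' The proportion of internal edges (non-trivial bipartitions) of the
#' reference tree absent from the estimated tree. Only the reference's
#' internal edge count enters the denominator: unlike the symmetric
#' Robinson-Foulds distance, this convention is not biased in favor of
#' unresolved estimates, which matters because reference trees built by
#' contracting zero-event branches need not be binary.
#'
#' @param ref reference tree (`phylo`)
#' @param est estimated tree (`phylo`), same leaf set
#' @return value in `[0, 1]`; `NaN` (with a warning) when the reference has
#'   no internal edges
#' @examples
#' r <- readNewick(text = "((a,b),(c,d),e);")
#' missingBranchRate(r, readNewick(text = "((a,c),(b,d),e);"))
#' @export
missingBranchRate <- function(ref, est) {
  .checkSameLeaves(ref, est)
  br <- .splitSet(ref)
  if (length(br) == 0) {
    warning("reference tree has no internal edges; rate undefined")
    return(NaN)
  }
  be <- .splitSet(est)
  length(setdiff(br, be)) / length(br)
}

#' Robinson-Foulds bipartition distance
#'
#' The size of the symmetric difference of the two trees' non-trivial
#' bipartition sets; `normalized = TRUE` divides by the total number of
#' internal edges of both trees. Provided as a secondary metric: the
#' headline tree-error metric of the package is [missingBranchRate()].
#'
#' @param a,b trees (`phylo`) on the same leaf set
#' @param normalized divide by the combined internal edge count
#' @return nonnegative numeric
#' @export
rfDistance <- function(a, b, normalized = FALSE) {
  .checkSameLeaves(a, b)
  sa <- .splitSet(a)
  sb <- .splitSet(b)
  d <- length(setdiff(sa, sb)) + length(setdiff(sb, sa))
  if (normalized) {
    tot <- length(sa) + length(sb)
    if (tot == 0) {
      warning("neither tree has internal edges; distance undefined")
      return(NaN)
    }
    d <- d / tot
  }
  d
}

.checkSameLeaves <- function(a, b) {
  stopifnot(inherits(a, "phylo"), inherits(b, "phylo"))
  if (!identical(sort(a$tip.label), sort(b$tip.label))) {
    stop("trees must share the same leaf set")
  }
  invisible(TRUE)
}

# Homology pairs of an alignment: for every taxon pair (i < j) and every
# column where both rows carry a residue, the pair of within-sequence site
# indices, encoded as strings "i|j|k|l".
.homologyPairs <- function(aln) {
  m <- as.matrix(aln)
  taxa <- alnTaxa(aln)
  n <- nrow(m)
  siteIdx <- t(apply(m != "-", 1, cumsum))
  out <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(both)) next
      out <- c(out, paste(
        taxa[i], taxa[j], siteIdx[i, both], siteIdx[j, both],
        sep = "|"
      ))
    }
  }
  out
}

#' SP-FN alignment error
#'
#' The fraction of homologous residue pairs of the reference alignment not
#' recovered by the estimated alignment: `1 - |H(est) ∩ H(ref)| / |H(ref)|`,
#' where `H(A)` collects, over all taxon pairs and columns, the pairs of
#' residues placed in one column of `A` (sites indexed within each degapped
#' sequence). Both alignments must degap to identical sequences.
#'
#' @param ref reference [AlignmentMatrix-class]
#' @param est estimated [AlignmentMatrix-class] on the same taxa
#' @return value in `[0, 1]`
#' @export
spFN <- function(ref, est) {
  stopifnot(is(ref, "AlignmentMatrix"), is(est, "AlignmentMatrix"))
  if (!identical(sort(alnTaxa(ref)), sort(alnTaxa(est)))) {
    stop("alignments must contain the same taxa")
  }
  dr <- .degap(alnRows(ref))
  de <- .degap(alnRows(est))
  if (!identical(dr[sort(names(dr))], de[sort(names(de))])) {
    stop("alignments must degap to identical sequences")
  }
  hr <- .homologyPairs(ref)
  if (length(hr) == 0) {
    warning("reference alignment has no homologous residue pairs")
    return(NaN)
  }
  he <- .homologyPairs(est)
  1 - length(intersect(he, hr)) / length(hr)
}

#' Majority-rule consensus tree
#'
#' Returns the tree containing exactly those non-trivial bipartitions
#' present in strictly more than half of the input trees. Such splits are
#' pairwise compatible by the majority-rule theorem, so the consensus
#' always exists; it may be multifurcating.
#'
#' @param trees list of `phylo` objects on a shared leaf set
#' @return a `phylo` object
#' @examples
#' t1 <- readNewick(text = "((a,b),(c,d),e);")
#' t2 <- readNewick(text = "((a,b),c,(d,e));")
#' t3 <- readNewick(text = "((a,b),(c,e),d);")
#' bipartitions(majorityConsensus(list(t1, t2, t3)))
#' @export
majorityConsensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1)
  labs <- sort(trees[[1]]$tip.label)
  for (t in trees) .checkSameLeaves(trees[[1]], t)
  counts <- table(unlist(lapply(trees, .splitSet)))
  majority <- names(counts)[counts > length(trees) / 2]
  .treeFromSplits(majority, labs)
}

# Build a (possibly multifurcating) tree realizing a set of pairwise
# compatible canonical splits. Splits are turned into nested clusters on
# the side not containing the lexicographically smallest taxon.
.treeFromSplits <- function(splits, labs) {
  nt <- length(labs)
  anchor <- labs[1]
  clusters <- lapply(strsplit(splits, "|", fixed = TRUE), function(side) {
    if (anchor %in% side) setdiff(labs, side) else side
  })
  ord <- order(lengths(clusters))
  clusters <- clusters[ord]
  nC <- length(clusters)
  # parent cluster = smallest strictly containing cluster (0 = root)
  parentOf <- integer(nC)
  for (i in seq_len(nC)) {
    parentOf[i] <- 0L
    if (i < nC) {
      for (j in (i + 1):nC) {
        if (all(clusters[[i]] %in% clusters[[j]])) {
          parentOf[i] <- j
          break
        }
      }
    }
  }
  n <- nt + 1L + nC # leaves, root, one node per cluster
  children <- vector("list", n)
  clusterNode <- nt + 1L + seq_len(nC)
  root <- nt + 1L
  for (i in seq_len(nC)) {
    p <- if (parentOf[i] == 0L) root else clusterNode[parentOf[i]]
    children[[p]] <- c(children[[p]], clusterNode[i])
  }
  leafParent <- rep(root, nt)
  for (k in seq_len(nt)) {
    for (i in seq_len(nC)) { # clusters sorted by size: first hit is smallest
      if (labs[k] %in% clusters[[i]]) {
        leafParent[k] <- clusterNode[i]
        break
      }
    }
  }
  for (k in seq_len(nt)) {
    children[[leafParent[k]]] <- c(children[[leafParent[k]]], k)
  }
  if (any(lengths(children[clusterNode]) < 2)) {
    stop("splits are not pairwise compatible")
  }
  .phyloFromChildren(children, root, nt, labs)
}
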