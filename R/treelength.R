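# Fixed-tree treelength scoring: assign gap-free sequences to internal
# nodes and score the tree as the sum over edges of the pairwise edit
# distance. The general fixed-tree problem is NP-hard, so the package
# offers two heuristics (lifted, do) and a brute-force exact solver for
# tiny instances.

.treelengthOf <- function(phy, nodeSeqs, scheme) {
  cv <- .costVector(scheme)
  s <- 0
  for (k in seq_len(nrow(phy$edge))) {
    s <- s + C_edit_distance(
      nodeSeqs[phy$edge[k, 1]], nodeSeqs[phy$edge[k, 2]], cv
    )
  }
  s
}

.leafSeqVector <- function(phy, seqs) {
  n <- .ntip(phy) + phy$Nnode
  out <- character(n)
  out[seq_len(.ntip(phy))] <- unname(seqs[phy$tip.label])
  out
}

.newAssignment <- function(phy, nodeSeqs, scheme, method) {
  names(nodeSeqs) <- as.character(seq_along(nodeSeqs))
  new("TreeAssignment",
    tree = phy, nodeSequences = nodeSeqs,
    treelength = .treelengthOf(phy, nodeSeqs, scheme),
    scheme = scheme, method = method
  )
}

# Degenerate two-leaf tree: the score is the pairwise edit distance and the
# degree-2 connector node carries the smaller-labelled leaf's sequence.
.twoLeafAssignment <- function(phy, seqs, scheme, method) {
  nodeSeqs <- .leafSeqVector(phy, seqs)
  nodeSeqs[3] <- nodeSeqs[which(phy$tip.label == min(phy$tip.label))[1]]
  .newAssignment(phy, nodeSeqs, scheme, method)
}

#' Score a fixed tree under a treelength criterion
#'
#' Assigns a gap-free sequence to every internal node of `tree` and returns
#' the resulting treelength (the sum over edges of [editDistance()] between
#' the endpoint sequences). `method = "lifted"` restricts internal nodes to
#' leaf sequences and finds the best such labeling by dynamic programming;
#' `method = "do"` builds direct-optimization-style consensus ancestors in a
#' post-order pass and then hill-climbs; `method = "exact"` enumerates all
#' candidate ancestral sequences up to a length bound and is only accepted
#' on tiny instances. Multifurcating trees are scored as-is. The reported
#' treelength of every method is an upper bound on the optimal fixed-tree
#' treelength and is always recomputed from the final node sequences.
#'
#' @param tree an ape `phylo` object whose tip labels match `names(seqs)`
#' @param seqs named character vector of gap-free sequences
#' @param scheme a [CostScheme-class]
#' @param method `"lifted"`, `"do"` or `"exact"`
#' @param ... passed on to [exactAssignment()] (`maxLen`, `maxTaxa`)
#' @return a [TreeAssignment-class]
#' @examples
#' phy <- readNewick(text = "((a,b),(c,d));")
#' seqs <- c(a = "ACGT", b = "ACGA", c = "TCGT", d = "TCGA")
#' scoreFixedTree(phy, seqs, costPreset("simple1"))
#' @export
scoreFixedTree <- function(tree, seqs, scheme,
                           method = c("lifted", "do", "exact"), ...) {
  method <- match.arg(method)
  switch(method,
    lifted = liftedAssignment(tree, seqs, scheme),
    do = doAssignment(tree, seqs, scheme),
    exact = exactAssignment(tree, seqs, scheme, ...)
  )
}

.checkScoringInput <- function(tree, seqs, scheme) {
  stopifnot(inherits(tree, "phylo"), is(scheme, "CostScheme"))
  if (.ntip(tree) < 2) stop("tree must have at least two leaves")
  .validateSeqs(seqs, aligned = FALSE, ambiguity = TRUE)
  .checkLeafMatch(tree, seqs)
}

#' Lifted-labeling treelength heuristic
#'
#' Every internal node is assigned the sequence of some leaf; the choice
#' minimizing total treelength over all lifted labelings is found by
#' dynamic programming over the tree using the all-pairs edit-distance
#' matrix of the leaf sequences. Under a metric edit distance the best
#' lifted labeling is within a factor 2 of the optimal assignment.
#'
#' @inheritParams scoreFixedTree
#' @return a [TreeAssignment-class] with `method = "lifted"`
#' @export
liftedAssignment <- function(tree, seqs, scheme) {
  .checkScoringInput(tree, seqs, scheme)
  phy <- .asUnrooted(tree)
  if (.ntip(phy) == 2) return(.twoLeafAssignment(phy, seqs, scheme, "lifted"))
  nt <- .ntip(phy)
  leafSeq <- .leafSeqVector(phy, seqs)[seq_len(nt)]
  cands <- unique(leafSeq[order(phy$tip.label)])
  K <- length(cands)
  D <- editDistanceMatrix(cands, scheme = scheme)
  rooted <- .rootedAt(phy, .traversalRoot(phy))
  n <- length(rooted$children)
  cost <- matrix(Inf, nrow = K, ncol = n)
  pick <- vector("list", n) # pick[[v]][k] = child candidate under parent cand k
  for (v in rooted$postorder) {
    if (v <= nt) {
      cost[match(leafSeq[v], cands), v] <- 0
    } else {
      tot <- numeric(K)
      for (ch in rooted$children[[v]]) {
        M <- D + cost[, ch] # M[j, k] = D[j, k] + cost[j, ch]
        best <- apply(M, 2, which.min)
        pick[[ch]] <- best
        tot <- tot + M[cbind(best, seq_len(K))]
      }
      cost[, v] <- tot
    }
  }
  nodeSeqs <- character(n)
  nodeSeqs[seq_len(nt)] <- leafSeq
  choice <- integer(n)
  choice[rooted$root] <- which.min(cost[, rooted$root])
  for (v in rooted$preorder) {
    if (v > nt && v != rooted$root) {
      choice[v] <- pick[[v]][choice[rooted$parent[v]]]
    }
    if (v > nt) nodeSeqs[v] <- cands[choice[v]]
  }
  # leaves whose parent DP picked them are fixed to their own sequence anyway
  .newAssignment(phy, nodeSeqs, scheme, "lifted")
}

# Column-wise consensus of a pairwise alignment: keep bases over gaps,
# break base/base ties alphabetically. The result is gap-free.
.consensusOf <- function(row_a, row_b) {
  A <- strsplit(row_a, "")[[1]]
  B <- strsplit(row_b, "")[[1]]
  out <- ifelse(A == "-", B, ifelse(B == "-", A, pmin(A, B)))
  paste(out, collapse = "")
}

#' Direct-optimization-style treelength heuristic
#'
#' A post-order pass assigns every internal node the column-wise consensus
#' of the optimal pairwise alignment of its children's assigned sequences
#' (base/base ties resolved alphabetically, gap-vs-base columns keep the
#' base; polytomies are folded left to right). A hill-climbing pass then
#' repeatedly replaces any internal node's sequence by a neighbor's sequence
#' whenever that strictly lowers the treelength, to a fixed point. The final
#' treelength is recomputed from the node sequences.
#'
#' @inheritParams scoreFixedTree
#' @param maxSweeps cap on hill-climbing sweeps over the internal nodes
#' @return a [TreeAssignment-class] with `method = "do"`
#' @export
doAssignment <- function(tree, seqs, scheme, maxSweeps = 20L) {
  .checkScoringInput(tree, seqs, scheme)
  phy <- .asUnrooted(tree)
  if (.ntip(phy) == 2) return(.twoLeafAssignment(phy, seqs, scheme, "do"))
  nt <- .ntip(phy)
  cv <- .costVector(scheme)
  rooted <- .rootedAt(phy, .traversalRoot(phy))
  n <- length(rooted$children)
  nodeSeqs <- character(n)
  nodeSeqs[seq_len(nt)] <- .leafSeqVector(phy, seqs)[seq_len(nt)]
  for (v in rooted$postorder) {
    if (v <= nt) next
    kids <- rooted$children[[v]]
    s <- nodeSeqs[kids[1]]
    for (ch in kids[-1]) {
      aln <- C_align_pair(s, nodeSeqs[ch], cv)
      if (!is.finite(aln$cost)) {
        # indels forbidden and lengths differ: keep the first child's sequence
        next
      }
      s <- .consensusOf(aln$row_a, aln$row_b)
    }
    nodeSeqs[v] <- s
  }
  # hill-climbing: re-lift nodes onto neighbor sequences while that helps
  neighbors <- vector("list", n)
  for (v in seq_len(n)) {
    neighbors[[v]] <- c(
      if (rooted$parent[v] > 0) rooted$parent[v],
      rooted$children[[v]]
    )
  }
  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    for (v in rooted$postorder) {
      if (v <= nt) next
      nb <- neighbors[[v]]
      cur <- sum(vapply(
        nb, function(w) C_edit_distance(nodeSeqs[v], nodeSeqs[w], cv),
        numeric(1)
      ))
      for (cand in unique(nodeSeqs[nb])) {
        if (identical(cand, nodeSeqs[v])) next
        alt <- sum(vapply(
          nb, function(w) C_edit_distance(cand, nodeSeqs[w], cv),
          numeric(1)
        ))
        if (alt < cur) {
          nodeSeqs[v] <- cand
          cur <- alt
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  .newAssignment(phy, nodeSeqs, scheme, "do")
}

#' Exact fixed-tree treelength on tiny instances
#'
#' Enumerates candidate ancestral sequences (all strings over A,C,G,T of
#' length at most `maxLen`) and finds the globally optimal assignment over
#' that space by Sankoff-style dynamic programming on the tree. Intended as
#' a verification oracle: the fixed-tree problem is NP-hard, so the
#' enumeration is only accepted for at most `maxTaxa` leaves.
#'
#' @inheritParams scoreFixedTree
#' @param maxLen maximum candidate ancestral sequence length (capped at 5)
#' @param maxTaxa maximum number of leaves accepted
#' @return a [TreeAssignment-class] with `method = "exact"`
#' @export
exactAssignment <- function(tree, seqs, scheme, maxLen = 4L, maxTaxa = 5L) {
  .checkScoringInput(tree, seqs, scheme)
  phy <- .asUnrooted(tree)
  nt <- .ntip(phy)
  if (nt > maxTaxa) {
    stop("exact assignment accepts at most ", maxTaxa, " leaves (got ", nt, ")")
  }
  if (maxLen > 5) stop("maxLen above 5 is not supported (candidate blow-up)")
  if (nt == 2) return(.twoLeafAssignment(phy, seqs, scheme, "exact"))
  cands <- .allStrings(maxLen)
  K <- length(cands)
  cv <- .costVector(scheme)
  leafSeq <- .leafSeqVector(phy, seqs)[seq_len(nt)]
  Dcc <- editDistanceMatrix(cands, scheme = scheme)
  Dcl <- editDistanceMatrix(cands, leafSeq, scheme)
  rooted <- .rootedAt(phy, .traversalRoot(phy))
  n <- length(rooted$children)
  cost <- matrix(0, nrow = K, ncol = n)
  pick <- vector("list", n)
  for (v in rooted$postorder) {
    if (v <= nt) next
    tot <- numeric(K)
    for (ch in rooted$children[[v]]) {
      if (ch <= nt) {
        tot <- tot + Dcl[, ch]
      } else {
        M <- Dcc + cost[, ch]
        best <- apply(M, 2, which.min)
        pick[[ch]] <- best
        tot <- tot + M[cbind(best, seq_len(K))]
      }
    }
    cost[, v] <- tot
  }
  if (!any(is.finite(cost[, rooted$root]))) {
    stop(
      "no finite-cost assignment in the enumerated space; ",
      "increase maxLen or relax the scheme"
    )
  }
  nodeSeqs <- character(n)
  nodeSeqs[seq_len(nt)] <- leafSeq
  choice <- integer(n)
  choice[rooted$root] <- which.min(cost[, rooted$root])
  for (v in rooted$preorder) {
    if (v <= nt) next
    if (v != rooted$root) choice[v] <- pick[[v]][choice[rooted$parent[v]]]
    nodeSeqs[v] <- cands[choice[v]]
  }
  .newAssignment(phy, nodeSeqs, scheme, "exact")
}

# All strings over {A,C,G,T} of length 0..maxLen (the empty string first).
.allStrings <- function(maxLen) {
  bases <- c("A", "C", "G", "T")
  out <- ""
  for (l in seq_len(maxLen)) {
    grid <- do.call(expand.grid, c(
      rep(list(bases), l),
      stringsAsFactors = FALSE
    ))
    out <- c(out, do.call(paste0, rev(grid)))
  }
  out
}

#' Recompute a treelength from its node sequences
#'
#' Sums [editDistance()] over the edges of the assignment's tree; by
#' construction this equals `treelength(assignment)` exactly.
#'
#' @param assignment a [TreeAssignment-class]
#' @return numeric treelength
#' @export
recomputeTreelength <- function(assignment) {
  stopifnot(is(assignment, "TreeAssignment"))
  .treelengthOf(
    assignment@tree, unname(assignment@nodeSequences), assignment@scheme
  )
}

#' Implied multiple sequence alignment of a tree assignment
#'
#' For every edge of the tree, the optimal pairwise alignment of its
#' endpoint sequences is computed with the deterministic traceback of
#' [alignPair()]; the transitive closure of the induced site-homology
#' relation across the tree defines the columns. Columns are ordered by
#' threading each child's unmatched sites into the global column order in a
#' pre-order pass (new sites are placed immediately before the next site of
#' the parent that the pairwise alignment matches, or at the end), which
#' yields an order consistent with every sequence's site order by
#' construction. Rows are restricted to the leaves and all-gap columns are
#' dropped.
#'
#' @param assignment a [TreeAssignment-class]
#' @return an [AlignmentMatrix-class] with one row per leaf, in tip-label
#'   order of the assignment's tree
#' @export
impliedAlignment <- function(assignment) {
  stopifnot(is(assignment, "TreeAssignment"))
  phy <- assignment@tree
  nt <- .ntip(phy)
  nodeSeqs <- unname(assignment@nodeSequences)
  cv <- .costVector(assignment@scheme)
  root <- if (nt == 2) nt + 1L else .traversalRoot(phy)
  rooted <- .rootedAt(phy, root)
  n <- length(rooted$children)
  cls <- vector("list", n)
  Lroot <- nchar(nodeSeqs[root])
  cls[[root]] <- seq_len(Lroot)
  G <- seq_len(Lroot)
  nextId <- Lroot
  for (v in rooted$preorder) {
    if (v == root) next
    u <- rooted$parent[v]
    aln <- C_align_pair(nodeSeqs[u], nodeSeqs[v], cv)
    if (!is.finite(aln$cost)) {
      stop("scheme admits no finite-cost alignment along an edge")
    }
    A <- strsplit(aln$row_a, "")[[1]]
    B <- strsplit(aln$row_b, "")[[1]]
    ncol <- length(A)
    clsV <- integer(nchar(nodeSeqs[v]))
    iu <- 0L
    iv <- 0L
    pendingNew <- integer(0) # new ids awaiting an anchor
    for (t in seq_len(ncol)) {
      if (A[t] != "-") {
        iu <- iu + 1L
        anchorClass <- cls[[u]][iu]
        if (length(pendingNew)) {
          pos <- match(anchorClass, G)
          G <- append(G, pendingNew, after = pos - 1L)
          pendingNew <- integer(0)
        }
        if (B[t] != "-") {
          iv <- iv + 1L
          clsV[iv] <- anchorClass
        }
      } else {
        # new site in v, unmatched in u
        iv <- iv + 1L
        nextId <- nextId + 1L
        clsV[iv] <- nextId
        pendingNew <- c(pendingNew, nextId)
      }
    }
    if (length(pendingNew)) G <- c(G, pendingNew)
    cls[[v]] <- clsV
  }
  # restrict to leaf-covered columns
  leafCls <- unique(unlist(cls[seq_len(nt)], use.names = FALSE))
  Gkeep <- G[G %in% leafCls]
  rows <- vapply(seq_len(nt), function(v) {
    chars <- rep("-", length(Gkeep))
    chars[match(cls[[v]], Gkeep)] <- strsplit(nodeSeqs[v], "")[[1]]
    paste(chars, collapse = "")
  }, character(1))
  alignmentMatrix(phy$tip.label, rows)
}

#' Construct an alignment matrix
#'
#' @param taxa ordered taxon labels
#' @param rows aligned rows (equal-length strings over A,C,G,T,N,-)
#' @return an [AlignmentMatrix-class]
#' @examples
#' alignmentMatrix(c("a", "b"), c("AC-G", "ACTG"))
#' @export
alignmentMatrix <- function(taxa, rows) {
  new("AlignmentMatrix", taxa = as.character(taxa), rows = unname(rows))
}
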