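# Independent oracles and fixture generators used across the suite.

BASES <- c("A", "C", "G", "T")

randomSeq <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

randomSeqs <- function(n, len, labels = NULL) {
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stats::setNames(vapply(rep(len, n), randomSeq, character(1)), labels)
}

# Equality that treats two infinities as equal (mp schemes produce Inf).
costEq <- function(x, y, tol = 1e-9) {
  (is.infinite(x) && is.infinite(y) && sign(x) == sign(y)) ||
    isTRUE(abs(x - y) <= tol)
}

# Independent per-site Sankoff parsimony oracle: gap-free equal-length
# sequences, substitution costs from `scheme`, indels forbidden. Uses only
# ape's postorder edge list; shares no code with the package's tree DP.
sankoffParsimony <- function(phy, seqs, scheme) {
  S <- outer(BASES, BASES, function(x, y) {
    mapply(function(a, b) substitutionCost(scheme, a, b), x, y)
  })
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  seqm <- do.call(rbind, strsplit(unname(seqs[phy$tip.label]), ""))
  L <- ncol(seqm)
  root <- po$edge[nrow(po$edge), 1]
  total <- 0
  for (site in seq_len(L)) {
    cost <- matrix(Inf, 4, nn)
    for (v in seq_len(nt)) cost[BASES == seqm[v, site], v] <- 0
    touched <- rep(FALSE, nn)
    for (k in seq_len(nrow(po$edge))) {
      u <- po$edge[k, 1]
      v <- po$edge[k, 2]
      if (!touched[u]) {
        cost[, u] <- 0
        touched[u] <- TRUE
      }
      childmin <- apply(S + matrix(cost[, v], 4, 4), 2, min)
      cost[, u] <- cost[, u] + childmin
    }
    total <- total + min(cost[, root])
  }
  total
}

# Brute-force homology-pair enumeration for SP-FN (independent of the
# package's column coding): explicit pair set over taxon pairs and columns.
homologyPairSet <- function(aln) {
  m <- as.matrix(aln)
  taxa <- alnTaxa(aln)
  pairs <- character(0)
  idx <- apply(m != "-", 1, cumsum)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = nrow(m))
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      for (col in seq_len(ncol(m))) {
        if (m[i, col] != "-" && m[j, col] != "-") {
          pairs <- c(pairs, paste(
            taxa[i], idx[col, i], taxa[j], idx[col, j],
            sep = ":"
          ))
        }
      }
    }
  }
  pairs
}

# Project two rows of an alignment onto each other: drop columns where both
# are gaps.
projectRows <- function(aln, t1, t2) {
  rows <- alnRows(aln)
  A <- strsplit(rows[[t1]], "")[[1]]
  B <- strsplit(rows[[t2]], "")[[1]]
  keep <- !(A == "-" & B == "-")
  list(a = paste(A[keep], collapse = ""), b = paste(B[keep], collapse = ""))
}

# Random gap-free test instance: a random binary tree plus random leaf
# sequences of the given length.
randomInstance <- function(n, len, seed) {
  withr::with_seed(seed, {
    labels <- paste0("t", seq_len(n))
    list(
      tree = randomBinaryTree(labels),
      seqs = randomSeqs(n, len, labels)
    )
  })
}
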