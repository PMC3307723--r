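# Random p-ECR perturbations and supporting tree surgery. All randomized
# operations are pure functions of (input, seed): passing a seed evaluates
# under a local RNG state; passing NULL draws from the current stream.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Internal edges of an unrooted phylo: edge rows whose child is internal.
.internalEdgeRows <- function(phy) {
  which(phy$edge[, 2] > .ntip(phy))
}

#' Contract edges of a tree
#'
#' Removes each listed internal edge and merges its endpoints; leaves are
#' untouched and the result may be multifurcating. Edges are identified by
#' their row index in `tree$edge` (the tree is first standardized to its
#' unrooted form; use [internalEdges()] to list contractible rows).
#'
#' @param tree an ape `phylo` object
#' @param edges integer row indices into the unrooted tree's edge matrix;
#'   each must be an internal edge
#' @return an ape `phylo` object (possibly multifurcating)
#' @examples
#' phy <- readNewick(text = "((a,b),(c,d));")
#' contractEdges(phy, internalEdges(phy))
#' @export
contractEdges <- function(tree, edges) {
  stopifnot(inherits(tree, "phylo"))
  phy <- .asUnrooted(tree)
  edges <- as.integer(edges)
  if (length(edges) == 0) return(phy)
  if (anyNA(edges) || any(edges < 1) || any(edges > nrow(phy$edge))) {
    stop("edge indices out of range")
  }
  nt <- .ntip(phy)
  if (any(phy$edge[edges, 2] <= nt)) {
    stop("cannot contract a leaf edge")
  }
  n <- nt + phy$Nnode
  rep_ <- seq_len(n)
  find <- function(v) {
    while (rep_[v] != v) v <- rep_[v]
    v
  }
  for (k in edges) {
    u <- find(phy$edge[k, 1])
    v <- find(phy$edge[k, 2])
    rep_[v] <- u
  }
  keep <- setdiff(seq_len(nrow(phy$edge)), edges)
  children <- vector("list", n)
  elen <- .edgeLengthAbove(phy)
  for (k in keep) {
    u <- find(phy$edge[k, 1])
    v <- phy$edge[k, 2] # child of a kept edge is never merged away
    children[[u]] <- c(children[[u]], v)
  }
  root <- find(nt + 1L)
  .phyloFromChildren(children, root, nt, phy$tip.label, elen)
}

#' List the internal edges of a tree
#'
#' @param tree an ape `phylo` object
#' @return integer row indices (into the unrooted tree's edge matrix) of the
#'   internal edges
#' @export
internalEdges <- function(tree) {
  .internalEdgeRows(.asUnrooted(tree))
}

#' Randomly refine a multifurcating tree to binary
#'
#' Every polytomy is resolved by repeatedly grouping a uniformly chosen pair
#' of its children under a new node. Every bipartition of the input is a
#' bipartition of the output, and the output is binary. Seeded and
#' reproducible; a binary input is returned unchanged (up to its unrooted
#' representation).
#'
#' @param tree an ape `phylo` object
#' @param seed integer seed, or `NULL` to use the current RNG stream
#' @return a binary unrooted `phylo` object
#' @export
randomRefine <- function(tree, seed = NULL) {
  .withSeed(seed, .randomRefineImpl(tree))
}

.randomRefineImpl <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  phy <- .asUnrooted(tree)
  nt <- .ntip(phy)
  if (nt < 4) return(phy)
  rooted <- .rootedAt(phy, nt + 1L)
  children <- rooted$children
  root <- rooted$root
  n <- length(children)
  elen <- .edgeLengthAbove(phy)
  for (v in seq_len(n)) {
    if (v <= nt || is.null(children[[v]])) next
    target <- if (v == root) 3L else 2L
    kids <- children[[v]]
    while (length(kids) > target) {
      pair <- sample(length(kids), 2L)
      n <- n + 1L
      children[[n]] <- kids[pair]
      elen[n] <- NA_real_
      kids <- c(kids[-pair], n)
    }
    children[[v]] <- kids
  }
  .phyloFromChildren(children, root, nt, phy$tip.label, elen)
}

#' Random p-ECR tree perturbation
#'
#' A random p-ECR move contracts `p` randomly selected internal edges of a
#' binary tree (uniformly, without replacement) and then randomly refines
#' the resulting unresolved tree to a binary tree. The leaf set is
#' preserved; at most `p` of the input's bipartitions are lost.
#'
#' @param tree a binary ape `phylo` object
#' @param p number of internal edges to contract (clamped to the number of
#'   internal edges, with a warning, on small trees)
#' @param seed integer seed, or `NULL` to use the current RNG stream
#' @return a binary unrooted `phylo` object on the same leaf set
#' @examples
#' phy <- randomBinaryTree(letters[1:8], seed = 1)
#' pEcr(phy, p = 2, seed = 7)
#' @export
pEcr <- function(tree, p, seed = NULL) {
  .withSeed(seed, .pEcrImpl(tree, p))
}

.pEcrImpl <- function(tree, p) {
  stopifnot(inherits(tree, "phylo"))
  p <- as.integer(p)
  if (p < 1) stop("p must be a positive integer")
  phy <- .asUnrooted(tree)
  internal <- .internalEdgeRows(phy)
  if (length(internal) == 0) return(phy)
  if (p > length(internal)) {
    warning(
      "p = ", p, " exceeds the ", length(internal),
      " internal edges; clamping"
    )
    p <- length(internal)
  }
  chosen <- internal[sample(length(internal), p)]
  .randomRefineImpl(contractEdges(phy, chosen))
}

#' Sample the p-ECR neighborhood of a tree
#'
#' Produces `count` trees, each obtained from `tree` by one independent
#' random p-ECR move with `p` drawn uniformly from 1 to
#' `min(pMax, n - 3)`. The default (`count = 20`, `pMax = 5`) samples the
#' neighborhood used around each selected tree in the candidate-pool
#' search. The drawn `p` values are attached as attribute `"p"`.
#'
#' @param tree a binary ape `phylo` object
#' @param count number of neighbors to draw
#' @param pMax largest `p` considered
#' @param seed integer seed, or `NULL` to use the current RNG stream
#' @return list of binary `phylo` objects with attribute `"p"`
#' @export
ecrNeighborhood <- function(tree, count = 20L, pMax = 5L, seed = NULL) {
  .withSeed(seed, {
    phy <- .asUnrooted(tree)
    nInternal <- length(.internalEdgeRows(phy))
    top <- max(1L, min(as.integer(pMax), nInternal))
    ps <- sample.int(top, as.integer(count), replace = TRUE)
    out <- lapply(ps, function(p) .pEcrImpl(phy, p))
    attr(out, "p") <- ps
    out
  })
}

#' Uniformly random unrooted binary tree topology
#'
#' Built by sequential random edge attachment: starting from the unique
#' 3-leaf tree, each further leaf is attached to a uniformly chosen edge of
#' the current tree, which yields the uniform distribution over unrooted
#' binary topologies.
#'
#' @param labels at least 3 leaf labels
#' @param seed integer seed, or `NULL` to use the current RNG stream
#' @return a binary unrooted `phylo` object
#' @export
randomBinaryTree <- function(labels, seed = NULL) {
  .withSeed(seed, .randomBinaryTreeImpl(labels))
}

.randomBinaryTreeImpl <- function(labels) {
  labels <- as.character(labels)
  nt <- length(labels)
  if (nt < 3) stop("need at least 3 labels")
  if (anyDuplicated(labels)) stop("labels must be unique")
  # nodes: 1..nt leaves, nt+1.. internal; edges as a growing 2-column matrix
  edges <- rbind(
    c(nt + 1L, 1L), c(nt + 1L, 2L), c(nt + 1L, 3L)
  )
  nextNode <- nt + 1L
  for (leaf in seq_len(nt)[-(1:3)]) {
    k <- sample(nrow(edges), 1L)
    u <- edges[k, 1]
    v <- edges[k, 2]
    nextNode <- nextNode + 1L
    edges <- rbind(
      edges[-k, , drop = FALSE],
      c(u, nextNode), c(nextNode, v), c(nextNode, leaf)
    )
  }
  children <- vector("list", nextNode)
  for (k in seq_len(nrow(edges))) {
    children[[edges[k, 1]]] <- c(children[[edges[k, 1]]], edges[k, 2])
  }
  .phyloFromChildren(children, nt + 1L, nt, labels)
}
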