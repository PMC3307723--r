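# Internal tree plumbing shared by the scoring, move and metric code.
# Trees are ape "phylo" objects; node ids follow ape's convention
# (1..ntip = leaves, ntip+1 = root of the stored orientation).

.ntip <- function(phy) length(phy$tip.label)

# Collapse a degree-2 root so trees are compared/scored as unrooted.
.asUnrooted <- function(phy) {
  if (.ntip(phy) >= 3) ape::unroot(phy) else phy
}

# Undirected adjacency list over node ids.
.adjacency <- function(phy) {
  n <- .ntip(phy) + phy$Nnode
  adj <- vector("list", n)
  for (k in seq_len(nrow(phy$edge))) {
    u <- phy$edge[k, 1]
    v <- phy$edge[k, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

# Orient the tree from `root`: children lists, parent vector and a postorder.
.rootedAt <- function(phy, root) {
  n <- .ntip(phy) + phy$Nnode
  adj <- .adjacency(phy)
  parent <- integer(n)
  children <- vector("list", n)
  order <- integer(0)
  stack <- c(root)
  parent[root] <- 0L
  seen <- logical(n)
  seen[root] <- TRUE
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        children[[v]] <- c(children[[v]], w)
        stack <- c(stack, w)
      }
    }
  }
  list(
    children = children, parent = parent, root = root,
    preorder = pre, postorder = rev(pre),
    ntip = .ntip(phy), labels = phy$tip.label
  )
}

# Deterministic traversal root: the internal node adjacent to the
# lexicographically smallest leaf label.
.traversalRoot <- function(phy) {
  leaf <- which(phy$tip.label == min(phy$tip.label))
  adj <- .adjacency(phy)
  adj[[leaf]][1]
}

# Leaf id sets of every subtree of a rooted orientation.
.subtreeLeaves <- function(rooted) {
  n <- length(rooted$children)
  sets <- vector("list", n)
  for (v in rooted$postorder) {
    if (v <= rooted$ntip) {
      sets[[v]] <- v
    } else {
      sets[[v]] <- sort(unlist(sets[rooted$children[[v]]], use.names = FALSE))
    }
  }
  sets
}

# Canonical non-trivial splits of an unrooted tree, as sorted label strings
# for the side containing the lexicographically smallest taxon.
.splitSet <- function(phy) {
  phy <- .asUnrooted(phy)
  nt <- .ntip(phy)
  if (nt < 4) return(character(0))
  rooted <- .rootedAt(phy, nt + 1L)
  sets <- .subtreeLeaves(rooted)
  labs <- phy$tip.label
  anchor <- min(labs)
  out <- character(0)
  for (v in seq_along(sets)) {
    if (v <= nt || v == rooted$root) next
    side <- labs[sets[[v]]]
    if (length(side) < 2 || length(side) > nt - 2) next
    if (!(anchor %in% side)) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# Newick serialization of a rooted children-list structure. `elen[v]` is the
# length of the edge above node v (NA = omit).
.newickFromChildren <- function(children, root, ntip, labels,
                               elen = NULL) {
  rec <- function(v) {
    body <- if (v <= ntip) {
      labels[v]
    } else {
      kids <- vapply(children[[v]], rec, character(1))
      paste0("(", paste(kids, collapse = ","), ")")
    }
    if (!is.null(elen) && v != root && !is.na(elen[v])) {
      body <- paste0(body, ":", format(elen[v], digits = 10))
    }
    body
  }
  paste0(rec(root), ";")
}

.phyloFromChildren <- function(children, root, ntip, labels, elen = NULL) {
  ape::read.tree(
    text = .newickFromChildren(children, root, ntip, labels, elen)
  )
}

# Branch length of the edge above each node (NA when absent), indexed by
# child node id.
.edgeLengthAbove <- function(phy) {
  n <- .ntip(phy) + phy$Nnode
  elen <- rep(NA_real_, n)
  if (!is.null(phy$edge.length)) {
    elen[phy$edge[, 2]] <- phy$edge.length
  }
  elen
}

.checkLeafMatch <- function(phy, seqs) {
  labs <- sort(phy$tip.label)
  if (!identical(labs, sort(names(seqs)))) {
    stop("tree leaf labels and sequence labels must match bijectively")
  }
  invisible(TRUE)
}
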