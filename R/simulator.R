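# Sequence evolution along a tree with substitutions and indels, tracking
# the homology of every site so that the true alignment and per-branch
# event counts are known exactly. Replaces external benchmark collections
# as the package's fixture generator.

#' Indel length model
#'
#' Either a single geometric distribution on 1, 2, ... (mean `1/p`) or a
#' mixture of geometrics, which produces the short-median/long-tail length
#' profiles seen in real data that a single geometric cannot match.
#'
#' @param type `"geometric"` or `"mixture"`
#' @param p success probability (vector of probabilities for a mixture)
#' @param weights mixture weights summing to 1 (mixture only)
#' @return list suitable for the `gapLengthModel` slot of [simParams()]
#' @examples
#' gapLengthModel("geometric", p = 0.5)
#' gapLengthModel("mixture", p = c(0.9, 0.1), weights = c(0.8, 0.2))
#' @export
gapLengthModel <- function(type = c("geometric", "mixture"), p,
                           weights = NULL) {
  type <- match.arg(type)
  if (type == "geometric") list(type = type, p = p)
  else list(type = type, p = p, weights = weights)
}

#' Simulation parameters
#'
#' Presets bundle indel length models with short (`"short"`, geometric
#' p = 0.7), medium (`"medium"`, p = 0.45) and long (`"long"`, p = 0.25)
#' expected gap lengths, mirroring the short/medium/long gap-length axes of
#' standard indel simulation studies; all other values can be overridden.
#'
#' @param rootLength sites in the root sequence
#' @param substitutionRate expected substitutions per site per unit branch
#'   length
#' @param indelRate expected indel events per site per unit branch length
#' @param insertionFraction probability an indel event is an insertion
#' @param gapLengthModel a [gapLengthModel()] list
#' @param tsTvRatio expected transitions per transversion
#' @param preset optional `"short"`, `"medium"` or `"long"` gap-length preset
#' @return a [SimParams-class]
#' @examples
#' simParams(rootLength = 500, preset = "medium")
#' @export
simParams <- function(rootLength = 1000L, substitutionRate = 0.5,
                      indelRate = 0.05, insertionFraction = 0.5,
                      gapLengthModel = NULL, tsTvRatio = 2,
                      preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("short", "medium", "long"))
    if (is.null(gapLengthModel)) {
      gapLengthModel <- switch(preset,
        short = list(type = "geometric", p = 0.7),
        medium = list(type = "geometric", p = 0.45),
        long = list(type = "geometric", p = 0.25)
      )
    }
  }
  if (is.null(gapLengthModel)) {
    gapLengthModel <- list(type = "geometric", p = 0.45)
  }
  new("SimParams",
    rootLength = as.integer(rootLength),
    substitutionRate = as.numeric(substitutionRate),
    indelRate = as.numeric(indelRate),
    insertionFraction = as.numeric(insertionFraction),
    gapLengthModel = gapLengthModel,
    tsTvRatio = as.numeric(tsTvRatio)
  )
}

.drawGapLength <- function(model, n = 1L) {
  if (model$type == "geometric") {
    rgeom(n, model$p) + 1L
  } else {
    comp <- sample.int(length(model$p), n, replace = TRUE,
      prob = model$weights)
    rgeom(n, model$p[comp]) + 1L
  }
}

.BASES <- c("A", "C", "G", "T")

# One substitution event on a base: transition with probability R/(R+1),
# otherwise one of the two transversion partners uniformly.
.substituteBases <- function(bases, tsTvRatio) {
  transitionOf <- c(A = "G", G = "A", C = "T", T = "C")
  transversionsOf <- list(
    A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G")
  )
  isTs <- runif(length(bases)) < tsTvRatio / (tsTvRatio + 1)
  out <- bases
  out[isTs] <- transitionOf[bases[isTs]]
  for (k in which(!isTs)) {
    out[k] <- sample(transversionsOf[[bases[k]]], 1L)
  }
  out
}

#' Evolve sequences along a model tree
#'
#' Simulates evolution from an i.i.d.-uniform root sequence down every
#' branch: per-site substitution event counts are Poisson with mean
#' `substitutionRate * b` (K2P-style transition/transversion choice governed
#' by `tsTvRatio`), and indel events are Poisson with mean
#' `indelRate * b * L` (`L` the length at the branch start), each an
#' insertion or deletion with uniformly chosen position and length drawn
#' from the gap-length model. Site homology is tracked through every event,
#' so the returned record carries the true alignment of the leaves,
#' per-branch substitution and indel-event tallies, and the reference tree
#' obtained by contracting zero-event internal branches.
#'
#' Branch lengths must be nonnegative; zero-length branches are allowed and
#' simply never see events.
#'
#' @param modelTree a `phylo` with branch lengths; treated as unrooted, with
#'   the simulation rooted at its basal internal node
#' @param params a [SimParams-class]
#' @param seed integer seed, or `NULL` to use the current RNG stream
#' @return a [SimulationRecord-class]
#' @examples
#' phy <- readNewick(text = "((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1,e:0.3);")
#' rec <- evolveSequences(phy, simParams(rootLength = 100), seed = 1)
#' dim(rec@trueAlignment)
#' @export
evolveSequences <- function(modelTree, params, seed = NULL) {
  stopifnot(inherits(modelTree, "phylo"), is(params, "SimParams"))
  .withSeed(seed, .evolveImpl(modelTree, params))
}

.evolveImpl <- function(modelTree, params) {
  phy <- .asUnrooted(modelTree)
  elen <- .edgeLengthAbove(phy)
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop("model tree must have a branch length on every edge")
  }
  if (any(phy$edge.length < 0)) stop("branch lengths must be nonnegative")
  nt <- .ntip(phy)
  rooted <- .rootedAt(phy, nt + 1L)
  n <- length(rooted$children)
  L0 <- params@rootLength
  chars <- vector("list", n) # per-node site characters
  ids <- vector("list", n) # per-node homology column ids
  G <- seq_len(L0) # global column order
  nextId <- L0
  chars[[rooted$root]] <- sample(.BASES, L0, replace = TRUE)
  ids[[rooted$root]] <- seq_len(L0)
  ev <- data.frame(
    parent = phy$edge[, 1], child = phy$edge[, 2],
    substitutions = 0L, indels = 0L,
    pdist = NA_real_, sharedSites = 0L
  )
  edgeRowOf <- function(u, v) which(ev$parent == u & ev$child == v |
    ev$parent == v & ev$child == u)
  for (v in rooted$preorder) {
    if (v == rooted$root) next
    u <- rooted$parent[v]
    b <- elen[v]
    sq <- chars[[u]]
    id <- ids[[u]]
    nSub <- 0L
    # substitutions
    L <- length(sq)
    if (L > 0 && params@substitutionRate * b > 0) {
      k <- rpois(L, params@substitutionRate * b)
      nSub <- sum(k)
      while (any(k > 0)) {
        hit <- which(k > 0)
        sq[hit] <- .substituteBases(sq[hit], params@tsTvRatio)
        k <- k - (k > 0)
      }
    }
    # indels
    nIndel <- 0L
    if (L > 0 && params@indelRate * b > 0) {
      nIndel <- rpois(1, params@indelRate * b * L)
      for (e in seq_len(nIndel)) {
        len <- .drawGapLength(params@gapLengthModel)
        cur <- length(sq)
        if (runif(1) < params@insertionFraction) {
          pos <- sample.int(cur + 1L, 1L) - 1L # insert after site `pos`
          newIds <- nextId + seq_len(len)
          nextId <- nextId + len
          anchorPos <- if (pos == 0L) {
            if (cur > 0) match(id[1], G) - 1L else length(G)
          } else {
            match(id[pos], G)
          }
          G <- append(G, newIds, after = anchorPos)
          newChars <- sample(.BASES, len, replace = TRUE)
          sq <- append(sq, newChars, after = pos)
          id <- append(id, newIds, after = pos)
        } else {
          if (cur == 0L) next
          pos <- sample.int(cur, 1L)
          drop <- pos:min(pos + len - 1L, cur)
          sq <- sq[-drop]
          id <- id[-drop]
        }
      }
    }
    chars[[v]] <- sq
    ids[[v]] <- id
    row <- edgeRowOf(u, v)
    ev$substitutions[row] <- nSub
    ev$indels[row] <- nIndel
    shared <- match(ids[[u]], id)
    ok <- !is.na(shared)
    ev$sharedSites[row] <- sum(ok)
    ev$pdist[row] <- if (any(ok)) {
      mean(chars[[u]][ok] != sq[shared[ok]])
    } else {
      NA_real_
    }
  }
  # true alignment over leaf-covered columns
  leafIds <- unique(unlist(ids[seq_len(nt)], use.names = FALSE))
  Gkeep <- G[G %in% leafIds]
  rows <- vapply(seq_len(nt), function(v) {
    out <- rep("-", length(Gkeep))
    out[match(ids[[v]], Gkeep)] <- chars[[v]]
    paste(out, collapse = "")
  }, character(1))
  aln <- alignmentMatrix(phy$tip.label, rows)
  leafSeqs <- stats::setNames(.degap(rows), phy$tip.label)
  ref <- contractZeroEventBranches(phy, ev)
  new("SimulationRecord",
    modelTree = phy, leafSeqs = leafSeqs, trueAlignment = aln,
    branchEvents = ev, referenceTree = ref, params = params
  )
}

#' Contract zero-event branches of a model tree
#'
#' Internal branches on which the simulation recorded neither a
#' substitution nor an indel event are contracted; leaf branches are never
#' contracted. The result is the reference tree against which estimated
#' topologies are scored, since recovery of zero-event branches is a matter
#' of chance.
#'
#' @param modelTree the (unrooted) model `phylo`
#' @param branchEvents data.frame with columns `parent`, `child`,
#'   `substitutions`, `indels` covering every edge of `modelTree`
#' @return a `phylo`, possibly multifurcating
#' @export
contractZeroEventBranches <- function(modelTree, branchEvents) {
  phy <- .asUnrooted(modelTree)
  need <- c("parent", "child", "substitutions", "indels")
  if (!all(need %in% names(branchEvents))) {
    stop("branchEvents must have columns ", paste(need, collapse = ", "))
  }
  nt <- .ntip(phy)
  zero <- integer(0)
  for (k in seq_len(nrow(phy$edge))) {
    if (phy$edge[k, 2] <= nt) next
    row <- which(
      (branchEvents$parent == phy$edge[k, 1] &
        branchEvents$child == phy$edge[k, 2]) |
        (branchEvents$parent == phy$edge[k, 2] &
          branchEvents$child == phy$edge[k, 1])
    )
    if (length(row) == 0) {
      stop("missing event tally for edge ", phy$edge[k, 1], "-", phy$edge[k, 2])
    }
    if (branchEvents$substitutions[row[1]] == 0 &&
      branchEvents$indels[row[1]] == 0) {
      zero <- c(zero, k)
    }
  }
  if (length(zero) == 0) return(phy)
  contractEdges(phy, zero)
}

#' Empirical statistics of a simulation record
#'
#' Summarizes a [SimulationRecord-class] the way simulation-study condition
#' tables do: setwise average and maximum p-distance (normalized Hamming
#' distance over true-alignment rows, columns where both rows carry gaps
#' excluded), gap percentage of the alignment matrix, column count, average,
#' median and maximum gap-run length, edgewise average and maximum
#' p-distance over model-tree edges (over shared homologous sites), and the
#' resolution of the reference tree (internal edges divided by `n - 3`).
#'
#' @param record a [SimulationRecord-class]
#' @return one-row data.frame
#' @export
empiricalStats <- function(record) {
  stopifnot(is(record, "SimulationRecord"))
  m <- as.matrix(record@trueAlignment)
  n <- nrow(m)
  pd <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- !(m[i, ] == "-" & m[j, ] == "-")
      pd <- c(pd, mean(m[i, keep] != m[j, keep]))
    }
  }
  gaps <- m == "-"
  runLens <- unlist(apply(gaps, 1, function(r) {
    rl <- rle(r)
    rl$lengths[rl$values]
  }), use.names = FALSE)
  ep <- record@branchEvents$pdist
  refInternal <- length(.internalEdgeRows(.asUnrooted(record@referenceTree)))
  nt <- length(record@leafSeqs)
  data.frame(
    setwise_avg_pdist = mean(pd),
    setwise_max_pdist = max(pd),
    gap_percent = 100 * mean(gaps),
    columns = ncol(m),
    avg_gap_length = if (length(runLens)) mean(runLens) else 0,
    median_gap_length = if (length(runLens)) stats::median(runLens) else 0,
    max_gap_length = if (length(runLens)) max(runLens) else 0,
    edgewise_avg_pdist = mean(ep, na.rm = TRUE),
    edgewise_max_pdist = max(ep, na.rm = TRUE),
    resolution = if (nt > 3) refInternal / (nt - 3) else NA_real_
  )
}
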