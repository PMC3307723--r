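setOldClass("phylo")

#' Edit-cost scheme for treelength criteria
#'
#' Holds the per-event substitution costs (match, transition, transversion)
#' and the gap-cost parameters. A maximal gap of length `l > 0` costs
#' `gapOpen + gapExtend * l`; a zero-length gap costs 0. `gapOpen = 0` gives
#' a "simple" (length-proportional) gap cost, `gapOpen > 0` an "affine" one,
#' and `gapOpen = Inf` forbids indels entirely, which turns treelength into
#' the maximum parsimony score.
#'
#' @slot name scheme name (free text; presets use simple1/simple2/affine/mp)
#' @slot match cost of aligning two identical bases (normally 0)
#' @slot transition cost of A<->G or C<->T substitutions
#' @slot transversion cost of purine<->pyrimidine substitutions
#' @slot gapOpen gap opening cost; may be `Inf`
#' @slot gapExtend per-residue gap extension cost
#' @seealso [costPreset()], [gapCost()], [substitutionCost()]
#' @export
setClass("CostScheme",
  representation(
    name = "character",
    match = "numeric",
    transition = "numeric",
    transversion = "numeric",
    gapOpen = "numeric",
    gapExtend = "numeric"
  )
)

setValidity("CostScheme", function(object) {
  msgs <- character()
  one <- function(x) length(x) == 1 && !is.na(x)
  if (!one(object@name) || !nzchar(object@name)) {
    msgs <- c(msgs, "name must be a single non-empty string")
  }
  for (s in c("match", "transition", "transversion", "gapExtend")) {
    v <- slot(object, s)
    if (!one(v) || !is.finite(v) || v < 0) {
      msgs <- c(msgs, paste0(s, " must be a single finite nonnegative number"))
    }
  }
  g <- object@gapOpen
  if (!one(g) || is.nan(g) || g < 0) {
    msgs <- c(msgs, "gapOpen must be a single nonnegative number (Inf allowed)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Multiple sequence alignment matrix
#'
#' Rows are taxa, columns are homology classes; the gap symbol is `-`.
#' All rows have equal length and no column is entirely gaps.
#'
#' @slot taxa ordered taxon labels
#' @slot rows aligned sequences (one string per taxon, over A,C,G,T,N,-)
#' @seealso [alignmentMatrix()], [impliedAlignment()], [spFN()]
#' @export
setClass("AlignmentMatrix",
  representation(taxa = "character", rows = "character")
)

setValidity("AlignmentMatrix", function(object) {
  msgs <- character()
  n <- length(object@taxa)
  if (n == 0) msgs <- c(msgs, "alignment must contain at least one taxon")
  if (length(object@rows) != n) {
    msgs <- c(msgs, "taxa and rows must have equal length")
  }
  if (anyDuplicated(object@taxa)) msgs <- c(msgs, "taxon labels must be unique")
  if (any(!nzchar(object@taxa))) msgs <- c(msgs, "taxon labels must be non-empty")
  if (length(object@rows) == n && n > 0) {
    w <- unique(nchar(object@rows))
    if (length(w) > 1) {
      msgs <- c(msgs, "all rows must have identical length")
    } else if (length(w) == 1 && w > 0) {
      if (any(grepl("[^ACGTN-]", object@rows))) {
        msgs <- c(msgs, "rows may only contain A, C, G, T, N and '-'")
      } else {
        m <- .charMatrix(object@rows)
        if (any(colSums(m != "-") == 0)) {
          msgs <- c(msgs, "no column may be entirely gaps")
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' A tree with sequences assigned to every node and its treelength
#'
#' The result of fixed-tree treelength scoring: the (unrooted, standardized)
#' tree, a gap-free sequence at every node (leaves keep their input
#' sequences), and the treelength, i.e. the sum over edges of the edit
#' distance between the endpoint sequences under `scheme`. The treelength is
#' always recomputed from `nodeSequences`, so it can be verified by summing
#' [editDistance()] over the edges of `tree`.
#'
#' @slot tree an ape `phylo` object (unrooted for >= 3 taxa); node ids in
#'   `nodeSequences` refer to this tree's internal numbering
#' @slot nodeSequences character vector of gap-free sequences named by node
#'   id (`"1"` ... tips first, then internal nodes)
#' @slot treelength the edge-sum score
#' @slot scheme the [CostScheme-class] used
#' @slot method one of `"lifted"`, `"do"`, `"exact"`
#' @seealso [scoreFixedTree()], [impliedAlignment()], [treelength()]
#' @export
setClass("TreeAssignment",
  representation(
    tree = "phylo",
    nodeSequences = "character",
    treelength = "numeric",
    scheme = "CostScheme",
    method = "character"
  )
)

setValidity("TreeAssignment", function(object) {
  msgs <- character()
  phy <- object@tree
  nn <- length(phy$tip.label) + phy$Nnode
  if (length(object@nodeSequences) != nn) {
    msgs <- c(msgs, "every node of the tree must carry a sequence")
  }
  if (any(grepl("-", object@nodeSequences, fixed = TRUE))) {
    msgs <- c(msgs, "node sequences must be gap-free")
  }
  if (length(object@treelength) != 1 || is.na(object@treelength) ||
    object@treelength < 0) {
    msgs <- c(msgs, "treelength must be a single nonnegative number")
  }
  if (!object@method %in% c("lifted", "do", "exact")) {
    msgs <- c(msgs, "method must be one of lifted, do, exact")
  }
  if (length(msgs)) msgs else TRUE
})

#' A scored candidate tree
#'
#' A [TreeAssignment-class] together with a tag recording where the tree
#' came from in a [beetleSearch()] pool (`supplied`, `nj_baseline`,
#' `random_baseline`, or `neighbor-of:<origin>`).
#'
#' @slot assignment the scored [TreeAssignment-class]
#' @slot origin provenance tag
#' @export
setClass("ScoredTree",
  representation(assignment = "TreeAssignment", origin = "character")
)

#' The scored candidate pool of a treelength search
#'
#' @slot scored list of [ScoredTree-class] objects (non-empty, shared leaf set)
#' @slot scheme the [CostScheme-class] all candidates were scored under
#' @slot baselineIndex index of the normalization baseline in `scored`
#' @seealso [beetleSearch()], [bestTree()], [normalizedScore()], [poolSummary()]
#' @export
setClass("CandidatePool",
  representation(
    scored = "list",
    scheme = "CostScheme",
    baselineIndex = "integer"
  )
)

setValidity("CandidatePool", function(object) {
  msgs <- character()
  if (length(object@scored) == 0) msgs <- c(msgs, "pool must be non-empty")
  if (!all(vapply(object@scored, is, logical(1), class2 = "ScoredTree"))) {
    msgs <- c(msgs, "all pool entries must be ScoredTree objects")
  } else if (length(object@scored) > 0) {
    leafsets <- lapply(object@scored, function(s) {
      sort(s@assignment@tree$tip.label)
    })
    if (length(unique(leafsets)) > 1) {
      msgs <- c(msgs, "all pool trees must share one leaf set")
    }
  }
  bi <- object@baselineIndex
  if (length(bi) != 1 || is.na(bi) || bi < 1 || bi > length(object@scored)) {
    msgs <- c(msgs, "baselineIndex must index into the pool")
  }
  if (length(msgs)) msgs else TRUE
})

#' Parameters of the sequence-evolution simulator
#'
#' @slot rootLength number of sites in the root sequence
#' @slot substitutionRate expected substitutions per site per unit branch length
#' @slot indelRate expected indel events per site per unit branch length
#' @slot insertionFraction probability that an indel event is an insertion
#' @slot gapLengthModel list describing the indel length distribution; see
#'   [gapLengthModel()]
#' @slot tsTvRatio expected transitions per transversion (K2P-style)
#' @seealso [simParams()], [evolveSequences()]
#' @export
setClass("SimParams",
  representation(
    rootLength = "integer",
    substitutionRate = "numeric",
    indelRate = "numeric",
    insertionFraction = "numeric",
    gapLengthModel = "list",
    tsTvRatio = "numeric"
  )
)

setValidity("SimParams", function(object) {
  msgs <- character()
  if (object@rootLength < 1) msgs <- c(msgs, "rootLength must be >= 1")
  if (object@substitutionRate < 0 || object@indelRate < 0) {
    msgs <- c(msgs, "rates must be nonnegative")
  }
  f <- object@insertionFraction
  if (f < 0 || f > 1) msgs <- c(msgs, "insertionFraction must be in [0, 1]")
  if (object@tsTvRatio <= 0) msgs <- c(msgs, "tsTvRatio must be positive")
  g <- object@gapLengthModel
  if (is.null(g$type) || !g$type %in% c("geometric", "mixture")) {
    msgs <- c(msgs, "gapLengthModel$type must be 'geometric' or 'mixture'")
  } else if (g$type == "geometric") {
    if (is.null(g$p) || g$p <= 0 || g$p > 1) {
      msgs <- c(msgs, "geometric gap model needs p in (0, 1]")
    }
  } else {
    if (is.null(g$weights) || is.null(g$p) ||
      length(g$weights) != length(g$p) ||
      abs(sum(g$weights) - 1) > 1e-9 || any(g$weights < 0) ||
      any(g$p <= 0) || any(g$p > 1)) {
      msgs <- c(msgs, "mixture gap model needs matching weights (summing to 1) and p values in (0, 1]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Record of one simulated evolutionary history
#'
#' @slot modelTree the (unrooted) model tree with branch lengths
#' @slot leafSeqs named character vector of evolved, gap-free leaf sequences
#' @slot trueAlignment the true [AlignmentMatrix-class] implied by the
#'   recorded homology of every site
#' @slot branchEvents data.frame with one row per model-tree edge: `parent`,
#'   `child`, `substitutions`, `indels`, `pdist` (p-distance between the
#'   endpoint sequences over shared homologous sites), `sharedSites`
#' @slot referenceTree the model tree with every zero-event internal branch
#'   contracted (possibly multifurcating)
#' @slot params the [SimParams-class] used
#' @seealso [evolveSequences()], [empiricalStats()]
#' @export
setClass("SimulationRecord",
  representation(
    modelTree = "phylo",
    leafSeqs = "character",
    trueAlignment = "AlignmentMatrix",
    branchEvents = "data.frame",
    referenceTree = "phylo",
    params = "SimParams"
  )
)
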