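#' Treelength of a scored object
#'
#' For a [TreeAssignment-class] or [ScoredTree-class], the edge-sum score;
#' for a [CandidatePool-class], the vector of scores over the pool.
#'
#' @param x object to extract the treelength from
#' @return numeric treelength(s)
#' @export
setGeneric("treelength", function(x) standardGeneric("treelength"))

#' Node sequences of a tree assignment
#'
#' @param x a [TreeAssignment-class] or [ScoredTree-class]
#' @return named character vector of gap-free sequences, one per node
#' @export
setGeneric("nodeSequences", function(x) standardGeneric("nodeSequences"))

#' Origin tags of pool candidates
#'
#' @param x a [ScoredTree-class] or [CandidatePool-class]
#' @return character vector of provenance tags
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname treelength
#' @export
setMethod("treelength", "TreeAssignment", function(x) x@treelength)

#' @rdname treelength
#' @export
setMethod("treelength", "ScoredTree", function(x) x@assignment@treelength)

#' @rdname treelength
#' @export
setMethod("treelength", "CandidatePool", function(x) {
  vapply(x@scored, function(s) s@assignment@treelength, numeric(1))
})

#' @rdname nodeSequences
#' @export
setMethod("nodeSequences", "TreeAssignment", function(x) x@nodeSequences)

#' @rdname nodeSequences
#' @export
setMethod("nodeSequences", "ScoredTree", function(x) x@assignment@nodeSequences)

#' @rdname origin
#' @export
setMethod("origin", "ScoredTree", function(x) x@origin)

#' @rdname origin
#' @export
setMethod("origin", "CandidatePool", function(x) {
  vapply(x@scored, function(s) s@origin, character(1))
})

#' Taxa of an alignment
#'
#' @param x an [AlignmentMatrix-class]
#' @return character vector of taxon labels
#' @export
setGeneric("alnTaxa", function(x) standardGeneric("alnTaxa"))

#' @rdname alnTaxa
#' @export
setMethod("alnTaxa", "AlignmentMatrix", function(x) x@taxa)

#' Aligned rows of an alignment
#'
#' @param x an [AlignmentMatrix-class]
#' @return named character vector of aligned rows (with gaps)
#' @export
setGeneric("alnRows", function(x) standardGeneric("alnRows"))

#' @rdname alnRows
#' @export
setMethod("alnRows", "AlignmentMatrix", function(x) {
  stats::setNames(x@rows, x@taxa)
})

#' @describeIn alignmentMatrix coerce to a character matrix (rows = taxa)
#' @param x an [AlignmentMatrix-class]
#' @param ... ignored
#' @export
setMethod("as.matrix", "AlignmentMatrix", function(x, ...) {
  m <- .charMatrix(x@rows)
  rownames(m) <- x@taxa
  m
})

#' @describeIn alignmentMatrix alignment dimensions (taxa, columns)
#' @export
setMethod("dim", "AlignmentMatrix", function(x) {
  c(length(x@taxa), if (length(x@rows)) nchar(x@rows[1]) else 0L)
})
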