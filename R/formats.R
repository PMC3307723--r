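# Shared small helpers ------------------------------------------------------

.charMatrix <- function(rows) {
  if (length(rows) == 0) return(matrix(character(0), nrow = 0, ncol = 0))
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

.degap <- function(x) gsub("-", "", x, fixed = TRUE)

.validateSeqs <- function(seqs, aligned = FALSE, ambiguity = FALSE,
                          what = "sequence") {
  labs <- names(seqs)
  if (is.null(labs) || any(!nzchar(labs)) || anyNA(labs)) {
    stop("every ", what, " must have a non-empty label")
  }
  if (anyDuplicated(labs)) {
    stop(
      "duplicate ", what, " label(s): ",
      paste(unique(labs[duplicated(labs)]), collapse = ", ")
    )
  }
  alphabet <- if (ambiguity) "ACGTN" else "ACGT"
  pat <- paste0("[^", alphabet, if (aligned) "-", "]")
  bad <- grepl(pat, seqs)
  if (any(bad)) {
    stop(
      "illegal character(s) in record '", labs[which(bad)[1]], "'",
      if (!aligned) " (gap symbols are only allowed in aligned mode)"
    )
  }
  invisible(seqs)
}

# formats --------------------------------------------------------------------

#' Read sequences from a FASTA file
#'
#' Record order is preserved and sequences are upper-cased. `.` gap symbols
#' are normalized to `-`. In unaligned mode (the default) gap symbols are
#' rejected; in aligned mode they are allowed. Ambiguity codes are rejected
#' unless `ambiguity = TRUE`, which collapses every IUPAC ambiguity code to
#' `N` (treated by the cost model as matching any base at cost 0).
#'
#' @param path path to a FASTA file (ignored when `text` is given)
#' @param text optional FASTA text given directly
#' @param aligned allow the gap symbol `-`
#' @param ambiguity map IUPAC ambiguity codes to `N` instead of rejecting them
#' @return named character vector of sequences (a sequence set)
#' @examples
#' readFasta(text = ">a\nACGT\n>b\nACGA\n")
#' @export
readFasta <- function(path, text = NULL, aligned = FALSE, ambiguity = FALSE) {
  if (!is.null(text)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(text, path)
  }
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not parseable as FASTA: ", conditionMessage(e))
  )
  if (length(set) == 0) stop("empty FASTA input")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set)) # label = first header word
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (ambiguity) {
    seqs <- gsub("[RYSWKMBDHVU]", "N", seqs)
  }
  .validateSeqs(seqs, aligned = aligned, ambiguity = ambiguity,
    what = "FASTA record")
  seqs
}

#' Write sequences to a FASTA file
#'
#' One header line per record, sequence lines wrapped at 60 columns.
#'
#' @param seqs named character vector of sequences
#' @param path destination file
#' @return invisibly, `path`
#' @export
writeFasta <- function(seqs, path) {
  if (length(seqs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("every sequence must have a non-empty label")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a phylogenetic tree from Newick
#'
#' Supports polytomies, branch lengths and quoted labels via ape's Newick
#' parser; underscores in unquoted labels are kept literal. When the
#' top-level node has three or more children the tree is interpreted as
#' unrooted.
#'
#' @param path path to a Newick file (ignored when `text` is given)
#' @param text optional Newick string given directly
#' @return an ape `phylo` object
#' @examples
#' readNewick(text = "(a,b,(c,d));")
#' @export
readNewick <- function(path, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("no such file: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  text <- trimws(paste(text, collapse = ""))
  if (!nzchar(text)) stop("empty Newick input")
  if (!endsWith(text, ";")) stop("Newick string must end with ';'")
  bare <- gsub("'[^']*'", "", text) # ignore parens inside quoted labels
  if (lengths(regmatches(bare, gregexpr("(", bare, fixed = TRUE))) !=
    lengths(regmatches(bare, gregexpr(")", bare, fixed = TRUE)))) {
    stop("unbalanced parentheses in Newick string")
  }
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("not parseable as Newick: ", substr(text, 1, 60))
  }
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf labels in tree")
  if (any(!nzchar(phy$tip.label))) stop("every leaf must have a label")
  phy
}

#' Serialize a tree to a Newick string
#'
#' Round-trips through [readNewick()] preserve the unrooted bipartition set
#' and branch lengths (to the configured precision).
#'
#' @param tree an ape `phylo` object
#' @param digits digits used for branch lengths
#' @return a single Newick string terminated by `;`
#' @export
writeNewick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}
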