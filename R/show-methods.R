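setMethod("show", "CostScheme", function(object) {
  cat(
    "CostScheme '", object@name, "': match=", object@match,
    " transition=", object@transition,
    " transversion=", object@transversion,
    " gapOpen=", object@gapOpen, " gapExtend=", object@gapExtend, "\n",
    sep = ""
  )
  if (is.infinite(object@gapOpen)) {
    cat("  (indels forbidden: treelength equals the maximum parsimony score)\n")
  }
})

setMethod("show", "AlignmentMatrix", function(object) {
  d <- dim(object)
  cat("AlignmentMatrix: ", d[1], " taxa x ", d[2], " columns\n", sep = "")
  k <- min(d[1], 6L)
  w <- min(d[2], 60L)
  for (i in seq_len(k)) {
    cat(
      format(object@taxa[i], width = 12), " ",
      substr(object@rows[i], 1, w),
      if (d[2] > w) "...", "\n",
      sep = ""
    )
  }
  if (d[1] > k) cat("  ... and", d[1] - k, "more taxa\n")
})

setMethod("show", "TreeAssignment", function(object) {
  cat(
    "TreeAssignment (method=", object@method, ", scheme=",
    object@scheme@name, "): ", .ntip(object@tree), " leaves, treelength ",
    format(object@treelength, digits = 10), "\n",
    sep = ""
  )
})

setMethod("show", "ScoredTree", function(object) {
  cat(
    "ScoredTree [", object@origin, "] treelength ",
    format(object@assignment@treelength, digits = 10), "\n",
    sep = ""
  )
})

setMethod("show", "CandidatePool", function(object) {
  tl <- treelength(object)
  cat(
    "CandidatePool: ", length(object@scored), " scored trees (scheme ",
    object@scheme@name, ")\n",
    "  treelengths: min ", format(min(tl), digits = 10),
    ", baseline ", format(tl[object@baselineIndex], digits = 10),
    ", max ", format(max(tl), digits = 10), "\n",
    sep = ""
  )
})

setMethod("show", "SimParams", function(object) {
  g <- object@gapLengthModel
  cat(
    "SimParams: rootLength=", object@rootLength,
    " subRate=", object@substitutionRate,
    " indelRate=", object@indelRate,
    " insertionFraction=", object@insertionFraction,
    " tsTv=", object@tsTvRatio,
    " gapModel=", g$type, "(p=", paste(g$p, collapse = ","), ")\n",
    sep = ""
  )
})

setMethod("show", "SimulationRecord", function(object) {
  d <- dim(object@trueAlignment)
  cat(
    "SimulationRecord: ", length(object@leafSeqs), " leaves, true alignment ",
    d[1], " x ", d[2], ", ",
    sum(object@branchEvents$substitutions), " substitutions and ",
    sum(object@branchEvents$indels), " indel events\n",
    sep = ""
  )
})
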