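#' Construct an edit-cost scheme
#'
#' @param name scheme name
#' @param match cost of a match (normally 0)
#' @param transition cost of A<->G / C<->T substitutions
#' @param transversion cost of the remaining substitutions
#' @param gapOpen gap opening cost; `Inf` forbids indels (the maximum
#'   parsimony limit)
#' @param gapExtend per-residue gap extension cost
#' @return a [CostScheme-class]
#' @examples
#' costScheme("unit", transition = 1, transversion = 1, gapExtend = 1)
#' @export
costScheme <- function(name, match = 0, transition = 1, transversion = 1,
                       gapOpen = 0, gapExtend = 1) {
  new("CostScheme",
    name = as.character(name), match = as.numeric(match),
    transition = as.numeric(transition),
    transversion = as.numeric(transversion),
    gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend)
  )
}

#' Named treelength criteria
#'
#' Returns one of the four built-in cost schemes. `simple1` charges every
#' indel residue and substitution equally (cost 1). `simple2` charges indel
#' residues and transversions 2 and transitions 1. `affine` adds a positive
#' gap-opening charge (open 2, extend 0.5 per residue, transition 1,
#' transversion 2). `mp` sets the gap-open cost to infinity, which forbids
#' indels and makes treelength identical to the maximum parsimony score
#' (unit substitution costs). Every numeric field can be overridden.
#'
#' @param name one of `"simple1"`, `"simple2"`, `"affine"`, `"mp"`
#' @param ... overrides for any of `match`, `transition`, `transversion`,
#'   `gapOpen`, `gapExtend`
#' @return a [CostScheme-class]
#' @examples
#' costPreset("affine")
#' costPreset("simple2", transversion = 3)
#' @export
costPreset <- function(name = c("simple1", "simple2", "affine", "mp"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    simple1 = list(match = 0, transition = 1, transversion = 1,
      gapOpen = 0, gapExtend = 1),
    simple2 = list(match = 0, transition = 1, transversion = 2,
      gapOpen = 0, gapExtend = 2),
    affine = list(match = 0, transition = 1, transversion = 2,
      gapOpen = 2, gapExtend = 0.5),
    mp = list(match = 0, transition = 1, transversion = 1,
      gapOpen = Inf, gapExtend = 0)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) {
    stop("unknown cost field(s): ", paste(bad, collapse = ", "))
  }
  base[names(over)] <- over
  do.call(costScheme, c(list(name = name), base))
}

#' Cost of a gap of given length
#'
#' `gapCost(scheme, 0)` is 0; for `l > 0` the cost is
#' `gapOpen + gapExtend * l` (infinite when `gapOpen` is infinite).
#'
#' @param scheme a [CostScheme-class]
#' @param l nonnegative integer gap length(s)
#' @return numeric cost(s)
#' @examples
#' gapCost(costPreset("affine"), 0:3)
#' @export
gapCost <- function(scheme, l) {
  stopifnot(is(scheme, "CostScheme"))
  if (any(l < 0)) stop("gap length must be nonnegative")
  ifelse(l == 0, 0, scheme@gapOpen + scheme@gapExtend * l)
}

#' Substitution cost between two bases
#'
#' Symmetric in its arguments: `match` for identical bases, `transition`
#' for A<->G and C<->T, `transversion` otherwise. `N` matches any base at
#' cost 0 (permissive-ambiguity extension).
#'
#' @param scheme a [CostScheme-class]
#' @param x,y single bases in A, C, G, T (or N)
#' @return numeric cost
#' @examples
#' substitutionCost(costPreset("simple2"), "A", "G")
#' @export
substitutionCost <- function(scheme, x, y) {
  stopifnot(is(scheme, "CostScheme"))
  ok <- c("A", "C", "G", "T", "N")
  if (!all(x %in% ok) || !all(y %in% ok)) {
    stop("bases must be one of A, C, G, T (or N)")
  }
  ts <- (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  out <- ifelse(x == "N" | y == "N", 0,
    ifelse(x == y, scheme@match,
      ifelse(ts, scheme@transition, scheme@transversion)
    )
  )
  as.numeric(out)
}

# cost vector handed to the C++ core: match, ts, tv, open, ext
.costVector <- function(scheme) {
  c(
    scheme@match, scheme@transition, scheme@transversion,
    scheme@gapOpen, scheme@gapExtend
  )
}
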