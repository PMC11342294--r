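#' Construct a molecular formula
#'
#' @param counts Named integer/numeric vector of element counts, e.g.
#'   `c(C = 10, H = 13, N = 5, O = 3)`. Zero counts are dropped.
#' @return A [MolecularFormula-class].
#' @examples
#' molecularFormula(c(C = 10, H = 13, N = 5, O = 3))
#' @export
molecularFormula <- function(counts = integer()) {
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("counts must be named by element symbol")
    counts <- tapply(counts, names(counts), sum)   # merge duplicates
    counts <- counts[counts != 0]
    storage <- as.integer(round(counts))
    if (any(abs(counts - storage) > 1e-9))
      stop("element counts must be whole numbers")
    counts <- setNames(storage, names(counts))
    counts <- counts[order(match(names(counts), isotopeElements()))]
  } else counts <- setNames(integer(), character())
  new("MolecularFormula", counts = counts)
}

#' Parse a molecular formula string
#'
#' Parses Hill-style strings such as `"C221H282N82O137P22"`. Element
#' symbols are one capital letter optionally followed by one lowercase
#' letter; a missing count means 1. Underscores and whitespace are
#' ignored, so `"C_221_H_282_..."` also parses.
#'
#' @param x Formula string.
#' @return A [MolecularFormula-class].
#' @examples
#' parseFormula("C45H61N15O28P4")
#' @export
parseFormula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("[_[:space:]]", "", x)
  if (!nzchar(s)) return(molecularFormula())
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  tok <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula string: ", x)
  el <- sub("[0-9]*$", "", tok)
  nn <- sub("^[A-Za-z]+", "", tok)
  cnt <- ifelse(nzchar(nn), suppressWarnings(as.integer(nn)), 1L)
  molecularFormula(setNames(cnt, el))
}

#' @describeIn elementCounts Counts of a MolecularFormula.
#' @export
setMethod("elementCounts", "MolecularFormula", function(object) object@counts)

#' Format a molecular formula as a string
#' @param x A [MolecularFormula-class].
#' @param ... Ignored.
#' @return Character scalar such as `"C10H13N5O3"`.
#' @export
setMethod("as.character", "MolecularFormula", function(x, ...) {
  cnt <- x@counts
  if (!length(cnt)) return("")
  paste0(names(cnt), ifelse(cnt == 1L, "", cnt), collapse = "")
})

setMethod("show", "MolecularFormula", function(object) {
  cat("MolecularFormula:", if (length(object@counts)) as.character(object)
      else "(empty)", "\n")
})

.formulaArith <- function(a, b, sign) {
  els <- union(names(a@counts), names(b@counts))
  ca <- setNames(integer(length(els)), els); ca[names(a@counts)] <- a@counts
  cb <- setNames(integer(length(els)), els); cb[names(b@counts)] <- b@counts
  res <- ca + sign * cb
  if (any(res < 0L))
    stop("formula subtraction would give a negative count for: ",
         paste(els[res < 0L], collapse = ", "))
  molecularFormula(res)
}

#' @rdname MolecularFormula-class
#' @param e1,e2 Formulas (or an integer multiplier for `*`).
#' @export
setMethod("+", signature("MolecularFormula", "MolecularFormula"),
          function(e1, e2) .formulaArith(e1, e2, 1L))

#' @rdname MolecularFormula-class
#' @export
setMethod("-", signature("MolecularFormula", "MolecularFormula"),
          function(e1, e2) .formulaArith(e1, e2, -1L))

#' @rdname MolecularFormula-class
#' @export
setMethod("*", signature("MolecularFormula", "numeric"), function(e1, e2) {
  stopifnot(length(e2) == 1L, e2 >= 0, e2 == round(e2))
  molecularFormula(e1@counts * as.integer(e2))
})

#' @rdname MolecularFormula-class
#' @export
setMethod("*", signature("numeric", "MolecularFormula"),
          function(e1, e2) e2 * e1)

#' @describeIn monoisotopicMass Monoisotopic mass of a formula: the sum of
#'   count times lightest-isotope mass over all elements. The empty formula
#'   has mass 0.
#' @export
setMethod("monoisotopicMass", "MolecularFormula", function(object, ...) {
  cnt <- object@counts
  if (!length(cnt)) return(0)
  iso <- .elementIsotopes()
  bad <- setdiff(names(cnt), names(iso))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  sum(vapply(names(cnt), function(e) iso[[e]]$mass[1], 0) * cnt)
})
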