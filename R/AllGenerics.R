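#' Monoisotopic mass of a molecule
#'
#' Sum over elements of count times lightest-isotope mass.
#'
#' @param object A [MolecularFormula-class] (or object coercible to one).
#' @param ... Further arguments for methods.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopicMass(parseFormula("C221H282N82O137P22"))
#' @export
setGeneric("monoisotopicMass",
           function(object, ...) standardGeneric("monoisotopicMass"))

#' Peak probabilities of an aggregated isotopic distribution
#' @param object An [IsotopeDistribution-class].
#' @return Numeric vector of probabilities.
#' @export
setGeneric("probs", function(object) standardGeneric("probs"))

#' Center masses of an aggregated isotopic distribution
#' @param object An [IsotopeDistribution-class].
#' @return Numeric vector of intensity-weighted center masses (Da).
#' @export
setGeneric("centerMasses", function(object) standardGeneric("centerMasses"))

#' Most-abundant (mode) peak of a distribution
#'
#' Returns the aggregated peak with the highest probability. Ties are
#' broken toward the lower nucleon shift (lower mass).
#'
#' @param object An [IsotopeDistribution-class].
#' @param ... Further arguments for methods.
#' @return A list with `offset` (integer nucleon shift from the
#'   monoisotopic peak, 0-based) and `mass` (center mass in Da).
#' @export
setGeneric("mostAbundantPeak",
           function(object, ...) standardGeneric("mostAbundantPeak"))

#' Intensity-weighted average mass
#'
#' @param object An [IsotopeDistribution-class] or [Envelope-class].
#' @param ... Further arguments for methods.
#' @return Average mass in Da: sum(q * mu) / sum(q).
#' @export
setGeneric("averageMass", function(object, ...) standardGeneric("averageMass"))

#' Element counts of a molecular formula
#' @param object A [MolecularFormula-class].
#' @return Named integer vector of element counts.
#' @export
setGeneric("elementCounts", function(object) standardGeneric("elementCounts"))
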