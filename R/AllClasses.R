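#' Molecular formula
#'
#' A multiset of chemical elements, stored as a named integer vector of
#' nonnegative counts. Supported elements are those present in the isotope
#' table (by default C, H, N, O, P, S, F, Na, K).
#'
#' @slot counts Named integer vector, element symbol -> count.
#' @seealso [molecularFormula()], [parseFormula()], [monoisotopicMass()]
#' @exportClass MolecularFormula
setClass("MolecularFormula", representation(counts = "integer"))

setValidity("MolecularFormula", function(object) {
  cnt <- object@counts
  if (length(cnt) && is.null(names(cnt)))
    return("counts must be a named integer vector")
  if (any(is.na(cnt)) || any(cnt < 0L))
    return("element counts must be nonnegative integers")
  known <- isotopeElements()
  bad <- setdiff(names(cnt), known)
  if (length(bad))
    return(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  TRUE
})

#' Aggregated isotopic distribution
#'
#' The first K peaks of the aggregated isotopic distribution of a molecule:
#' probabilities of the nominal +0, +1, +2, ... nucleon shifts and the
#' intensity-weighted exact center mass of each aggregated peak. The first
#' center mass equals the monoisotopic mass.
#'
#' @slot probs Numeric vector of peak probabilities (q_0, q_1, ...).
#' @slot masses Numeric vector of center masses in Da, same length.
#' @seealso [aggregatedDistribution()], [bruteForceDistribution()],
#'   [mostAbundantPeak()], [averageMass()]
#' @exportClass IsotopeDistribution
setClass("IsotopeDistribution",
         representation(probs = "numeric", masses = "numeric"))

setValidity("IsotopeDistribution", function(object) {
  q <- object@probs
  m <- object@masses
  if (length(q) != length(m))
    return("probs and masses must have equal length")
  if (length(q) < 1L)
    return("distribution must have at least one peak")
  if (any(q < -1e-12) || any(q > 1 + 1e-9))
    return("probabilities must lie in [0, 1]")
  if (sum(q) > 1 + 1e-9)
    return("probabilities must sum to at most 1")
  if (length(m) > 1L && any(diff(m) <= 0))
    return("center masses must be strictly increasing")
  TRUE
})

#' Isotopologue envelope
#'
#' A deconvoluted neutral-mass isotopic envelope: a peak list of
#' (neutral mass, intensity) pairs sorted by mass. Intensities are in
#' arbitrary units; for isotopologue envelopes consecutive peaks are spaced
#' by approximately 1 Da.
#'
#' @slot mass Numeric vector of neutral masses (Da), strictly increasing.
#' @slot intensity Numeric vector of nonnegative intensities.
#' @slot metadata List of optional metadata (e.g. scan id, source charge).
#' @seealso [envelope()], [readEnvelopes()], [selectMostAbundant()]
#' @exportClass Envelope
setClass("Envelope",
         representation(mass = "numeric", intensity = "numeric",
                        metadata = "list"))

setValidity("Envelope", function(object) {
  if (length(object@mass) < 1L)
    return("envelope must contain at least one peak")
  if (length(object@mass) != length(object@intensity))
    return("mass and intensity must have equal length")
  if (any(!is.finite(object@mass)))
    return("masses must be finite")
  if (length(object@mass) > 1L && any(diff(object@mass) <= 0))
    return("masses must be strictly increasing")
  if (any(is.na(object@intensity)) || any(object@intensity < 0))
    return("intensities must be nonnegative")
  TRUE
})

#' Fitted monoisotopic-mass predictor
#'
#' The two-stage piecewise-linear predictor of monoisotopic mass from
#' most-abundant mass: a global linear model (alpha, beta), one residual
#' line per branch (a branch is the integer offset between the
#' most-abundant and the monoisotopic aggregated peak), the optimal-Bayes
#' cut masses separating adjacent branches together with their
#' sliding-window proportion curves, and the empirical interval of
#' (average mass - most-abundant mass) used by the peak-selection
#' correction.
#'
#' @slot chemistry "DNA" or "RNA".
#' @slot alpha Intercept of the global linear model (Da).
#' @slot beta Slope of the global linear model (dimensionless).
#' @slot lines data.frame with columns branch, intercept, slope, domainLo,
#'   domainHi: the per-branch residual lines and their mass domains.
#' @slot cuts Numeric vector of strictly increasing interior cut masses
#'   (Da); length is one less than the number of branches.
#' @slot curves List of data.frames (mass, propUpper), one per cut: the
#'   sliding-window proportion of the lower-offset ("upper") residual line.
#' @slot amMa Numeric length-2: empirical [lo, hi] of AM - MA (Da).
#' @slot k Integer, number of aggregated peaks used in training.
#' @slot provenance List (seed, training size, package version, ...).
#' @seealso [fitMind()], [predictMono()], [writeMindModel()]
#' @exportClass MindModel
setClass("MindModel",
         representation(chemistry = "character", alpha = "numeric",
                        beta = "numeric", lines = "data.frame",
                        cuts = "numeric", curves = "list",
                        amMa = "numeric", k = "integer",
                        provenance = "list"))

setValidity("MindModel", function(object) {
  if (!object@chemistry %in% c("DNA", "RNA"))
    return("chemistry must be 'DNA' or 'RNA'")
  need <- c("branch", "intercept", "slope", "domainLo", "domainHi")
  if (!all(need %in% names(object@lines)))
    return("lines must have columns branch, intercept, slope, domainLo, domainHi")
  if (nrow(object@lines) < 1L)
    return("at least one residual line is required")
  if (is.unsorted(object@lines$branch, strictly = TRUE))
    return("branches must be strictly increasing")
  if (length(object@cuts) != nrow(object@lines) - 1L)
    return("number of cuts must be one less than the number of branches")
  if (length(object@cuts) > 1L && any(diff(object@cuts) <= 0))
    return("cut masses must be strictly increasing")
  if (length(object@amMa) != 2L || object@amMa[1] >= object@amMa[2])
    return("amMa must be a length-2 interval with lo < hi")
  TRUE
})
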