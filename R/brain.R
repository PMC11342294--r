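#' Aggregated isotopic distribution of a molecular formula
#'
#' Computes the first `K` peaks of the aggregated isotopic distribution
#' (probabilities and exact intensity-weighted center masses) directly from
#' the elemental composition, using power-sum recurrences on the
#' element-wise isotope polynomials: the log of the probability generating
#' polynomial is linear in the element counts, so peak probabilities follow
#' from a Newton-Girard-style exponentiation recurrence, and the
#' mass-moment series is the convolution of the probabilities with a
#' rational series that is again linear in the counts.
#'
#' @param f A [MolecularFormula-class] (or a formula string).
#' @param K Number of aggregated peaks to return (default 30).
#' @return An [IsotopeDistribution-class].
#' @examples
#' d <- aggregatedDistribution(parseFormula("C10H13N5O3"), K = 5)
#' probs(d)
#' centerMasses(d)[1]  # the monoisotopic mass
#' @export
aggregatedDistribution <- function(f, K = 30L) {
  if (is.character(f)) f <- parseFormula(f)
  stopifnot(is(f, "MolecularFormula"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  cnt <- elementCounts(f)
  if (!length(cnt) || sum(cnt) == 0L) stop("formula must be nonzero")
  st <- .seriesTables(names(cnt), K)
  lam <- if (K > 1L) as.numeric(cnt %*% st$L) else numeric(0)
  gam <- as.numeric(cnt %*% st$G)
  q <- numeric(K)
  q[1] <- exp(sum(cnt * st$logA0))
  if (K > 1L) for (j in seq_len(K - 1L)) {
    l <- seq_len(j)
    q[j + 1L] <- sum(l * lam[l] * q[j - l + 1L]) / j
  }
  eta <- vapply(seq_len(K), function(j) sum(gam[seq_len(j)] * q[j:1]), 0)
  # far-tail coefficients below the roundoff floor of the recurrence carry
  # no information; zero them and interpolate their center masses
  q[q < max(q) * 1e-13] <- 0
  new("IsotopeDistribution", probs = q, masses = .centerMassFill(q, eta))
}

# masses = eta/q where q > 0; zero-probability peaks get unit-spacing
# interpolated/extrapolated center masses so the mass axis stays monotone
.centerMassFill <- function(q, eta) {
  K <- length(q)
  nz <- which(q > 0)
  masses <- numeric(K)
  masses[nz] <- eta[nz] / q[nz]
  miss <- setdiff(seq_len(K), nz)
  if (length(miss)) {
    sp <- if (length(nz) >= 2L)
      (masses[max(nz)] - masses[min(nz)]) / (max(nz) - min(nz)) else 1.003
    for (j in miss) {
      below <- nz[nz < j]
      if (length(below)) {
        r <- max(below); masses[j] <- masses[r] + (j - r) * sp
      } else {
        r <- min(nz); masses[j] <- masses[r] - (r - j) * sp
      }
    }
  }
  masses
}

#' Brute-force aggregated isotopic distribution (reference oracle)
#'
#' Computes the same quantity as [aggregatedDistribution()] by explicit
#' convolution: each atom contributes its isotope vector (probability and
#' probability-weighted mass, indexed by nucleon shift), and atom vectors
#' are convolved one by one, truncated at `K` peaks. Exact but linear in
#' the atom count, so guarded to small molecules; intended as an
#' independent test oracle.
#'
#' @param f A [MolecularFormula-class] (or a formula string).
#' @param K Number of aggregated peaks (default 30).
#' @param maxAtoms Guard on the total atom count (default 5000).
#' @return An [IsotopeDistribution-class].
#' @export
bruteForceDistribution <- function(f, K = 30L, maxAtoms = 5000L) {
  if (is.character(f)) f <- parseFormula(f)
  stopifnot(is(f, "MolecularFormula"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  cnt <- elementCounts(f)
  if (!length(cnt) || sum(cnt) == 0L) stop("formula must be nonzero")
  if (sum(cnt) > maxAtoms)
    stop("formula too large for explicit convolution (", sum(cnt),
         " atoms > ", maxAtoms, ")")
  iso <- .elementIsotopes()
  # state: p[j] = probability of shift j-1; mm[j] = sum prob * mass
  p <- c(1, numeric(K - 1L)); mm <- numeric(K)
  conv <- function(p1, mm1, p2, mm2) {
    pr <- numeric(K); mr <- numeric(K)
    for (j in seq_len(K)) {
      k <- seq_len(j)
      pr[j] <- sum(p1[k] * p2[j - k + 1L])
      mr[j] <- sum(mm1[k] * p2[j - k + 1L] + p1[k] * mm2[j - k + 1L])
    }
    list(p = pr, mm = mr)
  }
  for (e in names(cnt)) {
    z <- iso[[e]]
    ap <- numeric(K); am <- numeric(K)
    keep <- z$shift < K
    ap[z$shift[keep] + 1L] <- z$abund[keep]
    am[z$shift[keep] + 1L] <- z$abund[keep] * z$mass[keep]
    # atom^n via binary exponentiation
    n <- cnt[[e]]
    bp <- ap; bm <- am; first <- TRUE
    accp <- NULL; accm <- NULL
    while (n > 0L) {
      if (n %% 2L == 1L) {
        if (is.null(accp)) { accp <- bp; accm <- bm }
        else { r <- conv(accp, accm, bp, bm); accp <- r$p; accm <- r$mm }
      }
      n <- n %/% 2L
      if (n > 0L) { r <- conv(bp, bm, bp, bm); bp <- r$p; bm <- r$mm }
    }
    r <- conv(p, mm, accp, accm); p <- r$p; mm <- r$mm
  }
  new("IsotopeDistribution", probs = p, masses = .centerMassFill(p, mm))
}

#' @describeIn mostAbundantPeak Argmax peak of an aggregated distribution;
#'   ties go to the lower offset.
#' @export
setMethod("mostAbundantPeak", "IsotopeDistribution", function(object, ...) {
  i <- which.max(object@probs)   # which.max takes the first maximum
  list(offset = i - 1L, mass = object@masses[i])
})

#' @describeIn averageMass Intensity-weighted average over the peaks of a
#'   truncated aggregated distribution.
#' @export
setMethod("averageMass", "IsotopeDistribution", function(object, ...) {
  s <- sum(object@probs)
  if (s <= 0) stop("all peak probabilities are zero")
  sum(object@probs * object@masses) / s
})

#' @describeIn probs Probabilities slot.
#' @export
setMethod("probs", "IsotopeDistribution", function(object) object@probs)

#' @describeIn centerMasses Center-mass slot.
#' @export
setMethod("centerMasses", "IsotopeDistribution", function(object) object@masses)

setMethod("show", "IsotopeDistribution", function(object) {
  K <- length(object@probs)
  cat("IsotopeDistribution with", K, "aggregated peaks\n")
  cat("  monoisotopic mass:", format(object@masses[1], nsmall = 4), "Da\n")
  mp <- mostAbundantPeak(object)
  cat("  most-abundant peak: offset", mp$offset, "at",
      format(mp$mass, nsmall = 4), "Da\n")
  cat("  total probability:", format(sum(object@probs), digits = 6), "\n")
})

# Batch summaries for a matrix of element counts (columns named by element
# symbol). Returns a data.frame with one row per input row:
# mono, modeOffset, modeMass, am, sumQ, monoModeRatio.
.brainBatch <- function(ec, K = 30L) {
  K <- as.integer(K)
  els <- colnames(ec)
  st <- .seriesTables(els, K)
  storage.mode(ec) <- "integer"
  out <- brain_summaries_cpp(ec, st$L, st$G, st$logA0, st$mono, K)
  colnames(out) <- c("mono", "modeOffset", "modeMass", "am", "sumQ",
                     "monoModeRatio")
  as.data.frame(out)
}

# Full q and mu matrices (n x K) for a matrix of element counts.
.brainFull <- function(ec, K = 30L) {
  K <- as.integer(K)
  st <- .seriesTables(colnames(ec), K)
  storage.mode(ec) <- "integer"
  brain_full_cpp(ec, st$L, st$G, st$logA0, st$mono, K)
}
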