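#' Isotope table
#'
#' Loads the table of stable-isotope masses and abundances used by all mass
#' computations. The packaged default pins the NIST/IUPAC values
#' conventionally used by isotope-pattern calculators for C, H, N, O, P,
#' S, F, Na and K. A custom table
#' can be supplied as a CSV with columns `element`, `nucleon_number`,
#' `mass_da`, `abundance`; per-element abundances must sum to one and
#' masses must increase with nucleon number.
#'
#' @param path Path to a CSV isotope table; `NULL` (default) uses the
#'   packaged table.
#' @return A data.frame with attribute `"version"` (provenance string).
#' @examples
#' head(isotopeTable())
#' @export
isotopeTable <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.oligomind_cache$isotab)) return(.oligomind_cache$isotab)
    path <- system.file("extdata", "isotopes.csv", package = "oligomind")
    default <- TRUE
  } else default <- FALSE
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "nucleon_number", "mass_da", "abundance")
  if (!all(need %in% names(tab)))
    stop("isotope table must have columns ", paste(need, collapse = ", "))
  for (el in unique(tab$element)) {
    sub <- tab[tab$element == el, ]
    sub <- sub[order(sub$nucleon_number), ]
    if (abs(sum(sub$abundance) - 1) > 1e-10)
      stop("abundances of element ", el, " do not sum to 1")
    if (any(diff(sub$mass_da) <= 0))
      stop("isotope masses of element ", el, " are not strictly increasing")
  }
  attr(tab, "version") <- if (default) "NIST-IUPAC-1998" else basename(path)
  if (default) .oligomind_cache$isotab <- tab
  tab
}

#' Elements covered by the isotope table
#' @return Character vector of element symbols.
#' @export
isotopeElements <- function() unique(isotopeTable()$element)

# Per-element isotope data as a list:
# list(<el> = list(shift=, mass=, abund=)); shift is the nucleon-number
# offset from the lightest isotope (may skip values, e.g. S has no +3).
.elementIsotopes <- function() {
  if (!is.null(.oligomind_cache$eliso)) return(.oligomind_cache$eliso)
  tab <- isotopeTable()
  out <- lapply(split(tab, tab$element), function(sub) {
    sub <- sub[order(sub$nucleon_number), ]
    list(shift = sub$nucleon_number - sub$nucleon_number[1],
         mass = sub$mass_da, abund = sub$abundance)
  })
  .oligomind_cache$eliso <- out
  out
}

# Power series log of 1 + sum p_l x^l, to order K-1 (L_0 = 0 dropped).
.seriesLog <- function(p, K) {
  n <- max(K - 1L, 1L)
  p <- c(p, numeric(max(0L, n - length(p))))[seq_len(n)]
  L <- numeric(K - 1L)
  for (l in seq_len(K - 1L)) {
    s <- l * p[l]
    if (l > 1L) {
      k <- seq_len(l - 1L)
      s <- s - sum(k * L[k] * p[l - k])
    }
    L[l] <- s / l
  }
  L
}

# Power series of r / (1 + sum p_l x^l), both indexed from x^0, to order K-1.
.seriesDiv <- function(r, p, K) {
  g <- numeric(K)
  pad <- function(v, n) c(v, numeric(max(0L, n - length(v))))[seq_len(n)]
  r <- pad(r, K)
  pfull <- pad(c(1, p), K)
  for (l in seq_len(K)) {
    s <- r[l]
    if (l > 1L) {
      k <- seq_len(l - 1L)
      s <- s - sum(g[k] * pfull[l - k + 1L])
    }
    g[l] <- s
  }
  g
}

# Per-element coefficient tables for the aggregated-distribution
# recurrences, for elements `els`, truncated at K peaks:
#   logA0[e]  log abundance of the lightest isotope
#   mono[e]   lightest-isotope mass
#   L[e, l]   series log coefficients of P_e(x)/a_e0, l = 1..K-1
#   G[e, l]   series coefficients of R_e(x)/P_e(x), l = 0..K-1, where
#             R_e(x) = sum_i a_i m_i x^{shift_i}
# Cached per (elements, K).
.seriesTables <- function(els, K) {
  key <- paste(c(K, els), collapse = "|")
  hit <- .oligomind_cache$series[[key]]
  if (!is.null(hit)) return(hit)
  iso <- .elementIsotopes()
  bad <- setdiff(els, names(iso))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  E <- length(els)
  L <- matrix(0, E, max(K - 1L, 1L), dimnames = list(els, NULL))
  G <- matrix(0, E, K, dimnames = list(els, NULL))
  logA0 <- mono <- setNames(numeric(E), els)
  for (e in els) {
    z <- iso[[e]]
    maxsh <- max(z$shift)
    p <- numeric(maxsh)                       # coefficients of x^1..x^maxsh
    r <- numeric(maxsh + 1L)                  # coefficients of x^0..x^maxsh
    a0 <- z$abund[1]
    for (i in seq_along(z$shift)) {
      sh <- z$shift[i]
      if (sh > 0L) p[sh] <- z$abund[i] / a0
      r[sh + 1L] <- z$abund[i] / a0 * z$mass[i]
    }
    logA0[e] <- log(a0)
    mono[e] <- z$mass[1]
    if (K > 1L) L[e, ] <- .seriesLog(p, K)
    G[e, ] <- .seriesDiv(r, p, K)
  }
  out <- list(els = els, logA0 = logA0, mono = mono, L = L, G = G)
  if (is.null(.oligomind_cache$series)) .oligomind_cache$series <- list()
  .oligomind_cache$series[[key]] <- out
  out
}
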