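#' Enumerate the oligonucleotide composition universe
#'
#' Every multiset of the four bases with total length between `nMin` and
#' `nMax`, each exactly once. Distinct compositions have distinct
#' elemental compositions and hence distinct masses. The number of
#' compositions is `choose(nMax + 4, 4) - choose(nMin + 3, 4)`
#' (3,321,890 for lengths 5 to 92).
#'
#' @param nMin,nMax Length range (defaults 5 and 92).
#' @param chemistry `"DNA"` or `"RNA"` (stored as an attribute; RNA
#'   columns are named with U in place of T).
#' @return data.frame of integer base counts, one row per composition,
#'   with attribute `"chemistry"`.
#' @examples
#' nrow(enumerateCompositions(1, 2))  # 4 + 10 multisets
#' @export
enumerateCompositions <- function(nMin = 5L, nMax = 92L,
                                  chemistry = c("DNA", "RNA")) {
  chemistry <- match.arg(chemistry)
  nMin <- as.integer(nMin); nMax <- as.integer(nMax)
  if (nMin < 1L || nMin > nMax) stop("need 1 <= nMin <= nMax")
  # three-level vectorized expansion of {(a,c,g,t): nMin <= a+c+g+t <= nMax}
  a <- rep.int(0:nMax, nMax + 1L - 0:nMax)
  c_ <- sequence(nMax + 1L - 0:nMax, from = 0L)
  rem1 <- nMax - a - c_
  a <- rep.int(a, rem1 + 1L); c_ <- rep.int(c_, rem1 + 1L)
  g <- sequence(rem1 + 1L, from = 0L)
  s <- a + c_ + g
  t0 <- pmax(0L, nMin - s)
  len <- nMax - s - t0 + 1L
  keep <- len > 0L
  a <- rep.int(a[keep], len[keep]); c_ <- rep.int(c_[keep], len[keep])
  g <- rep.int(g[keep], len[keep])
  t <- sequence(len[keep], from = t0[keep])
  out <- data.frame(A = a, C = c_, G = g, T = t)
  if (chemistry == "RNA") names(out)[4] <- "U"
  attr(out, "chemistry") <- chemistry
  out
}

#' Build the mass table of a composition universe
#'
#' Computes, for every composition, the monoisotopic mass, the
#' most-abundant aggregated peak (offset and center mass), the
#' intensity-weighted average mass and the retained probability of the
#' K-peak truncation. The default terminal convention is the nucleotide
#' monophosphate polymer (`"phosphate"`), the convention of the enumerated
#' training universe.
#'
#' @param compositions data.frame from [enumerateCompositions()] (or any
#'   data.frame with base-count columns and a `"chemistry"` attribute).
#' @param K Number of aggregated peaks (default 30).
#' @param terminal Terminal convention, see [oligoChemistry].
#' @param chunkSize Rows per evaluation chunk (memory guard).
#' @return data.frame: the base counts plus columns `n`, `mono`,
#'   `modeOffset`, `modeMass`, `am`, `sumQ`, `monoModeRatio`, with
#'   attributes `"chemistry"`, `"terminal"` and `"k"`.
#' @export
buildMassTable <- function(compositions, K = 30L,
                           terminal = c("phosphate", "OH"),
                           chunkSize = 500000L) {
  terminal <- match.arg(terminal)
  chemistry <- attr(compositions, "chemistry")
  if (is.null(chemistry)) chemistry <- "DNA"
  letters <- .baseLetters(chemistry)
  stopifnot(all(letters %in% names(compositions)))
  bases <- as.matrix(compositions[, letters, drop = FALSE])
  N <- nrow(bases)
  res <- vector("list", ceiling(N / chunkSize))
  for (ci in seq_along(res)) {
    i0 <- (ci - 1L) * chunkSize + 1L
    i1 <- min(ci * chunkSize, N)
    ec <- .elementCountsFromBases(bases[i0:i1, , drop = FALSE],
                                  chemistry, terminal)
    res[[ci]] <- .brainBatch(ec, K)
  }
  out <- do.call(rbind, res)
  low <- out$sumQ < 0.999
  if (any(low))
    warning(sum(low), " composition(s) retain < 99.9% of the isotope ",
            "distribution within K = ", K, " peaks")
  out <- cbind(compositions[, letters, drop = FALSE],
               n = as.integer(rowSums(bases)), out)
  attr(out, "chemistry") <- chemistry
  attr(out, "terminal") <- terminal
  attr(out, "k") <- as.integer(K)
  out
}

#' Largest mass at which the monoisotopic peak retains a given intensity
#' ratio to the most-abundant peak
#'
#' Scans the mass table for the largest monoisotopic mass among records
#' whose mono-to-mode intensity ratio is at least `ratio`. At a ratio of
#' 0.05 over the DNA universe this is where the monoisotopic peak drops
#' below 5% of the mode (about 11,181 Da).
#'
#' @param table Mass table from [buildMassTable()].
#' @param ratio Intensity ratio threshold in (0, 1).
#' @return Mass in Da.
#' @export
monoToModeRatioThreshold <- function(table, ratio = 0.05) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("ratio must lie in (0, 1)")
  keep <- table$monoModeRatio >= ratio
  if (!any(keep)) stop("no record satisfies the ratio threshold")
  max(table$mono[keep])
}

#' Random training/validation split of a mass table
#'
#' Holds out `size` randomly chosen records as a validation set; the rest
#' form the training set. Reproducible under a fixed seed; the global RNG
#' state is restored on exit.
#'
#' @param table Mass table from [buildMassTable()].
#' @param size Validation size (default 10000). `0` returns the full
#'   table as training.
#' @param seed Optional integer seed.
#' @return List with elements `training` and `validation`.
#' @export
splitMassTable <- function(table, size = 10000L, seed = NULL) {
  size <- as.integer(size)
  if (size < 0L || size >= nrow(table))
    stop("validation size must be in [0, nrow(table))")
  idx <- if (size == 0L) integer(0) else
    .withSeed(seed, sample.int(nrow(table), size))
  atts <- attributes(table)[c("chemistry", "terminal", "k")]
  training <- if (length(idx)) table[-idx, , drop = FALSE] else table
  validation <- table[idx, , drop = FALSE]
  attributes(training)[names(atts)] <- atts
  attributes(validation)[names(atts)] <- atts
  list(training = training, validation = validation)
}

# evaluate expr under a temporary RNG state seeded with `seed`;
# expr is a promise, so it runs after set.seed()
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
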