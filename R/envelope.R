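#' Construct an isotopologue envelope
#'
#' @param mass Numeric vector of neutral masses (Da). Unsorted input is
#'   sorted (with its intensities) with a warning.
#' @param intensity Numeric vector of nonnegative intensities.
#' @param metadata Optional list of metadata.
#' @return An [Envelope-class].
#' @export
envelope <- function(mass, intensity, metadata = list()) {
  if (length(mass) > 1L && is.unsorted(mass, strictly = TRUE)) {
    warning("envelope masses are not sorted; sorting")
    o <- order(mass)
    mass <- mass[o]; intensity <- intensity[o]
  }
  new("Envelope", mass = as.numeric(mass), intensity = as.numeric(intensity),
      metadata = metadata)
}

#' Theoretical envelope of an aggregated distribution
#' @param d An [IsotopeDistribution-class].
#' @return An [Envelope-class] with the peak probabilities as intensities.
#' @export
asEnvelope <- function(d) {
  stopifnot(is(d, "IsotopeDistribution"))
  envelope(centerMasses(d), probs(d))
}

#' Peak masses and intensities of an envelope
#' @param e An [Envelope-class].
#' @return data.frame with columns `mass`, `intensity`.
#' @export
peaks <- function(e) data.frame(mass = e@mass, intensity = e@intensity)

#' @describeIn averageMass Intensity-weighted mean of the peak masses of
#'   an envelope, computed over the full envelope.
#' @export
setMethod("averageMass", "Envelope", function(object, ...) {
  s <- sum(object@intensity)
  if (s <= 0) stop("all envelope intensities are zero")
  sum(object@intensity * object@mass) / s
})

setMethod("show", "Envelope", function(object) {
  cat("Envelope with", length(object@mass), "peaks,",
      format(object@mass[1], nsmall = 2), "-",
      format(object@mass[length(object@mass)], nsmall = 2), "Da\n")
})

#' Most-abundant peak selection with average-mass correction
#'
#' Starts from the most intense peak (ties to the lower mass) and checks
#' the difference between the envelope's intensity-weighted average mass
#' (AM) and the candidate peak mass against the empirical AM-MA interval
#' of the theoretical universe. If the difference exceeds the upper bound
#' the candidate is too light and the next heavier peak is taken; below
#' the lower bound, the previous peak. The walk repeats until the
#' difference falls inside the interval. The walk is bounded (at most two
#' passes over the envelope, with revisit detection): an envelope on
#' which no peak satisfies the interval - typically a mixture of
#' overlapping envelopes - is reported as uncorrectable
#' (`ok = FALSE` with a warning).
#'
#' @param e An [Envelope-class].
#' @param interval Length-2 numeric `[lo, hi]` in Da: the acceptance
#'   interval for AM minus the selected mass. Defaults to the DNA
#'   universe interval; pass `amMaInterval(model)` for a fitted model.
#' @return List with `index` (peak index), `mass` (selected peak mass,
#'   Da), `steps` (number of correction steps taken), `ok` (logical).
#'   On failure `index` and `mass` are `NA`.
#' @export
selectMostAbundant <- function(e, interval = c(0.115, 1.21)) {
  stopifnot(is(e, "Envelope"), length(interval) == 2L,
            interval[1] < interval[2])
  am <- averageMass(e)
  i <- which.max(e@intensity)          # ties break toward lower mass
  visited <- logical(length(e@mass))
  steps <- 0L
  maxSteps <- 2L * length(e@mass)
  repeat {
    if (i < 1L || i > length(e@mass) || visited[i] || steps > maxSteps) {
      warning("uncorrectable envelope: no peak satisfies the AM-MA ",
              "interval (possibly a mixture of envelopes)")
      return(list(index = NA_integer_, mass = NA_real_, steps = steps,
                  ok = FALSE))
    }
    visited[i] <- TRUE
    d <- am - e@mass[i]
    if (d > interval[2]) i <- i + 1L          # candidate too light
    else if (d < interval[1]) i <- i - 1L     # candidate too heavy
    else return(list(index = i, mass = e@mass[i], steps = steps, ok = TRUE))
    steps <- steps + 1L
  }
}

#' Read/write envelopes as delimited peak lists
#'
#' Envelope files are TSV (or CSV, by file extension) with columns
#' `envelope_id`, `neutral_mass`, `intensity`. Peaks of each envelope are
#' sorted by mass on reading (with a warning if the file was unsorted);
#' malformed rows raise an error naming the offending line numbers.
#'
#' @param path File path (`.csv` is comma-separated, anything else
#'   tab-separated).
#' @return `readEnvelopes`: named list of [Envelope-class] objects.
#' @export
readEnvelopes <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("envelope_id", "neutral_mass", "intensity")
  if (!all(need %in% names(tab)))
    stop("envelope file must have columns ", paste(need, collapse = ", "))
  if (!nrow(tab)) return(setNames(list(), character()))
  num <- suppressWarnings(list(m = as.numeric(tab$neutral_mass),
                               i = as.numeric(tab$intensity)))
  bad <- which(!is.finite(num$m) | !is.finite(num$i) | num$i < 0)
  if (length(bad))
    stop("malformed envelope row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  ids <- as.character(tab$envelope_id)
  out <- lapply(split(seq_len(nrow(tab)), factor(ids, levels = unique(ids))),
                function(ix) envelope(num$m[ix], num$i[ix],
                                      metadata = list(id = ids[ix[1]])))
  out
}

#' @rdname readEnvelopes
#' @param envelopes Named list of [Envelope-class] objects.
#' @return `writeEnvelopes`: `path`, invisibly.
#' @export
writeEnvelopes <- function(path, envelopes) {
  if (is(envelopes, "Envelope")) envelopes <- list(envelopes)
  ids <- names(envelopes)
  if (is.null(ids)) ids <- paste0("env", seq_along(envelopes))
  rows <- lapply(seq_along(envelopes), function(i) {
    e <- envelopes[[i]]
    data.frame(envelope_id = ids[i], neutral_mass = e@mass,
               intensity = e@intensity)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(envelope_id = character(), neutral_mass = numeric(),
                      intensity = numeric())
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # full double precision so the round trip is lossless
  tab$neutral_mass <- sprintf("%.17g", tab$neutral_mass)
  tab$intensity <- sprintf("%.17g", tab$intensity)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annotate a batch of envelopes with monoisotopic-mass predictions
#'
#' For each envelope: computes the experimental average mass, selects the
#' most-abundant peak with the AM-MA correction, and predicts the
#' monoisotopic mass with the fitted model. Uncorrectable envelopes are
#' flagged and carry NA predictions.
#'
#' @param model A [MindModel-class].
#' @param envelopes Named list of [Envelope-class] objects (as returned by
#'   [readEnvelopes()]).
#' @param correction Apply the peak-selection correction (default TRUE);
#'   otherwise the raw most intense peak is used.
#' @return data.frame with one row per envelope: `envelope_id`,
#'   `averageMass`, `mostAbundantMass`, `correctionSteps`, `mono`,
#'   `branch`, `pError`, `inDomain`, `flag` ("" or "uncorrectable").
#' @export
annotateEnvelopes <- function(model, envelopes, correction = TRUE) {
  if (is(envelopes, "Envelope")) envelopes <- list(envelopes)
  ids <- names(envelopes) %||% paste0("env", seq_along(envelopes))
  rows <- lapply(seq_along(envelopes), function(i) {
    e <- envelopes[[i]]
    am <- averageMass(e)
    if (correction) {
      sel <- withCallingHandlers(
        selectMostAbundant(e, amMaInterval(model)),
        warning = function(w) invokeRestart("muffleWarning"))
    } else {
      j <- which.max(e@intensity)
      sel <- list(index = j, mass = e@mass[j], steps = 0L, ok = TRUE)
    }
    if (!sel$ok)
      return(data.frame(envelope_id = ids[i], averageMass = am,
                        mostAbundantMass = NA_real_, correctionSteps = sel$steps,
                        mono = NA_real_, branch = NA_integer_,
                        pError = NA_real_, inDomain = NA,
                        flag = "uncorrectable"))
    p <- predictMono(model, sel$mass, warn = FALSE)
    data.frame(envelope_id = ids[i], averageMass = am,
               mostAbundantMass = sel$mass, correctionSteps = sel$steps,
               mono = p$mono, branch = p$branch, pError = p$pError,
               inDomain = p$inDomain, flag = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
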