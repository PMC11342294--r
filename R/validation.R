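#' Relative mass error in parts per million
#' @param observed,expected Masses in Da (`expected` nonzero).
#' @return `(observed - expected) / expected * 1e6`.
#' @export
ppmError <- function(observed, expected) {
  if (any(expected == 0)) stop("expected mass must be nonzero")
  (observed - expected) / expected * 1e6
}

#' Central tendency and dispersion of an error sample
#'
#' The five summary statistics used for mass-error reporting: mean,
#' median, interquartile range, standard deviation and the median
#' absolute deviation about the median. The MAD is reported raw, without
#' the 1.4826 normal-consistency factor.
#'
#' @param errors Nonempty numeric vector (typically ppm errors).
#' @return Named numeric: `mean`, `median`, `IQR`, `SD`, `MAD`.
#' @export
errorSummary <- function(errors) {
  if (!length(errors)) stop("empty error vector")
  c(mean = mean(errors), median = median(errors),
    IQR = unname(diff(quantile(errors, c(0.25, 0.75)))),
    SD = if (length(errors) > 1L) sd(errors) else 0,
    MAD = median(abs(errors - median(errors))))
}

# off-by-one bin label of prediction errors in Da: 0 if |err| < 0.5,
# else the signed integer label (errors cluster at about +/- 1 Da)
.errorBin <- function(err) {
  bin <- integer(length(err))
  off <- abs(err) >= 0.5
  bin[off] <- as.integer(sign(err[off])) * pmax(1L, round(abs(err[off])))
  bin
}

# recompute full K-peak distributions for the rows of a mass table
.tableDistributions <- function(table, K = NULL) {
  chemistry <- attr(table, "chemistry"); if (is.null(chemistry)) chemistry <- "DNA"
  terminal <- attr(table, "terminal"); if (is.null(terminal)) terminal <- "phosphate"
  if (is.null(K)) { K <- attr(table, "k"); if (is.null(K)) K <- 30L }
  bases <- as.matrix(table[, .baseLetters(chemistry), drop = FALSE])
  ec <- .elementCountsFromBases(bases, chemistry, terminal)
  .brainFull(ec, K)
}

#' In-silico validation of a fitted predictor
#'
#' Runs the held-out validation study: the theoretical K-peak envelope of
#' each validation molecule is perturbed with zero-centered uniform
#' intensity noise, the most-abundant peak is selected (with the AM-MA
#' correction by default), the monoisotopic mass is predicted, and the
#' prediction error is binned into off-by-one labels (0 when
#' |error| < 0.5 Da, otherwise the signed Da label).
#'
#' @param model A [MindModel-class].
#' @param validation Validation mass table (held out from training).
#' @param width Uniform noise support width as a fraction of peak height
#'   (default 0.10).
#' @param seed Optional integer seed for the noise.
#' @param correction Apply the AM-MA peak-selection correction (default
#'   TRUE).
#' @return Object of class `mindValidation`: a list with `perMolecule`
#'   (data.frame: trueMono, trueMode, selectedMass, predicted, error,
#'   bin), `accuracy`, `rateMinus1`, `ratePlus1` (percentages over all
#'   validation molecules), `nUncorrectable`, and `binPpm` (per-bin ppm
#'   error summaries).
#' @export
insilicoValidation <- function(model, validation, width = 0.10,
                               seed = NULL, correction = TRUE) {
  stopifnot(is(model, "MindModel"))
  dist <- .tableDistributions(validation, K = model@k)
  intens <- .withSeed(seed, .noisyIntensities(dist$q, width))
  if (correction) {
    sel <- .selectMostAbundantBatch(intens, dist$mu, amMaInterval(model))
    idx <- sel$index
  } else {
    idx <- max.col(intens, ties.method = "first")
  }
  n <- nrow(validation)
  ok <- !is.na(idx)
  selMass <- rep(NA_real_, n)
  selMass[ok] <- dist$mu[cbind(which(ok), idx[ok])]
  pred <- rep(NA_real_, n)
  pErr <- rep(NA_real_, n)
  if (any(ok)) {
    p <- predictMono(model, selMass[ok], warn = FALSE)
    pred[ok] <- p$mono
    pErr[ok] <- p$pError
  }
  err <- pred - validation$mono
  bin <- rep(NA_integer_, n)
  bin[ok] <- .errorBin(err[ok])
  per <- data.frame(trueMono = validation$mono,
                    trueMode = validation$modeMass,
                    selectedMass = selMass, predicted = pred,
                    error = err, pError = pErr, bin = bin)
  binPpm <- lapply(split(ppmError(pred[ok], validation$mono[ok]), bin[ok]),
                   errorSummary)
  out <- list(perMolecule = per,
              accuracy = 100 * sum(bin == 0L, na.rm = TRUE) / n,
              rateMinus1 = 100 * sum(bin == -1L, na.rm = TRUE) / n,
              ratePlus1 = 100 * sum(bin == 1L, na.rm = TRUE) / n,
              nUncorrectable = sum(!ok),
              binPpm = binPpm,
              width = width, correction = correction)
  class(out) <- "mindValidation"
  out
}

#' @export
print.mindValidation <- function(x, ...) {
  cat("In-silico validation of", nrow(x$perMolecule), "molecules",
      sprintf("(noise width %.0f%%, correction %s)\n",
              100 * x$width, if (x$correction) "on" else "off"))
  cat(sprintf("  accuracy: %.2f%%  (-1 Da: %.2f%%, +1 Da: %.2f%%)\n",
              x$accuracy, x$rateMinus1, x$ratePlus1))
  if (x$nUncorrectable)
    cat("  uncorrectable envelopes:", x$nUncorrectable, "\n")
  invisible(x)
}

#' Robustness of the predictor to a chemical modification
#'
#' Applies a modification from the registry `times` times to every
#' molecule of a validation table, recomputes the aggregated isotope
#' distribution of the modified formulas, predicts the monoisotopic mass
#' from the theoretical most-abundant mass (no noise, no peak-selection
#' correction), and summarizes the fraction of predictions in the
#' "0 ppm" bin (|error| < 0.5 Da), the median ppm error within the bin
#' and the ppm interval width containing 95% of the bin members.
#' Molecules on which the modification is inapplicable (the formula
#' delta would drive an element count negative, as happens for repeated
#' depurination of short sequences) or whose modified most-abundant
#' mass leaves the trained model domain are counted as missing and
#' excluded from the percentages. Applicability is checked at the
#' formula level - the study treats modifications as elemental deltas,
#' not sequence edits.
#'
#' @param model A [MindModel-class].
#' @param validation Validation mass table.
#' @param modification Registry name or one-row registry data.frame.
#' @param times Number of applications (default 1).
#' @return One-row data.frame: `modification`, `times`, `pct0ppm`,
#'   `medianPpm`, `width95`, `missing`.
#' @export
modificationRobustness <- function(model, validation, modification,
                                   times = 1L) {
  stopifnot(is(model, "MindModel"))
  times <- as.integer(times)
  if (times < 1L) stop("times must be at least 1")
  mod <- .getModification(modification)
  chemistry <- attr(validation, "chemistry"); if (is.null(chemistry)) chemistry <- "DNA"
  terminal <- attr(validation, "terminal"); if (is.null(terminal)) terminal <- "phosphate"
  letters <- .baseLetters(chemistry)
  bases <- as.matrix(validation[, letters, drop = FALSE])
  ec <- .elementCountsFromBases(bases, chemistry, terminal)
  d <- .modificationDelta(mod) * times
  ec2 <- matrix(0L, nrow(ec), length(union(colnames(ec), names(d))),
                dimnames = list(NULL, union(colnames(ec), names(d))))
  ec2[, colnames(ec)] <- ec
  for (el in names(d)) ec2[, el] <- ec2[, el] + as.integer(d[[el]])
  applicable <- rowSums(ec2 < 0L) == 0L
  ec2[!applicable, ] <- 1L      # placeholder rows, discarded below
  sm <- .brainBatch(ec2, attr(validation, "k") %||% model@k)
  inDomain <- sm$modeMass >= modelDomain(model)[1] &
    sm$modeMass <= modelDomain(model)[2]
  use <- applicable & inDomain
  missing <- sum(!use)
  pred <- predictMono(model, sm$modeMass[use], warn = FALSE)
  err <- pred$mono - sm$mono[use]
  bin0 <- abs(err) < 0.5
  ppm <- ppmError(pred$mono[bin0], sm$mono[use][bin0])
  data.frame(modification = mod$name, times = times,
             pct0ppm = 100 * mean(bin0),
             medianPpm = median(ppm),
             width95 = unname(diff(quantile(ppm, c(0.025, 0.975)))),
             missing = missing)
}
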