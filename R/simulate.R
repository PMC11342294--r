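#' Noisy theoretical envelope
#'
#' Adds zero-centered uniform intensity noise to a theoretical aggregated
#' distribution: peak j gets `q_j + U(-w*q_j/2, +w*q_j/2)` with `w` the
#' support width expressed as a fraction of the peak's own height
#' (default 0.10), clipped at zero. Masses are left untouched - mass
#' noise would propagate one-to-one into the prediction without telling
#' anything about the model.
#'
#' @param d An [IsotopeDistribution-class].
#' @param width Noise support width as a fraction of peak height, in
#'   `[0, 1)` (default 0.10). `0` returns the exact theoretical envelope.
#' @param seed Optional integer seed (global RNG state restored on exit).
#' @return An [Envelope-class].
#' @export
noisyEnvelope <- function(d, width = 0.10, seed = NULL) {
  stopifnot(is(d, "IsotopeDistribution"), width >= 0, width < 1)
  q <- probs(d)
  intens <- .withSeed(seed,
    pmax(0, q + runif(length(q), -width * q / 2, width * q / 2)))
  envelope(centerMasses(d), intens)
}

#' Finite-ion-count envelope
#'
#' Simulates poor ion statistics: intensities are a multinomial draw of
#' `nIons` ions over the normalized peak probabilities; masses are
#' unchanged.
#'
#' @param d An [IsotopeDistribution-class].
#' @param nIons Total number of ions (>= 1).
#' @param seed Optional integer seed.
#' @return An [Envelope-class] with integer ion counts as intensities.
#' @export
sampledEnvelope <- function(d, nIons, seed = NULL) {
  stopifnot(is(d, "IsotopeDistribution"))
  nIons <- as.integer(nIons)
  if (nIons < 1L) stop("nIons must be at least 1")
  q <- probs(d)
  if (sum(q) <= 0) stop("all peak probabilities are zero")
  cnt <- .withSeed(seed, as.vector(rmultinom(1L, nIons, q / sum(q))))
  envelope(centerMasses(d), cnt)
}

# vectorized noise for an n x K intensity matrix (used by the in-silico
# validation study); caller owns the RNG state
.noisyIntensities <- function(q, width) {
  if (width == 0) return(q)
  pmax(q + matrix(runif(length(q), -width / 2, width / 2),
                  nrow(q), ncol(q)) * q, 0)
}

# vectorized AM-MA correction walk over rows of intensity/mass matrices;
# returns list(index [NA when uncorrectable], steps)
.selectMostAbundantBatch <- function(intens, mu, interval) {
  n <- nrow(intens); K <- ncol(intens)
  idx <- max.col(intens, ties.method = "first")
  am <- rowSums(intens * mu) / rowSums(intens)
  steps <- integer(n)
  failed <- rep(FALSE, n)
  for (it in seq_len(2L * K)) {
    d <- am - mu[cbind(seq_len(n), ifelse(failed, 1L, idx))]
    up <- !failed & d > interval[2]   # candidate too light: step heavier
    dn <- !failed & d < interval[1]   # candidate too heavy: step lighter
    if (!any(up | dn)) break
    idx[up] <- idx[up] + 1L
    idx[dn] <- idx[dn] - 1L
    steps[up | dn] <- steps[up | dn] + 1L
    failed <- failed | idx < 1L | idx > K
    idx[failed] <- pmin(pmax(idx[failed], 1L), K)  # keep indices in range
  }
  d <- am - mu[cbind(seq_len(n), idx)]
  failed <- failed | d < interval[1] | d > interval[2]
  idx[failed] <- NA_integer_
  list(index = idx, steps = steps, am = am)
}
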