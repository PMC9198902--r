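#' Standard SSVEP preprocessing
#'
#' Downsamples to \code{targetFs} (250 Hz by default, integer decimation
#' with an anti-alias low-pass), band-passes to 6--90 Hz with a zero-phase
#' 4th-order Butterworth filter, and suppresses mains interference with a
#' zero-phase constant-Q notch.
#'
#' @param raw an [EpochSet-class]; its sampling rate must be >=
#'   \code{targetFs}.
#' @param low,high band-pass edges (Hz).
#' @param notch mains frequency to suppress (Hz); \code{NA} disables the
#'   notch.
#' @param notchQ quality factor of the notch biquad.
#' @param targetFs output sampling rate (Hz).
#' @return the preprocessed [EpochSet-class] at \code{targetFs}.
#' @export
preprocess <- function(raw, low = 6, high = 90, notch = 50, notchQ = 35,
                       targetFs = 250) {
  if (raw@fs < targetFs)
    stop("input sampling rate must be >= the target rate")
  data <- raw@data
  fs <- raw@fs
  onset <- raw@onsetIndex
  if (fs > targetFs) {
    fac <- fs / targetFs
    if (abs(fac - round(fac)) > 1e-9)
      stop("sampling rate must be an integer multiple of targetFs")
    fac <- as.integer(round(fac))
    aa <- butterBandpass(0.5, 0.45 * targetFs, fs, order = 4L)
    data <- filterEpochArray(data, aa)
    keep <- seq(1L, dim(data)[3], by = fac)
    data <- data[, , keep, drop = FALSE]
    onset <- as.integer(floor((onset - 1L) / fac) + 1L)
    fs <- targetFs
  }
  data <- filterEpochArray(data, butterBandpass(low, high, fs))
  if (!is.na(notch))
    data <- filterEpochArray(data, notchBiquad(notch, fs, notchQ))
  new("EpochSet", data = data, fs = fs, labels = raw@labels,
      block = raw@block, day = raw@day, electrode = raw@electrode,
      onsetIndex = onset)
}

#' Extract the decoding window from each trial
#'
#' Crops every trial to \code{[onset + latency, onset + latency + length)},
#' discarding the visual-latency delay before the SSVEP emerges.
#'
#' @param epochs an [EpochSet-class].
#' @param latency visual latency to skip (s).
#' @param length window length (s, > 0).
#' @return the cropped [EpochSet-class] (onset index 1).
#' @export
extractWindow <- function(epochs, latency = 0.14, length = 1) {
  fs <- epochs@fs
  nWin <- round(length * fs)
  if (nWin < 1) stop("bounds error: window must contain at least 1 sample")
  from <- epochs@onsetIndex + round(latency * fs)
  to <- from + nWin - 1L
  if (from < 1L || to > nSamples(epochs))
    stop("bounds error: window exceeds the trial")
  new("EpochSet", data = epochs@data[, , from:to, drop = FALSE], fs = fs,
      labels = epochs@labels, block = epochs@block, day = epochs@day,
      electrode = epochs@electrode, onsetIndex = 1L)
}

#' Sine-cosine reference matrix for one stimulus frequency
#'
#' Rows are ordered sin(2 pi f t), cos(2 pi f t), ..., sin(2 pi H f t),
#' cos(2 pi H f t) on the time grid t = 1/fs, ..., n/fs.
#'
#' @param f stimulus frequency (Hz).
#' @param nHarmonics number of harmonics H.
#' @param fs sampling rate (Hz).
#' @param nSamples number of time points (>= 2).
#' @return a (2 * nHarmonics) x nSamples matrix.
#' @export
makeReference <- function(f, nHarmonics, fs, nSamples) {
  if (nSamples < 2) stop("nSamples must be >= 2")
  if (nHarmonics * f >= fs / 2)
    stop("aliasing error: harmonic at or above Nyquist")
  t <- seq_len(nSamples) / fs
  Y <- matrix(0, 2L * nHarmonics, nSamples)
  for (h in seq_len(nHarmonics)) {
    Y[2L * h - 1L, ] <- sin(2 * pi * h * f * t)
    Y[2L * h, ]      <- cos(2 * pi * h * f * t)
  }
  Y
}

# references for every class of a design at a given window length
referenceSet <- function(design, fs, nSamples,
                         nHarmonics = NULL) {
  if (is.null(nHarmonics)) nHarmonics <- design@nHarmonics
  lapply(stimulusFrequencies(design), makeReference,
         nHarmonics = nHarmonics, fs = fs, nSamples = nSamples)
}

#' Construct a filter-bank specification
#'
#' Sub-band \eqn{n} spans \eqn{[(n \times 8) - 2, 90]} Hz; fusion weights
#' are \eqn{v(n) = n^{-a} + b}.
#'
#' @param nSubbands number of sub-bands (1..5).
#' @param weightA weight exponent a.
#' @param weightB weight offset b.
#' @param highEdge common upper cut-off (Hz).
#' @return a [FilterBankSpec-class].
#' @export
makeFilterBankSpec <- function(nSubbands = 5L, weightA = 1.25,
                               weightB = 0.25, highEdge = 90) {
  n <- as.integer(nSubbands)
  edges <- cbind((seq_len(n) * 8) - 2, rep(highEdge, n))
  new("FilterBankSpec", nSubbands = n, bandEdges = edges,
      weightA = weightA, weightB = weightB)
}

#' Sub-band fusion weights v(n)
#'
#' @param spec a [FilterBankSpec-class].
#' @return numeric vector \code{v(n) = n^-a + b} for n = 1..nSubbands.
#' @export
subbandWeights <- function(spec) {
  n <- seq_len(spec@nSubbands)
  n^(-spec@weightA) + spec@weightB
}

#' Decompose epochs into filter-bank sub-bands
#'
#' @param epochs an [EpochSet-class].
#' @param spec a [FilterBankSpec-class].
#' @return a list of [EpochSet-class] objects, one per sub-band.
#' @export
filterbankDecompose <- function(epochs, spec) {
  lapply(seq_len(spec@nSubbands), function(n) {
    coef <- butterBandpass(spec@bandEdges[n, 1], spec@bandEdges[n, 2],
                           epochs@fs)
    new("EpochSet", data = filterEpochArray(epochs@data, coef),
        fs = epochs@fs, labels = epochs@labels, block = epochs@block,
        day = epochs@day, electrode = epochs@electrode,
        onsetIndex = epochs@onsetIndex)
  })
}

#' Subset every band of a pre-decomposed sub-band list by trial index
#'
#' @param bands list of [EpochSet-class] sub-bands from
#'   [filterbankDecompose()], or \code{NULL}.
#' @param idx logical or integer trial selector.
#' @return the subset band list (or \code{NULL}).
#' @export
subsetBands <- function(bands, idx) {
  if (is.null(bands)) return(NULL)
  lapply(bands, function(b) b[idx])
}

#' Fuse per-sub-band class scores
#'
#' Computes \eqn{\tilde\rho_k = \sum_n v(n) \rho_{k,n}^2}.  When
#' \code{signed} is \code{TRUE} (default) the square preserves the sign of
#' each sub-band score so that negative template correlations keep their
#' discriminative information.
#'
#' @param scores a list of per-sub-band numeric score vectors (equal
#'   lengths), or a matrix with one column per sub-band.
#' @param spec a [FilterBankSpec-class].
#' @param signed preserve score signs through the squaring.
#' @return fused class-score vector.
#' @export
combineSubbands <- function(scores, spec, signed = TRUE) {
  if (is.list(scores)) {
    if (!length(scores)) stop("empty score sequence")
    len <- unique(vapply(scores, length, 1L))
    if (length(len) != 1L) stop("sub-band score vectors differ in length")
    scores <- do.call(cbind, scores)
  }
  if (!length(scores)) stop("empty score sequence")
  v <- subbandWeights(spec)[seq_len(ncol(scores))]
  sq <- if (signed) sign(scores) * scores^2 else scores^2
  as.numeric(sq %*% v)
}
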