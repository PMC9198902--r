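# Synthetic SSVEP generator with planted within-subject domain shifts.
#
# Signal model per trial of class k (time t from stimulus onset, s):
#   s(t) = signalAmp * sum_h harmonicAmps[h] *
#            sin(2*pi*h*f_k*(t - latency) + h*phi_k),  for t >= latency
# mixed through the unit-norm spatialPattern, plus background noise that is
# AR(1) in time (coefficient rho) and spatially coloured by the Cholesky
# factor of noiseCov.

# run expr with a private, restored RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed))
    stop("a seed is required: simulation must be reproducible")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# default spatial noise covariance: unit variance per channel with
# exponentially decaying inter-channel correlation
defaultNoiseCov <- function(nChannels, correlation = 0.3, variance = 1) {
  variance * correlation^abs(outer(seq_len(nChannels), seq_len(nChannels),
                                   "-"))
}

#' Construct a simulated subject's generative profile
#'
#' @param nChannels number of EEG channels.
#' @param latency visual latency (s); the population value 0.14 s by
#'   default.
#' @param harmonicAmps relative harmonic amplitudes (non-increasing);
#'   defaults to \code{h^-1.25} for h = 1..5.
#' @param spatialPattern unit-norm channel mixing vector; a fixed
#'   occipital-dominant profile by default, or random when \code{seed}
#'   is given and \code{spatialPattern} is \code{NULL} with
#'   \code{randomPattern = TRUE}.
#' @param noiseCov channels x channels SPD noise covariance (uV^2);
#'   defaults to unit-variance channels with 0.3 inter-channel correlation
#'   decay.
#' @param signalAmp SSVEP amplitude scale (uV).
#' @param randomPattern draw a random unit-norm pattern instead of the
#'   fixed default (requires \code{seed}).
#' @param seed RNG seed for the random pattern.
#' @return a [SubjectProfile-class].
#' @export
makeSubjectProfile <- function(nChannels = 8L, latency = 0.14,
                               harmonicAmps = (1:5)^-1.25,
                               spatialPattern = NULL, noiseCov = NULL,
                               signalAmp = 1, randomPattern = FALSE,
                               seed = NULL) {
  if (is.null(spatialPattern)) {
    if (randomPattern) {
      spatialPattern <- withSeed(seed, rnorm(nChannels))
    } else {
      # occipito-parietal gradient: posterior channels dominate
      spatialPattern <- seq(0.5, 1.5, length.out = nChannels)
    }
  }
  spatialPattern <- spatialPattern / sqrt(sum(spatialPattern^2))
  if (is.null(noiseCov)) noiseCov <- defaultNoiseCov(length(spatialPattern))
  new("SubjectProfile", latency = latency, harmonicAmps = harmonicAmps,
      spatialPattern = spatialPattern, noiseCov = noiseCov,
      signalAmp = signalAmp)
}

#' Construct a random orthogonal rotation for a domain shift
#'
#' Orthogonalises \code{I + theta * A} (A random antisymmetric) by QR,
#' giving a rotation whose distance from the identity grows with
#' \code{theta}.
#'
#' @param nChannels matrix dimension.
#' @param theta shift magnitude (0 = identity).
#' @param seed RNG seed (required when theta > 0).
#' @return an orthogonal nChannels x nChannels matrix.
#' @export
makeRotation <- function(nChannels, theta = 0, seed = NULL) {
  if (theta == 0) return(diag(nChannels))
  withSeed(seed, {
    A <- matrix(rnorm(nChannels^2), nChannels)
    A <- (A - t(A)) / 2
    qd <- qr(diag(nChannels) + theta * A)
    Q <- qr.Q(qd)
    # fix column signs so Q is close to the identity for small theta
    Q %*% diag(sign(diag(qr.R(qd))))
  })
}

#' Construct a recording-domain specification
#'
#' @param day session day index.
#' @param electrodeType \code{"wet"} or \code{"dry"}.
#' @param rotation orthogonal channel rotation (identity by default).
#' @param noiseGain noise covariance multiplier.
#' @param ampGain signal amplitude multiplier.
#' @param nChannels used to build the default identity rotation.
#' @return a [DomainSpec-class].
#' @export
makeDomainSpec <- function(day = 1L, electrodeType = "wet",
                           rotation = NULL, noiseGain = 1, ampGain = 1,
                           nChannels = 8L) {
  if (is.null(rotation)) rotation <- diag(nChannels)
  new("DomainSpec", day = as.integer(day), electrodeType = electrodeType,
      rotation = rotation, noiseGain = noiseGain, ampGain = ampGain)
}

#' Apply a domain shift to a subject profile
#'
#' Rotates the spatial pattern, scales the noise covariance by
#' \code{noiseGain} and the signal amplitude by \code{ampGain}.
#'
#' @param profile a [SubjectProfile-class].
#' @param spec a [DomainSpec-class].
#' @return the shifted [SubjectProfile-class].
#' @export
applyDomainShift <- function(profile, spec) {
  C <- length(profile@spatialPattern)
  if (!all(dim(spec@rotation) == c(C, C)))
    stop("shape error: rotation dimension does not match channel count")
  new("SubjectProfile",
      latency        = profile@latency,
      harmonicAmps   = profile@harmonicAmps,
      spatialPattern = as.numeric(spec@rotation %*% profile@spatialPattern),
      noiseCov       = spec@noiseGain * profile@noiseCov,
      signalAmp      = spec@ampGain * profile@signalAmp)
}

# SSVEP waveform of class k on time grid t (s, from onset); zero before
# the visual latency
ssvepWaveform <- function(profile, freq, phase, t) {
  s <- numeric(length(t))
  on <- t >= profile@latency
  td <- t[on] - profile@latency
  for (h in seq_along(profile@harmonicAmps))
    s[on] <- s[on] + profile@harmonicAmps[h] *
      sin(2 * pi * h * freq * td + h * phase)
  profile@signalAmp * s
}

#' Simulate labelled SSVEP epochs
#'
#' Generates \code{nBlocks * nTargets} trials (block-major order, one trial
#' per target per block).  Identical inputs (including the seed) give
#' bit-identical output.
#'
#' @param profile a [SubjectProfile-class].
#' @param design a [StimulusDesign-class].
#' @param nBlocks number of blocks.
#' @param epochLen epoch length (s).
#' @param fs sampling rate (Hz).
#' @param seed RNG seed (mandatory).
#' @param arCoef AR(1) coefficient of the temporal noise colouring.
#' @param day,electrodeType metadata stamped on every trial.
#' @return an [EpochSet-class]; stimulus onset is the first sample.
#' @export
simulateEpochs <- function(profile, design, nBlocks, epochLen, fs, seed,
                           arCoef = 0.9, day = 1L, electrodeType = "wet") {
  if (missing(seed)) stop("a seed is required: simulation must be reproducible")
  N <- round(epochLen * fs)
  if (N < 2) stop("epochLen * fs must be at least 2 samples")
  if (nBlocks < 1) stop("nBlocks must be >= 1")
  C <- length(profile@spatialPattern)
  K <- nTargets(design)
  nTrial <- nBlocks * K
  t <- (seq_len(N) - 1) / fs
  freqs <- stimulusFrequencies(design)
  phases <- stimulusPhases(design)

  # class waveforms (K x N), common to all blocks
  S <- vapply(seq_len(K),
              function(k) ssvepWaveform(profile, freqs[k], phases[k], t),
              numeric(N))

  Rchol <- chol(profile@noiseCov)  # noiseCov = t(Rchol) %*% Rchol
  withSeed(seed, {
    # innovations for all trials at once: N x (C * nTrial)
    W <- matrix(rnorm(N * C * nTrial), nrow = N)
    # exact stationary AR(1): scale innovations by sqrt(1-rho^2), except the
    # first sample which keeps full variance
    innovSd <- sqrt(1 - arCoef^2)
    W[1, ] <- W[1, ] / innovSd
    E <- iir_filter_mat(innovSd, c(1, -arCoef), W)

    data <- array(0, dim = c(nTrial, C, N))
    labels <- integer(nTrial)
    block <- integer(nTrial)
    i <- 0L
    for (b in seq_len(nBlocks)) {
      for (k in seq_len(K)) {
        i <- i + 1L
        noise <- t(Rchol) %*% t(E[, (i - 1L) * C + seq_len(C), drop = FALSE])
        data[i, , ] <- outer(profile@spatialPattern, S[, k]) + noise
        labels[i] <- k
        block[i] <- b
      }
    }
    new("EpochSet", data = data, fs = fs, labels = labels, block = block,
        day = rep(as.integer(day), nTrial),
        electrode = rep(electrodeType, nTrial), onsetIndex = 1L)
  })
}

#' Simulate one recording session in a shifted domain
#'
#' Applies the domain shift to the profile, simulates epochs, and stamps
#' the domain metadata.
#'
#' @inheritParams simulateEpochs
#' @param domain a [DomainSpec-class].
#' @return an [EpochSet-class].
#' @export
simulateSession <- function(profile, design, domain, nBlocks, epochLen, fs,
                            seed, arCoef = 0.9) {
  shifted <- applyDomainShift(profile, domain)
  simulateEpochs(shifted, design, nBlocks, epochLen, fs, seed,
                 arCoef = arCoef, day = domain@day,
                 electrodeType = domain@electrodeType)
}
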