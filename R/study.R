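# Whole-study simulation: one subject recorded on several days with wet
# and dry electrode headsets, with planted cross-day (montage rotation)
# and cross-electrode (larger rotation, noisier, attenuated) domain shifts.

#' Default run configuration
#'
#' All defaults mirror the standard 40-target speller protocol: 250 Hz,
#' 8 occipito-parietal channels, 6 blocks per session, 3 days, wet and dry
#' headsets, 4 s stimulation, 0.14 s visual latency, 5 filter-bank
#' sub-bands with weights v(n) = n^-1.25 + 0.25, 1 s gaze shift.  Domain
#' shifts: day-to-day montage rotation theta 0.2, electrode-change rotation
#' theta 0.5, dry-electrode noise gain 3 and amplitude gain 0.8.
#'
#' @return named list of configuration values.
#' @export
defaultRunConfig <- function() {
  list(
    nTargets = 40L, baseFreq = 8, freqStep = 0.2,
    basePhase = 0, phaseStep = 0.5 * pi, nHarmonics = 5L,
    nChannels = 8L, fs = 250, nBlocks = 6L, epochLen = 4,
    days = 3L, electrodes = c("wet", "dry"),
    latency = 0.14, arCoef = 0.9, signalAmp = 0.9,
    thetaDay = 0.2, thetaElectrode = 0.5,
    noiseGainDry = 3, ampGainDry = 0.8,
    nSubbands = 5L, weightA = 1.25, weightB = 0.25,
    gazeShift = 1, lengths = seq(0.4, 4, by = 0.4),
    signedSubbands = TRUE, seed = 1L
  )
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to
#' [defaultRunConfig()].
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return merged configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  modifyList(cfg, user)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + index * 12347) %% 2147480017)
}

#' Build the stimulus design or filter bank described by a configuration
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @return `designFromConfig` a [StimulusDesign-class]; `fbFromConfig` a
#'   [FilterBankSpec-class].
#' @export
designFromConfig <- function(config) {
  makeStimulusDesign(config$nTargets, config$baseFreq, config$freqStep,
                     config$basePhase, config$phaseStep, config$nHarmonics)
}

#' @rdname designFromConfig
#' @export
fbFromConfig <- function(config) {
  makeFilterBankSpec(config$nSubbands, config$weightA, config$weightB)
}

#' Simulate a multi-day wet/dry recording study for one subject
#'
#' Day 1 wet is the reference domain (identity rotation).  Every later day
#' applies an independent montage rotation of magnitude \code{thetaDay};
#' every dry session additionally applies an independent electrode
#' rotation of magnitude \code{thetaElectrode}, a noise-covariance gain
#' \code{noiseGainDry} and an amplitude gain \code{ampGainDry}.  All
#' randomness derives from \code{seed}.
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @param seed master RNG seed (overrides \code{config$seed}).
#' @param sessions optional character vector of session names
#'   (\code{"day<d>_<electrode>"}) to simulate; others are skipped without
#'   disturbing the per-session seed derivation.
#' @return named list of [EpochSet-class] objects, one per session, named
#'   \code{day<d>_<electrode>}.
#' @export
simulateStudy <- function(config = defaultRunConfig(), seed = config$seed,
                          sessions = NULL) {
  design <- designFromConfig(config)
  profile <- makeSubjectProfile(
    nChannels = config$nChannels, latency = config$latency,
    harmonicAmps = (seq_len(config$nHarmonics))^-1.25,
    signalAmp = config$signalAmp)
  C <- config$nChannels
  out <- list()
  idx <- 0L
  for (d in seq_len(config$days)) {
    Rday <- if (d == 1L) diag(C)
            else makeRotation(C, config$thetaDay, subSeed(seed, 100L + d))
    for (el in config$electrodes) {
      idx <- idx + 1L
      name <- sprintf("day%d_%s", d, el)
      if (!is.null(sessions) && !name %in% sessions) next
      R <- Rday
      noiseGain <- 1; ampGain <- 1
      if (el == "dry") {
        R <- Rday %*% makeRotation(C, config$thetaElectrode,
                                   subSeed(seed, 200L + d))
        noiseGain <- config$noiseGainDry
        ampGain <- config$ampGainDry
      }
      dom <- makeDomainSpec(d, el, R, noiseGain, ampGain, C)
      out[[name]] <-
        simulateSession(profile, design, dom, config$nBlocks,
                        config$epochLen, config$fs,
                        seed = subSeed(seed, idx), arCoef = config$arCoef)
    }
  }
  out
}

#' Combine several epoch sets into one
#'
#' Concatenates trials; all inputs must share channel count, sample count
#' and sampling rate.
#'
#' @param sets list of [EpochSet-class] objects.
#' @return a single [EpochSet-class].
#' @export
combineEpochSets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  d1 <- dim(sets[[1]]@data)
  for (s in sets)
    if (!all(dim(s@data)[2:3] == d1[2:3]) || s@fs != sets[[1]]@fs)
      stop("epoch sets are not compatible")
  n <- sum(vapply(sets, nTrials, 1L))
  data <- array(0, dim = c(n, d1[2], d1[3]))
  i <- 0L
  for (s in sets) {
    data[i + seq_len(nTrials(s)), , ] <- s@data
    i <- i + nTrials(s)
  }
  new("EpochSet", data = data, fs = sets[[1]]@fs,
      labels = unlist(lapply(sets, epochLabels)),
      block = unlist(lapply(sets, epochBlocks)),
      day = unlist(lapply(sets, epochDays)),
      electrode = unlist(lapply(sets, epochElectrodes)),
      onsetIndex = sets[[1]]@onsetIndex)
}

#' Select the trials of one recording domain
#'
#' @param epochs an [EpochSet-class].
#' @param day session day.
#' @param electrode electrode type.
#' @return the subset [EpochSet-class].
#' @export
selectDomain <- function(epochs, day, electrode) {
  idx <- epochs@day == day & epochs@electrode == electrode
  if (!any(idx)) stop("no trials for day ", day, ", ", electrode)
  epochs[idx]
}
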