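#' Stimulus design for a joint frequency-phase modulated (JFPM) speller grid
#'
#' Describes a grid of flickering targets in which target \eqn{k}
#' (1-based) flashes at frequency \code{baseFreq + (k-1) * freqStep} Hz with
#' initial phase \code{(basePhase + (k-1) * phaseStep) mod 2pi} radians.
#' The canonical 40-target speller uses 8--15.8 Hz in 0.2 Hz steps and
#' phases cycling through 0, 0.5pi, pi, 1.5pi.
#'
#' @slot nTargets number of stimulus classes.
#' @slot baseFreq frequency of target 1 (Hz).
#' @slot freqStep frequency increment between consecutive targets (Hz).
#' @slot basePhase initial phase of target 1 (rad).
#' @slot phaseStep phase increment between consecutive targets (rad).
#' @slot nHarmonics number of harmonics modelled in the sine-cosine
#'   references.
#' @seealso [makeStimulusDesign()]
#' @export
setClass("StimulusDesign",
  representation(
    nTargets   = "integer",
    baseFreq   = "numeric",
    freqStep   = "numeric",
    basePhase  = "numeric",
    phaseStep  = "numeric",
    nHarmonics = "integer"
  )
)

setValidity("StimulusDesign", function(object) {
  msg <- character()
  if (object@nTargets < 1L) msg <- c(msg, "nTargets must be >= 1")
  if (object@nHarmonics < 1L) msg <- c(msg, "nHarmonics must be >= 1")
  if (object@baseFreq <= 0) msg <- c(msg, "baseFreq must be positive")
  if (object@freqStep < 0) msg <- c(msg, "freqStep must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Generative profile of one simulated subject
#'
#' Parameters of the forward model used by [simulateEpochs()]: the SSVEP of
#' class \eqn{k} is a harmonic series at the stimulus frequency, delayed by
#' the subject's visual latency, projected onto the scalp through a fixed
#' unit-norm spatial mixing pattern, and buried in spatially and temporally
#' coloured background noise.
#'
#' @slot latency visual response latency (s).
#' @slot harmonicAmps relative amplitudes of harmonics 1..H (non-increasing).
#' @slot spatialPattern unit-norm channel mixing vector.
#' @slot noiseCov channels x channels SPD noise covariance (uV^2).
#' @slot signalAmp SSVEP fundamental amplitude scale (uV).
#' @seealso [makeSubjectProfile()], [applyDomainShift()]
#' @export
setClass("SubjectProfile",
  representation(
    latency        = "numeric",
    harmonicAmps   = "numeric",
    spatialPattern = "numeric",
    noiseCov       = "matrix",
    signalAmp      = "numeric"
  )
)

setValidity("SubjectProfile", function(object) {
  msg <- character()
  if (object@latency < 0) msg <- c(msg, "latency must be >= 0")
  if (object@signalAmp < 0) msg <- c(msg, "signalAmp must be >= 0")
  if (any(diff(object@harmonicAmps) > 1e-12))
    msg <- c(msg, "harmonicAmps must be non-increasing")
  if (abs(sqrt(sum(object@spatialPattern^2)) - 1) > 1e-6)
    msg <- c(msg, "spatialPattern must have unit norm")
  C <- length(object@spatialPattern)
  if (!all(dim(object@noiseCov) == c(C, C)))
    msg <- c(msg, "noiseCov dimension must match spatialPattern length")
  if (max(abs(object@noiseCov - t(object@noiseCov))) > 1e-8)
    msg <- c(msg, "noiseCov must be symmetric")
  ev <- tryCatch(min(eigen(object@noiseCov, symmetric = TRUE,
                           only.values = TRUE)$values),
                 error = function(e) -Inf)
  if (ev <= 0) msg <- c(msg, "noiseCov must be positive definite")
  if (length(msg)) msg else TRUE
})

#' Recording-domain specification
#'
#' One recording domain is a (day, electrode type) pair.  Relative to the
#' subject's reference profile it rotates the spatial mixing pattern by an
#' orthogonal matrix (electrode repositioning / montage drift), scales the
#' noise covariance (e.g. high-impedance dry electrodes) and attenuates the
#' signal amplitude.
#'
#' @slot day session day index.
#' @slot electrodeType \code{"wet"} or \code{"dry"}.
#' @slot rotation channels x channels orthogonal matrix.
#' @slot noiseGain noise covariance multiplier (>= 0).
#' @slot ampGain signal amplitude multiplier (>= 0).
#' @seealso [makeDomainSpec()], [applyDomainShift()]
#' @export
setClass("DomainSpec",
  representation(
    day           = "integer",
    electrodeType = "character",
    rotation      = "matrix",
    noiseGain     = "numeric",
    ampGain       = "numeric"
  )
)

setValidity("DomainSpec", function(object) {
  msg <- character()
  if (!object@electrodeType %in% c("wet", "dry"))
    msg <- c(msg, "electrodeType must be 'wet' or 'dry'")
  if (object@noiseGain < 0) msg <- c(msg, "noiseGain must be >= 0")
  if (object@ampGain < 0) msg <- c(msg, "ampGain must be >= 0")
  R <- object@rotation
  if (nrow(R) != ncol(R)) msg <- c(msg, "rotation must be square")
  else if (max(abs(crossprod(R) - diag(nrow(R)))) > 1e-10)
    msg <- c(msg, "rotation must be orthogonal (R'R = I within 1e-10)")
  if (length(msg)) msg else TRUE
})

#' Labelled multichannel EEG epochs
#'
#' The universal signal container: a trials x channels x samples array plus
#' per-trial metadata (target label, block, day, electrode type) and the
#' sample index of stimulus onset.
#'
#' @slot data trials x channels x samples array (uV).
#' @slot fs sampling rate (Hz).
#' @slot labels 1-based target class per trial.
#' @slot block block index per trial.
#' @slot day session day per trial.
#' @slot electrode electrode type per trial ("wet"/"dry").
#' @slot onsetIndex sample index of stimulus onset (1-based).
#' @seealso [simulateEpochs()], [extractWindow()], [writeEpochs()]
#' @export
setClass("EpochSet",
  representation(
    data       = "array",
    fs         = "numeric",
    labels     = "integer",
    block      = "integer",
    day        = "integer",
    electrode  = "character",
    onsetIndex = "integer"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-D array")
  else {
    n <- d[1]
    for (f in c("labels", "block", "day", "electrode"))
      if (length(slot(object, f)) != n)
        msg <- c(msg, sprintf("length of '%s' must equal the trial count", f))
    if (object@onsetIndex < 1L || object@onsetIndex > d[3])
      msg <- c(msg, "onsetIndex must lie inside the epoch")
  }
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(object@labels) && min(object@labels) < 1L)
    msg <- c(msg, "labels must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Filter-bank specification
#'
#' Harmonic sub-band decomposition: sub-band \eqn{n} is band-passed to
#' \eqn{[(n \times 8) - 2, 90]} Hz, and per-sub-band scores are fused with
#' weights \eqn{v(n) = n^{-a} + b} (defaults a = 1.25, b = 0.25).
#'
#' @slot nSubbands number of sub-bands (1..5).
#' @slot bandEdges nSubbands x 2 matrix of (low, high) cut-offs (Hz).
#' @slot weightA weight exponent a.
#' @slot weightB weight offset b.
#' @seealso [makeFilterBankSpec()], [combineSubbands()]
#' @export
setClass("FilterBankSpec",
  representation(
    nSubbands = "integer",
    bandEdges = "matrix",
    weightA   = "numeric",
    weightB   = "numeric"
  )
)

setValidity("FilterBankSpec", function(object) {
  msg <- character()
  n <- object@nSubbands
  if (n < 1L || n > 5L) msg <- c(msg, "nSubbands must lie in 1..5")
  if (!all(dim(object@bandEdges) == c(n, 2L)))
    msg <- c(msg, "bandEdges must be nSubbands x 2")
  else {
    lows <- (seq_len(n) * 8) - 2
    if (max(abs(object@bandEdges[, 1] - lows)) > 1e-9)
      msg <- c(msg, "low edge of sub-band n must be (n*8)-2 Hz")
    if (any(object@bandEdges[, 2] <= object@bandEdges[, 1]))
      msg <- c(msg, "high edges must exceed low edges")
  }
  if (length(msg)) msg else TRUE
})

#' Per-class averaged SSVEP templates
#'
#' @slot templates list of channels x samples class-average matrices, one
#'   per class (index = class).
#' @slot classes the class indices covered (1..Nf, complete).
#' @slot domain list with elements \code{day} and \code{electrode} tagging
#'   the domain the training data came from.
#' @slot nTrainingBlocks number of training blocks averaged.
#' @seealso [buildTemplates()], [eccaScore()]
#' @export
setClass("TemplateSet",
  representation(
    templates       = "list",
    classes         = "integer",
    domain          = "list",
    nTrainingBlocks = "integer"
  )
)

setValidity("TemplateSet", function(object) {
  msg <- character()
  if (length(object@templates) != length(object@classes))
    msg <- c(msg, "one template per class required")
  dims <- unique(lapply(object@templates, dim))
  if (length(dims) > 1L) msg <- c(msg, "all templates must share dimensions")
  if (length(msg)) msg else TRUE
})

#' Trained task-related component analysis (TRCA) model
#'
#' Per class, the spatial filter maximising inter-trial reproducibility
#' (leading generalised eigenvector of the aggregated/inter-trial covariance
#' pencil); the ensemble filter matrix stacks all class filters.
#'
#' @slot filters channels x Nf ensemble filter matrix W (column k = w_k,
#'   unit norm).
#' @slot templates the [TemplateSet-class] of class averages.
#' @slot covariances per-class list with elements \code{S} (inter-trial) and
#'   \code{Q} (aggregated) covariance matrices.
#' @slot classes class indices.
#' @seealso [trcaTrain()], [trcaClassify()]
#' @export
setClass("TRCAModel",
  representation(
    filters     = "matrix",
    templates   = "TemplateSet",
    covariances = "list",
    classes     = "integer"
  )
)

setValidity("TRCAModel", function(object) {
  msg <- character()
  if (ncol(object@filters) != length(object@classes))
    msg <- c(msg, "filters must have one column per class")
  nrm <- sqrt(colSums(object@filters^2))
  if (length(nrm) && max(abs(nrm - 1)) > 1e-6)
    msg <- c(msg, "each filter column must have unit norm")
  if (length(msg)) msg else TRUE
})

#' Subspace alignment maps between two recording domains
#'
#' @slot P per-class orthogonal Procrustes maps (list of d x d matrices)
#'   aligning source and target spatial patterns.
#' @slot Qc per-class CORAL covariance maps (list of channels x channels
#'   matrices).
#' @slot Cs per-class source covariance matrices (list).
#' @slot Ct pooled target covariance matrix.
#' @seealso [aspAlign()], [coralMap()], [alphaFit()]
#' @export
setClass("AlignmentMaps",
  representation(
    P  = "list",
    Qc = "list",
    Cs = "list",
    Ct = "matrix"
  )
)

#' Fitted align-and-pool (ALPHA) transfer decoder
#'
#' Holds, per filter-bank sub-band and stimulus class, the source-domain
#' spatial filters and templates, the target-domain filters estimated from
#' unlabelled data, the Procrustes and CORAL alignment maps, and the
#' precomputed projections used by [alphaClassify()].
#'
#' @slot design the [StimulusDesign-class].
#' @slot fb the [FilterBankSpec-class] used.
#' @slot fs sampling rate (Hz).
#' @slot nSamples decoding-window length (samples).
#' @slot bands internal per-sub-band fit data.
#' @slot maps per-sub-band [AlignmentMaps-class].
#' @slot signedSubbands whether sub-band fusion preserves score signs.
#' @seealso [alphaFit()], [alphaClassify()]
#' @export
setClass("AlphaModel",
  representation(
    design         = "StimulusDesign",
    fb             = "FilterBankSpec",
    fs             = "numeric",
    nSamples       = "integer",
    bands          = "list",
    maps           = "list",
    signedSubbands = "logical"
  )
)
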