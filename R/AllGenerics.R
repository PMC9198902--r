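#' @name EpochSet-accessors
#' @title Accessors for EpochSet objects
#' @description Dimension and metadata accessors for the
#'   [EpochSet-class] container, plus trial subsetting with `[`.
#' @param x,object an \code{EpochSet}.
#' @param i trial indices (logical or integer).
#' @param j,...,drop ignored (present for generic compatibility).
#' @return `nTrials`, `nChannels`, `nSamples` return integer counts;
#'   `samplingRate` the sampling rate in Hz; `epochLabels`, `epochBlocks`,
#'   `epochDays`, `epochElectrodes` per-trial metadata vectors;
#'   `epochData` the trials x channels x samples array; `x[i]` a subset
#'   \code{EpochSet}.
NULL

#' @rdname EpochSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("epochBlocks", function(x) standardGeneric("epochBlocks"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("epochDays", function(x) standardGeneric("epochDays"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("epochElectrodes", function(x) standardGeneric("epochElectrodes"))

#' @rdname EpochSet-accessors
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1])
#' @rdname EpochSet-accessors
#' @export
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2])
#' @rdname EpochSet-accessors
#' @export
setMethod("nSamples", "EpochSet", function(x) dim(x@data)[3])
#' @rdname EpochSet-accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname EpochSet-accessors
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)
#' @rdname EpochSet-accessors
#' @export
setMethod("epochLabels", "EpochSet", function(x) x@labels)
#' @rdname EpochSet-accessors
#' @export
setMethod("epochBlocks", "EpochSet", function(x) x@block)
#' @rdname EpochSet-accessors
#' @export
setMethod("epochDays", "EpochSet", function(x) x@day)
#' @rdname EpochSet-accessors
#' @export
setMethod("epochElectrodes", "EpochSet", function(x) x@electrode)

#' @rdname EpochSet-accessors
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  new("EpochSet",
      data = x@data[i, , , drop = FALSE], fs = x@fs,
      labels = x@labels[i], block = x@block[i], day = x@day[i],
      electrode = x@electrode[i], onsetIndex = x@onsetIndex)
})

#' @name design-accessors
#' @title Accessors for StimulusDesign objects
#' @param x a [StimulusDesign-class].
#' @return `stimulusFrequencies` the per-target frequencies (Hz),
#'   `stimulusPhases` the per-target initial phases reduced to \[0, 2pi),
#'   `nTargets` and `nHarmonics` integer counts.
NULL

#' @rdname design-accessors
#' @export
setGeneric("stimulusFrequencies",
           function(x) standardGeneric("stimulusFrequencies"))
#' @rdname design-accessors
#' @export
setGeneric("stimulusPhases", function(x) standardGeneric("stimulusPhases"))
#' @rdname design-accessors
#' @export
setGeneric("nTargets", function(x) standardGeneric("nTargets"))
#' @rdname design-accessors
#' @export
setGeneric("nHarmonics", function(x) standardGeneric("nHarmonics"))

#' @rdname design-accessors
#' @export
setMethod("stimulusFrequencies", "StimulusDesign", function(x)
  x@baseFreq + (seq_len(x@nTargets) - 1) * x@freqStep)
#' @rdname design-accessors
#' @export
setMethod("stimulusPhases", "StimulusDesign", function(x)
  (x@basePhase + (seq_len(x@nTargets) - 1) * x@phaseStep) %% (2 * pi))
#' @rdname design-accessors
#' @export
setMethod("nTargets", "StimulusDesign", function(x) x@nTargets)
#' @rdname design-accessors
#' @export
setMethod("nHarmonics", "StimulusDesign", function(x) x@nHarmonics)

setMethod("show", "StimulusDesign", function(object) {
  f <- stimulusFrequencies(object)
  cat(sprintf(
    "StimulusDesign: %d targets, %.1f-%.1f Hz (step %.2g Hz), %d harmonics\n",
    object@nTargets, min(f), max(f), object@freqStep, object@nHarmonics))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat(sprintf("  classes: %d, blocks: %d, days: %s, electrodes: %s\n",
              length(unique(object@labels)), length(unique(object@block)),
              paste(unique(object@day), collapse = ","),
              paste(unique(object@electrode), collapse = ",")))
})

setMethod("show", "FilterBankSpec", function(object) {
  cat(sprintf("FilterBankSpec: %d sub-bands, v(n) = n^-%g + %g\n",
              object@nSubbands, object@weightA, object@weightB))
  for (n in seq_len(object@nSubbands))
    cat(sprintf("  band %d: %g-%g Hz (weight %.3f)\n", n,
                object@bandEdges[n, 1], object@bandEdges[n, 2],
                subbandWeights(object)[n]))
})

setMethod("show", "TRCAModel", function(object) {
  cat(sprintf("TRCAModel: %d classes, %d channels (domain day %s, %s)\n",
              length(object@classes), nrow(object@filters),
              paste(unique(object@templates@domain$day), collapse = ","),
              paste(unique(object@templates@domain$electrode),
                    collapse = ",")))
})

setMethod("show", "AlphaModel", function(object) {
  cat(sprintf(
    "AlphaModel: %d classes, %d sub-bands, window %d samples @ %g Hz\n",
    nTargets(object@design), object@fb@nSubbands, object@nSamples,
    object@fs))
})

setMethod("show", "TemplateSet", function(object) {
  d <- dim(object@templates[[1]])
  cat(sprintf(
    "TemplateSet: %d classes, %d channels x %d samples (day %s, %s, %d blocks)\n",
    length(object@classes), d[1], d[2],
    paste(object@domain$day, collapse = ","),
    paste(object@domain$electrode, collapse = ","),
    object@nTrainingBlocks))
})
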