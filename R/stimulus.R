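#' Construct a JFPM stimulus design
#'
#' Builds the joint frequency-phase coded target grid.  With the defaults
#' this is the standard 40-target speller layout: frequencies 8 to 15.8 Hz
#' in 0.2 Hz steps, initial phases cycling through 0, 0.5pi, pi, 1.5pi.
#'
#' @param nTargets number of targets (>= 1).
#' @param baseFreq frequency of target 1 (Hz, > 0).
#' @param freqStep frequency increment (Hz, >= 0).
#' @param basePhase initial phase of target 1 (rad).
#' @param phaseStep phase increment (rad).
#' @param nHarmonics number of harmonics used for reference signals.
#' @return a [StimulusDesign-class] object.
#' @examples
#' design <- makeStimulusDesign()
#' stimulusFrequencies(design)[40]  # 15.8 Hz
#' @export
makeStimulusDesign <- function(nTargets = 40L, baseFreq = 8, freqStep = 0.2,
                               basePhase = 0, phaseStep = 0.5 * pi,
                               nHarmonics = 5L) {
  if (baseFreq <= 0) stop("invalid design: baseFreq must be positive")
  new("StimulusDesign",
      nTargets = as.integer(nTargets), baseFreq = baseFreq,
      freqStep = freqStep, basePhase = basePhase, phaseStep = phaseStep,
      nHarmonics = as.integer(nHarmonics))
}
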