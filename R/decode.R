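#' Train-and-classify front end for the five decoders
#'
#' Unified interface used by the evaluation protocols: trains the requested
#' decoder on the (windowed) source epochs and classifies the (windowed)
#' test epochs.  Methods:
#' \describe{
#'   \item{\code{"cca"}}{training-free CCA / FBCCA; \code{source} ignored.}
#'   \item{\code{"ecca"}}{extended CCA with templates from \code{source}
#'     (assumed same domain as the test data).}
#'   \item{\code{"ttcca"}}{eCCA with templates transferred from a different
#'     domain, no alignment.}
#'   \item{\code{"trca"}}{ensemble TRCA trained per sub-band on
#'     \code{source}.}
#'   \item{\code{"alpha"}}{align-and-pool transfer decoder; the test trials
#'     serve as the unlabelled target set.}
#' }
#'
#' @param method one of \code{"cca"}, \code{"ecca"}, \code{"ttcca"},
#'   \code{"trca"}, \code{"alpha"}.
#' @param source labelled training [EpochSet-class] (ignored for
#'   \code{"cca"}).
#' @param test [EpochSet-class] to classify; must share the window length.
#' @param design a [StimulusDesign-class].
#' @param fb optional [FilterBankSpec-class]; when supplied all methods use
#'   filter-bank fusion.
#' @param nHarmonics reference harmonics.
#' @param srcBands,testBands optional pre-decomposed sub-band lists (as
#'   returned by [filterbankDecompose()]), reused by the evaluation
#'   protocols to avoid repeated filtering.
#' @return integer predictions with score matrix attribute \code{"scores"}.
#' @export
decodeTransfer <- function(method, source, test, design, fb = NULL,
                           nHarmonics = NULL, srcBands = NULL,
                           testBands = NULL) {
  method <- match.arg(method, c("cca", "ecca", "ttcca", "trca", "alpha"))
  K <- nTargets(design)
  if (method == "cca") {
    if (is.null(testBands))
      return(ccaClassify(test, design, fb, nHarmonics))
    return(ccaClassifyBands(test, testBands, design, fb, nHarmonics))
  }
  if (is.null(fb)) fbUse <- makeFilterBankSpec(1L) else fbUse <- fb
  if (is.null(srcBands))
    srcBands <- if (is.null(fb)) list(source)
                else filterbankDecompose(source, fb)
  if (is.null(testBands))
    testBands <- if (is.null(fb)) list(test)
                 else filterbankDecompose(test, fb)
  if (method %in% c("ecca", "ttcca")) {
    templates <- lapply(srcBands, buildTemplates, nClasses = K)
    if (method == "ttcca") {
      dom <- templates[[1]]@domain
      if (setequal(dom$day, unique(test@day)) &&
          setequal(dom$electrode, unique(test@electrode)))
        warning("template domain equals test domain; ttCCA degenerates to eCCA")
    }
    return(eccaClassifyEpochs(test, templates, design, fb, nHarmonics,
                              testBands = testBands))
  }
  if (method == "trca") {
    models <- trcaFitBands(srcBands, K)
    if (is.null(fb)) return(trcaClassify(testBands[[1]], models[[1]]))
    return(trcaClassifyBands(testBands, models, fb))
  }
  # alpha: the test trials serve as the unlabelled target set
  alphaPipeline(source, test, design, fbUse, nHarmonics,
                srcBands = if (is.null(fb)) list(source) else srcBands,
                tgtBands = if (is.null(fb)) list(test) else testBands)
}
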