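# Individual-template CCA decoding: class-average templates, the
# three-feature extended CCA (eCCA) score, and its transferred-template
# variant (ttCCA).

#' Build per-class averaged templates from labelled training epochs
#'
#' Template k is the arithmetic mean over all class-k training trials.
#'
#' @param training a labelled [EpochSet-class].
#' @param nClasses total number of classes expected (defaults to the
#'   largest label present).
#' @return a [TemplateSet-class] tagged with the training domain.
#' @export
buildTemplates <- function(training, nClasses = max(training@labels)) {
  classes <- seq_len(nClasses)
  missing <- setdiff(classes, unique(training@labels))
  if (length(missing))
    stop("incomplete training: no trials for class ",
         paste(missing, collapse = ", "))
  templates <- lapply(classes, function(k) {
    idx <- which(training@labels == k)
    m <- training@data[idx[1], , ]
    if (length(idx) > 1L)
      for (i in idx[-1]) m <- m + training@data[i, , ]
    m / length(idx)
  })
  new("TemplateSet", templates = templates, classes = classes,
      domain = list(day = unique(training@day),
                    electrode = unique(training@electrode)),
      nTrainingBlocks = length(unique(training@block)))
}

# correlation of two 1-D projections; 0 (with a warning) when either has
# zero variance
safeCor <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) {
    warning("zero-variance projection; feature score set to 0")
    return(0)
  }
  cor(a, b)
}

# sign-preserving squared sum pooling of correlation features
signedSquareSum <- function(r) sum(sign(r) * r^2)

#' Extended-CCA score vector for one trial
#'
#' For every class k, three correlation features are computed: (1) the test
#' trial against the class template, both projected through the filter from
#' CCA(template, reference); (2) the same pair projected through the filter
#' from CCA(trial, reference); (3) the plain canonical correlation between
#' trial and reference.  Features are pooled by the sign-preserving squared
#' sum.
#'
#' @param X channels x samples test trial.
#' @param templates a [TemplateSet-class].
#' @param references list of per-class reference matrices (see
#'   [referenceSet()]).
#' @return numeric class-score vector rho_k with the features matrix
#'   (classes x 3) as attribute \code{"features"}.
#' @export
eccaScore <- function(X, templates, references) {
  if (!length(templates@templates)) stop("empty TemplateSet")
  K <- length(templates@classes)
  if (length(references) < K)
    stop("references must cover every class")
  Xc <- rowCenter(as.matrix(X))
  feats <- matrix(0, K, 3)
  for (k in seq_len(K)) {
    Tk <- rowCenter(templates@templates[[k]])
    if (!all(dim(Tk) == dim(Xc)))
      stop("template/trial dimension mismatch")
    Qy <- refBasis(references[[k]])
    w1 <- suppressWarnings(ccaDecomp(Tk, references[[k]])$wx)
    cc <- ccaFast(Xc, Qy, wantFilter = TRUE)
    feats[k, 1] <- safeCor(crossprod(Xc, w1), crossprod(Tk, w1))
    feats[k, 2] <- safeCor(crossprod(Xc, cc$wx), crossprod(Tk, cc$wx))
    feats[k, 3] <- cc$rho
  }
  structure(apply(feats, 1, signedSquareSum), features = feats)
}

#' Transferred-template CCA score vector
#'
#' Identical computation to [eccaScore()] but with templates built in a
#' different (day, electrode) domain; warns when the template domain equals
#' the test domain, in which case the method degenerates to eCCA.
#'
#' @param X channels x samples test trial.
#' @param transferredTemplates a [TemplateSet-class] from the source
#'   domain.
#' @param references list of per-class reference matrices.
#' @param testDomain optional list(day =, electrode =) of the test trial,
#'   used for the degenerate-transfer warning.
#' @return as [eccaScore()].
#' @export
ttccaScore <- function(X, transferredTemplates, references,
                       testDomain = NULL) {
  if (!length(transferredTemplates@templates)) stop("empty TemplateSet")
  if (!is.null(testDomain)) {
    dom <- transferredTemplates@domain
    if (setequal(dom$day, testDomain$day) &&
        setequal(dom$electrode, testDomain$electrode))
      warning("template domain equals test domain; ttCCA degenerates to eCCA")
  }
  eccaScore(X, transferredTemplates, references)
}
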