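# Canonical correlation analysis between a multichannel trial and a
# reference set, plus the training-free CCA/FBCCA classifiers.

rowCenter <- function(X) X - rowMeans(X)

# Cholesky of a Gram matrix, ridge-regularised (eps = ridge * trace / dim)
# when rank-deficient.  Returns list(R = upper Cholesky, ridged = logical).
cholRidge <- function(G, ridge = 1e-9) {
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (!is.null(R)) return(list(R = R, ridged = FALSE))
  eps <- ridge * sum(diag(G)) / nrow(G)
  if (eps <= 0) eps <- ridge
  list(R = chol(G + eps * diag(nrow(G))), ridged = TRUE)
}

# sign convention: largest-magnitude coefficient positive
fixSign <- function(w) {
  s <- sign(w[which.max(abs(w))])
  if (s == 0) s <- 1
  w * s
}

#' Canonical correlation between two multichannel signals
#'
#' Finds the spatial filter pair \code{(wx, wy)} maximising the Pearson
#' correlation between \code{t(X) \%*\% wx} and \code{t(Y) \%*\% wy}.
#' Both inputs are mean-centred per row internally.  Rank-deficient
#' within-set covariances are ridge-regularised (eps = 1e-9 * trace / dim)
#' with a warning.
#'
#' @param X channels x samples matrix.
#' @param Y reference (or second signal) matrix, rows x samples.
#' @return a list with elements \code{wx}, \code{wy} (first canonical
#'   filter pair, largest-magnitude coefficient positive) and \code{rho}
#'   (largest canonical correlation, clipped to \[0, 1\]).
#' @examples
#' X <- matrix(rnorm(3 * 200), 3)
#' ccaDecomp(X, X)$rho  # 1
#' @export
ccaDecomp <- function(X, Y) {
  X <- rowCenter(as.matrix(X))
  Y <- rowCenter(as.matrix(Y))
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same sample count")
  Gx <- tcrossprod(X)
  Gy <- tcrossprod(Y)
  Gxy <- tcrossprod(X, Y)
  cx <- cholRidge(Gx)
  cy <- cholRidge(Gy)
  if (cx$ridged || cy$ridged)
    warning("rank-deficient within-set covariance; ridge regularisation applied")
  M <- backsolve(cx$R, t(backsolve(cy$R, t(Gxy), transpose = TRUE)),
                 transpose = TRUE)
  sv <- svd(M, nu = 1, nv = 1)
  wx <- backsolve(cx$R, sv$u[, 1])
  wy <- backsolve(cy$R, sv$v[, 1])
  # keep corr(X'wx, Y'wy) = +rho under the sign convention on wx
  s <- sign(wx[which.max(abs(wx))])
  if (s == 0) s <- 1
  list(wx = wx * s, wy = wy * s, rho = min(max(sv$d[1], 0), 1))
}

# precomputed per-class reference structure for the fast per-trial CCA:
# orthonormal basis Qy (samples x 2H) of the centred reference rows
refBasis <- function(Y) {
  Yc <- rowCenter(Y)
  qr.Q(qr(t(Yc)))
}

# fast CCA of a centred trial Xc against a precomputed reference basis.
# Returns rho and (optionally) wx.
ccaFast <- function(Xc, Qy, wantFilter = FALSE) {
  Gx <- tcrossprod(Xc)
  cx <- cholRidge(Gx)
  B <- Xc %*% Qy
  M <- backsolve(cx$R, B, transpose = TRUE)
  if (wantFilter) {
    sv <- svd(M, nu = 1, nv = 0)
    list(rho = min(max(sv$d[1], 0), 1),
         wx = fixSign(backsolve(cx$R, sv$u[, 1])))
  } else {
    d2 <- eigen(tcrossprod(M), symmetric = TRUE, only.values = TRUE)$values[1]
    list(rho = min(sqrt(max(d2, 0)), 1))
  }
}

# CCA from accumulated (per-trial centred) covariances -- equivalent to CCA
# on trials concatenated against a periodically tiled reference
ccaFromCov <- function(Cxx, Cyy, Cxy) {
  cx <- cholRidge(Cxx)
  cy <- cholRidge(Cyy)
  M <- backsolve(cx$R, t(backsolve(cy$R, t(Cxy), transpose = TRUE)),
                 transpose = TRUE)
  sv <- svd(M)
  wx <- apply(backsolve(cx$R, sv$u), 2, fixSign)
  list(wx = wx, rho = pmin(pmax(sv$d, 0), 1))
}

#' Training-free CCA / FBCCA classification
#'
#' Scores every trial against the sine-cosine references of every class and
#' picks the class with the largest canonical correlation.  With a
#' [FilterBankSpec-class] the trial is first decomposed into sub-bands and
#' the per-band correlations fused with [combineSubbands()] (the FBCCA
#' decoder).  Ties break to the lowest class index.
#'
#' @param epochs an [EpochSet-class] of (windowed) test trials.
#' @param design a [StimulusDesign-class].
#' @param fb optional [FilterBankSpec-class].
#' @param nHarmonics harmonics in the references (defaults to the design's).
#' @return integer vector of predicted classes, with the trials x classes
#'   fused score matrix as attribute \code{"scores"}.
#' @export
ccaClassify <- function(epochs, design, fb = NULL,
                        nHarmonics = NULL) {
  bands <- if (is.null(fb)) list(epochs) else filterbankDecompose(epochs, fb)
  ccaClassifyBands(epochs, bands, design, fb, nHarmonics)
}

# band-level CCA/FBCCA scoring on pre-decomposed sub-bands
ccaClassifyBands <- function(epochs, bands, design, fb = NULL,
                             nHarmonics = NULL) {
  refs <- referenceSet(design, epochs@fs, nSamples(epochs), nHarmonics)
  bases <- lapply(refs, refBasis)
  Qyall <- do.call(cbind, bases)
  m <- ncol(bases[[1]])
  K <- nTargets(design)
  n <- nTrials(epochs)
  perBand <- lapply(bands, function(b) {
    S <- matrix(0, n, K)
    for (i in seq_len(n)) {
      Xc <- rowCenter(b@data[i, , ])
      S[i, ] <- batchCcaRho(Xc, Qyall, m, K)
    }
    S
  })
  scores <- if (is.null(fb)) perBand[[1]] else {
    fused <- matrix(0, n, K)
    for (i in seq_len(n))
      fused[i, ] <- combineSubbands(lapply(perBand, function(S) S[i, ]), fb)
    fused
  }
  pred <- apply(scores, 1, which.max)  # which.max: lowest index on ties
  structure(as.integer(pred), scores = scores)
}
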