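# Task-related component analysis: spatial filters maximising inter-trial
# reproducibility of the SSVEP, with ensemble classification.

# per-class TRCA covariance pair: S sums Cov(Xi, Xj) over i != j; the
# aggregated Q sums over all (i, j) pairs including i = j
trcaCovariances <- function(trials) {
  C <- nrow(trials[[1]])
  nb <- length(trials)
  cent <- lapply(trials, rowCenter)
  Ssum <- matrix(0, C, C)
  D <- matrix(0, C, C)
  # sum over all pairs = Cov(sum Xi, sum Xj); subtract the diagonal terms
  Xsum <- Reduce(`+`, cent)
  allPairs <- tcrossprod(Xsum)
  for (i in seq_len(nb)) D <- D + tcrossprod(cent[[i]])
  S <- allPairs - D
  list(S = S, Q = allPairs)
}

#' Train a TRCA model
#'
#' Per class, solves the generalised Rayleigh quotient
#' \eqn{\max_w w'Sw / w'Qw} where S is the inter-trial covariance (sum of
#' cross-trial covariances, i != j) and Q the aggregated covariance (all
#' pairs).  The class filters are stacked into the ensemble matrix W.  At
#' least two trials per class are required; a singular Q is
#' ridge-regularised with a warning.
#'
#' Trials are mean-centred per channel before covariances are computed.
#' Note some TRCA variants use the concatenated-data covariance for Q; here
#' the aggregated all-pairs form is used.
#'
#' @param training a labelled [EpochSet-class].
#' @param nClasses number of classes (defaults to the largest label).
#' @return a [TRCAModel-class].
#' @export
trcaTrain <- function(training, nClasses = max(training@labels)) {
  classes <- seq_len(nClasses)
  C <- nChannels(training)
  W <- matrix(0, C, length(classes))
  covs <- vector("list", length(classes))
  for (k in classes) {
    idx <- which(training@labels == k)
    if (length(idx) < 2L)
      stop("insufficient trials: TRCA needs >= 2 trials per class")
    trials <- lapply(idx, function(i) training@data[i, , ])
    cv <- trcaCovariances(trials)
    cq <- cholRidge(cv$Q, ridge = 1e-9)
    if (cq$ridged)
      warning("singular aggregated covariance; ridge regularisation applied")
    # leading eigenvector of Q^-1 S via the symmetric whitened pencil
    Mw <- backsolve(cq$R, t(backsolve(cq$R, t(cv$S), transpose = TRUE)),
                    transpose = TRUE)
    ev <- eigen((Mw + t(Mw)) / 2, symmetric = TRUE)
    w <- backsolve(cq$R, ev$vectors[, 1])
    w <- fixSign(w / sqrt(sum(w^2)))
    W[, k] <- w
    covs[[k]] <- cv
  }
  new("TRCAModel", filters = W, templates = buildTemplates(training, nClasses),
      covariances = covs, classes = classes)
}

# centred, flattened ensemble projection of a trial: vec(t(X) %*% W)
trcaProjection <- function(X, W) {
  v <- as.numeric(crossprod(rowCenter(X), W))
  v - mean(v)
}

#' Classify trials with a TRCA model
#'
#' Projects the test trial and every class template through the full
#' ensemble filter matrix W, flattens the (samples x Nf) projections, and
#' Pearson-correlates them; the predicted class maximises the correlation
#' (lowest index on ties).
#'
#' @param test an [EpochSet-class] of test trials.
#' @param model a [TRCAModel-class].
#' @return integer vector of predictions with the score matrix as
#'   attribute \code{"scores"}.
#' @export
trcaClassify <- function(test, model) {
  W <- model@filters
  K <- length(model@classes)
  N <- nSamples(test)
  n <- nTrials(test)
  M <- vapply(seq_len(K),
              function(k) trcaProjection(model@templates@templates[[k]], W),
              numeric(N * ncol(W)))
  Mn <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  # all trial projections in two large products: centre per channel,
  # project through W, then flatten each trial's (samples x Nf) projection
  d <- test@data - as.vector(rowMeans(test@data, dims = 2L))
  D <- matrix(aperm(d, c(3, 1, 2)), N * n)         # (sample, trial) x chan
  P <- array(D %*% W, c(N, n, ncol(W)))
  V <- matrix(aperm(P, c(1, 3, 2)), N * ncol(W), n)  # vec per trial
  V <- sweep(V, 2, colMeans(V))
  S <- crossprod(V, Mn) / sqrt(colSums(V^2))       # Pearson (Mn centred)
  pred <- apply(S, 1, which.max)
  structure(as.integer(pred), scores = S)
}

# filter-bank TRCA: train one model per sub-band, fuse scores with v(n)
trcaFitBands <- function(trainBands, nClasses) {
  lapply(trainBands, trcaTrain, nClasses = nClasses)
}

trcaClassifyBands <- function(testBands, models, fb, signed = TRUE) {
  perBand <- lapply(seq_along(testBands), function(b)
    attr(trcaClassify(testBands[[b]], models[[b]]), "scores"))
  n <- nrow(perBand[[1]])
  K <- ncol(perBand[[1]])
  fused <- matrix(0, n, K)
  for (i in seq_len(n))
    fused[i, ] <- combineSubbands(lapply(perBand, function(S) S[i, ]),
                                  fb, signed = signed)
  pred <- apply(fused, 1, which.max)
  structure(as.integer(pred), scores = fused)
}
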