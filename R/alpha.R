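# Align-and-pool (ALPHA) transfer decoder: subspace decomposition of the
# source model, orthogonal-Procrustes alignment of spatial patterns (ASP),
# CORAL covariance alignment (AC), and pooled correlation scoring.

#' Spatial pattern of a filter matrix
#'
#' The forward mixing pattern corresponding to a spatial filter matrix W is
#' its inverse-transpose (pseudo-inverse-transpose for non-square W), so
#' that \code{t(W) \%*\% A = I} for full-column-rank W.  Rank-deficient
#' input is handled with a regularised pseudo-inverse and a warning.
#'
#' @param W channels x d filter matrix.
#' @return channels x d pattern matrix.
#' @export
spatialPattern <- function(W) {
  W <- as.matrix(W)
  G <- crossprod(W)
  Gi <- tryCatch(solve(G), error = function(e) NULL)
  if (is.null(Gi)) {
    warning("rank-deficient filter matrix; regularised pseudo-inverse used")
    Gi <- solve(G + 1e-10 * sum(diag(G)) / nrow(G) * diag(nrow(G)))
  }
  W %*% Gi
}

#' Orthogonal Procrustes alignment of two spatial-pattern matrices
#'
#' Solves \eqn{\min_P \|A_1 - A_2 P'\|_F} over orthogonal P; the solution
#' is \eqn{P = U V'} with U, V the singular vectors of \eqn{A_1' A_2}.
#'
#' @param A1 source-domain pattern matrix (channels x d).
#' @param A2 target-domain pattern matrix, same shape.
#' @return the d x d orthogonal map P.
#' @export
aspAlign <- function(A1, A2) {
  if (!all(dim(as.matrix(A1)) == dim(as.matrix(A2))))
    stop("A1 and A2 must have the same shape")
  M <- crossprod(as.matrix(A1), as.matrix(A2))
  if (max(abs(M)) == 0) stop("degenerate SVD: zero pattern matrix")
  sv <- svd(M)
  sv$u %*% t(sv$v)
}

#' Transform a filter matrix by a Procrustes map
#'
#' @param W2 filter matrix (channels x d).
#' @param P orthogonal map from [aspAlign()].
#' @return \code{W2 \%*\% t(P)}.
#' @export
applyAsp <- function(W2, P) as.matrix(W2) %*% t(P)

# covariance of horizontally concatenated trials with a centering matrix
# over the concatenated length
concatCovariance <- function(trials) {
  X <- do.call(cbind, trials)
  n <- ncol(X)
  if (n < 2) stop("fewer than 2 samples")
  Xc <- X - rowMeans(X)
  tcrossprod(Xc) / (n - 1)
}

#' Per-class source and pooled target covariances
#'
#' The per-class source covariance concatenates all class-k source trials
#' and applies the centering matrix over the concatenated length; the
#' target covariance pools all (unlabelled) target trials the same way.
#'
#' @param source a labelled [EpochSet-class].
#' @param targetUnlabeled an [EpochSet-class]; labels are ignored.
#' @return list with \code{Cs} (per-class list of channels x channels
#'   matrices) and \code{Ct}.
#' @export
classCovariances <- function(source, targetUnlabeled) {
  classes <- sort(unique(source@labels))
  Cs <- lapply(classes, function(k) {
    idx <- which(source@labels == k)
    concatCovariance(lapply(idx, function(i) source@data[i, , ]))
  })
  names(Cs) <- classes
  Ct <- concatCovariance(lapply(seq_len(nTrials(targetUnlabeled)),
                                function(i) targetUnlabeled@data[i, , ]))
  list(Cs = Cs, Ct = Ct)
}

# symmetric PSD matrix power via eigendecomposition; the ridge floor is
# applied only when the spectrum actually needs it
symmPower <- function(M, p, ridge = 1e-6) {
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  eps <- ridge * sum(diag(M)) / nrow(M)
  vals <- ev$values
  if (min(vals) < eps) vals <- pmax(vals, max(eps, .Machine$double.eps))
  ev$vectors %*% (vals^p * t(ev$vectors))
}

#' CORAL covariance-alignment map
#'
#' Computes \eqn{Q_c = C_s^{-1/2} C_t^{1/2}} with symmetric PSD square
#' roots (ridge eps = 1e-6 * trace / dim applied before the inverse root),
#' the minimiser of the Frobenius distance between the mapped source and
#' target second-order statistics: \eqn{Q_c' C_s Q_c = C_t}.
#'
#' @param Cs source covariance (SPD).
#' @param Ct target covariance (SPD).
#' @return the channels x channels map Q_c.
#' @export
coralMap <- function(Cs, Ct) {
  if (max(abs(Cs - t(Cs))) > 1e-8 || max(abs(Ct - t(Ct))) > 1e-8)
    stop("covariances must be symmetric")
  symmPower(Cs, -0.5) %*% symmPower(Ct, 0.5)
}

#' Transform a spatial filter by a CORAL map
#'
#' @param W filter matrix (channels x d).
#' @param Qc map from [coralMap()].
#' @return \code{Qc \%*\% W}.
#' @export
applyCoral <- function(W, Qc) {
  W <- as.matrix(W)
  if (ncol(Qc) != nrow(W)) stop("shape mismatch between Qc and W")
  Qc %*% W
}

# Rank-1 task-related spatial subspace of an epoch set, estimated from the
# labelled (or pseudo-labelled) whitened cross-covariances with the class
# references: stack per-class accumulated trial-reference cross terms,
# whiten by the pooled trial covariance, and take the leading left
# singular direction.  Returns the unit filter (largest-magnitude
# coefficient positive).
stackedSubspaceFilter <- function(bandData, labs, bases, K) {
  C <- dim(bandData)[2]
  m <- ncol(bases[[1]])
  Cxx <- matrix(0, C, C)
  B <- matrix(0, C, m * K)
  for (i in seq_len(dim(bandData)[1])) {
    Xc <- rowCenter(bandData[i, , ])
    k <- labs[i]
    Cxx <- Cxx + tcrossprod(Xc)
    cols <- (k - 1L) * m + seq_len(m)
    B[, cols] <- B[, cols] + Xc %*% bases[[k]]
  }
  cx <- cholRidge(Cxx)
  sv <- svd(backsolve(cx$R, B, transpose = TRUE), nu = 1, nv = 0)
  w <- backsolve(cx$R, sv$u[, 1])
  fixSign(w / sqrt(sum(w^2)))
}

# per-band fit of everything ALPHA needs; band inputs are already
# filter-bank-decomposed epoch sets
alphaFitBand <- function(sb, tb, refs, bases, K) {
  N <- nSamples(sb)
  refsC <- lapply(refs, rowCenter)
  Cyy <- lapply(refsC, tcrossprod)
  templ <- buildTemplates(sb, K)
  trca <- suppressWarnings(trcaTrain(sb, K))
  covs <- classCovariances(sb, tb)

  W1 <- WB <- vector("list", K)
  PT <- vector("list", K)
  Qk <- vector("list", K)
  for (k in seq_len(K)) {
    Tk <- rowCenter(templ@templates[[k]])
    w1 <- suppressWarnings(ccaDecomp(Tk, refs[[k]])$wx)
    idx <- which(sb@labels == k)
    srcC <- lapply(idx, function(i) rowCenter(sb@data[i, , ]))
    CxxS <- Reduce(`+`, lapply(srcC, tcrossprod))
    CxyS <- Reduce(`+`, lapply(srcC, function(Xc) tcrossprod(Xc, refsC[[k]])))
    w2 <- ccaFromCov(CxxS, length(idx) * Cyy[[k]], CxyS)$wx[, 1]
    w3 <- trca@filters[, k]
    W1k <- cbind(w1, w2, w3)
    Qc <- coralMap(covs$Cs[[as.character(k)]], covs$Ct)
    W1[[k]] <- W1k
    WB[[k]] <- applyCoral(W1k, Qc)   # CORAL-mapped source filters
    PT[[k]] <- crossprod(Tk, W1k)    # template projections (N x 3)
    Qk[[k]] <- Qc
  }
  w1s <- stackedSubspaceFilter(sb@data, sb@labels, bases, K)
  PT1s <- vapply(seq_len(K), function(k)
    as.numeric(crossprod(rowCenter(templ@templates[[k]]), w1s)), numeric(N))
  list(templates = templ, refsBases = bases,
       W1 = W1, WB = WB,
       WBall = do.call(cbind, WB), PTall = do.call(cbind, PT),
       w1s = w1s, PT1s = PT1s, Qc = Qk, Cs = covs$Cs, Ct = covs$Ct)
}

# stage-1 (CORAL + reference-CCA families) score matrix for one band
alphaStage1Scores <- function(bandEpochs, bd, K) {
  n <- nTrials(bandEpochs)
  Qyall <- do.call(cbind, bd$refsBases)
  m <- ncol(bd$refsBases[[1]])
  S <- matrix(0, n, K)
  for (i in seq_len(n)) {
    Xc <- rowCenter(bandEpochs@data[i, , ])
    rC <- batchCcaRho(Xc, Qyall, m, K)
    rB <- batchColCor(crossprod(Xc, bd$WBall), bd$PTall)
    S[i, ] <- colSums(matrix(sign(rB) * rB^2, nrow = 3L)) + sign(rC) * rC^2
  }
  S
}

# aligned-subspace (ASP family) raw correlations for one band: the test
# trial through the target subspace filter against each class template
# through the source subspace filter
alphaAspScores <- function(bandEpochs, bd, K) {
  n <- nTrials(bandEpochs)
  S <- matrix(0, n, K)
  PTc <- sweep(bd$PT1s, 2, colMeans(bd$PT1s))
  PTn <- sqrt(colSums(PTc^2))
  for (i in seq_len(n)) {
    px <- as.numeric(crossprod(rowCenter(bandEpochs@data[i, , ]), bd$w2s))
    px <- px - mean(px)
    den <- PTn * sqrt(sum(px^2))
    r <- as.numeric(crossprod(PTc, px))
    S[i, ] <- ifelse(den == 0, 0, r / den)
  }
  S
}

fuseBandScores <- function(perBand, fb, signed) {
  n <- nrow(perBand[[1]])
  K <- ncol(perBand[[1]])
  fused <- matrix(0, n, K)
  v <- subbandWeights(fb)[seq_along(perBand)]
  for (b in seq_along(perBand)) {
    sq <- if (signed) sign(perBand[[b]]) * perBand[[b]]^2 else perBand[[b]]^2
    fused <- fused + v[b] * sq
  }
  fused
}

#' Fit the ALPHA transfer decoder
#'
#' Per filter-bank sub-band the fit proceeds in three steps.
#' (1) Subspace decomposition: three source filters per class
#' (template-reference CCA, trial-reference CCA, TRCA) plus a shared
#' rank-1 task subspace filter estimated from the labelled source trials;
#' per-class source covariances and the pooled target covariance.
#' (2) Covariance alignment (AC): the CORAL map from each class's source
#' covariance to the pooled target covariance is applied to that class's
#' source filters.  (3) Spatial-pattern alignment (ASP): the target task
#' subspace cannot be estimated from unlabelled trials directly at
#' realistic SNR, so the AC + reference-CCA stage first classifies the
#' unlabelled target trials; the pseudo-labels then drive the same
#' stacked-subspace estimator on the target side, and the source and
#' target subspaces are aligned by orthogonal Procrustes on their spatial
#' patterns (for the rank-1 subspace the map reduces to a sign, fixed by
#' consensus with the pseudo-labels).
#'
#' @param source a fully labelled [EpochSet-class] (windowed).
#' @param targetUnlabeled an [EpochSet-class] of unlabelled target-domain
#'   trials (the test trials themselves may serve).
#' @param design a [StimulusDesign-class].
#' @param fb a [FilterBankSpec-class].
#' @param nHarmonics reference harmonics (defaults to the design's).
#' @param signedSubbands preserve score signs in sub-band fusion.
#' @return an [AlphaModel-class].
#' @export
alphaFit <- function(source, targetUnlabeled, design, fb,
                     nHarmonics = NULL, signedSubbands = TRUE) {
  alphaFitCore(source, targetUnlabeled, design, fb, nHarmonics,
               signedSubbands)$model
}

# full fit; also returns the stage-1 band scores and pseudo-labels of the
# target trials so that pipelines classifying exactly those trials can
# avoid recomputation
alphaFitCore <- function(source, targetUnlabeled, design, fb,
                         nHarmonics = NULL, signedSubbands = TRUE,
                         srcBands = NULL, tgtBands = NULL) {
  if (nTrials(targetUnlabeled) < 1L) stop("empty target set")
  if (nSamples(source) != nSamples(targetUnlabeled))
    stop("source and target windows must have equal length")
  K <- nTargets(design)
  N <- nSamples(source)
  refs <- referenceSet(design, source@fs, N, nHarmonics)
  bases <- lapply(refs, refBasis)
  if (is.null(srcBands)) srcBands <- filterbankDecompose(source, fb)
  if (is.null(tgtBands)) tgtBands <- filterbankDecompose(targetUnlabeled, fb)
  nb <- fb@nSubbands

  bands <- lapply(seq_len(nb), function(b)
    alphaFitBand(srcBands[[b]], tgtBands[[b]], refs, bases, K))

  # stage 1: classify the unlabelled target trials with AC + reference
  # features, giving pseudo-labels for the target-subspace estimation
  stage1 <- lapply(seq_len(nb), function(b)
    alphaStage1Scores(tgtBands[[b]], bands[[b]], K))
  pseudo <- apply(fuseBandScores(stage1, fb, signedSubbands), 1, which.max)

  # stage 2: pseudo-labelled target subspace + Procrustes alignment
  maps <- vector("list", nb)
  aspTgt <- vector("list", nb)
  for (b in seq_len(nb)) {
    w2s <- stackedSubspaceFilter(tgtBands[[b]]@data, pseudo, bases, K)
    P <- aspAlign(spatialPattern(cbind(bands[[b]]$w1s)),
                  spatialPattern(cbind(w2s)))
    bands[[b]]$w2s <- w2s
    rA <- alphaAspScores(tgtBands[[b]], bands[[b]], K)
    # sign consensus: the raw subspace correlation at the pseudo-labelled
    # class should be positive on average
    s <- sign(mean(rA[cbind(seq_along(pseudo), pseudo)]))
    if (s == 0) s <- as.numeric(P)
    bands[[b]]$signA <- s
    aspTgt[[b]] <- s * rA
    maps[[b]] <- new("AlignmentMaps", P = list(shared = P),
                     Qc = bands[[b]]$Qc, Cs = bands[[b]]$Cs,
                     Ct = bands[[b]]$Ct)
  }
  model <- new("AlphaModel", design = design, fb = fb, fs = source@fs,
               nSamples = as.integer(N), bands = bands, maps = maps,
               signedSubbands = signedSubbands)
  list(model = model, stage1 = stage1, aspTgt = aspTgt, pseudo = pseudo,
       tgtBands = tgtBands)
}

# per-band pooled score matrices (all feature families) for decomposed
# test bands
alphaScoreBands <- function(testBands, model) {
  K <- nTargets(model@design)
  lapply(seq_along(testBands), function(b) {
    bd <- model@bands[[b]]
    S <- alphaStage1Scores(testBands[[b]], bd, K)
    rA <- bd$signA * alphaAspScores(testBands[[b]], bd, K)
    S + sign(rA) * rA^2
  })
}

#' Classify trials with a fitted ALPHA model
#'
#' Per sub-band and class, pools (by the sign-preserving squared sum) the
#' CORAL-aligned template correlations, the training-free canonical
#' correlation with the class reference, and the aligned-subspace template
#' correlation; sub-bands are fused with the filter-bank weights and the
#' argmax class returned (lowest index on ties).
#'
#' @param test an [EpochSet-class] of (windowed) target-domain trials.
#' @param model an [AlphaModel-class].
#' @return integer predictions with the fused score matrix as attribute
#'   \code{"scores"}.
#' @export
alphaClassify <- function(test, model) {
  if (nSamples(test) != model@nSamples)
    stop("test window length differs from the fitted model")
  testBands <- filterbankDecompose(test, model@fb)
  perBand <- alphaScoreBands(testBands, model)
  fused <- fuseBandScores(perBand, model@fb, model@signedSubbands)
  pred <- apply(fused, 1, which.max)
  structure(as.integer(pred), scores = fused)
}

# end-to-end pipeline when the unlabelled target trials are the test
# trials themselves: reuses the stage-1 scores computed during the fit
alphaPipeline <- function(source, test, design, fb, nHarmonics = NULL,
                          signedSubbands = TRUE, srcBands = NULL,
                          tgtBands = NULL) {
  core <- alphaFitCore(source, test, design, fb, nHarmonics,
                       signedSubbands, srcBands, tgtBands)
  perBand <- lapply(seq_along(core$stage1), function(b) {
    rA <- core$aspTgt[[b]]
    core$stage1[[b]] + sign(rA) * rA^2
  })
  fused <- fuseBandScores(perBand, fb, signedSubbands)
  pred <- apply(fused, 1, which.max)
  structure(as.integer(pred), scores = fused, model = core$model)
}
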