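# Batched scoring primitives shared by the template-based decoders.  These
# avoid per-(trial, class) recomputation of trial-side Cholesky factors and
# vectorise the many short Pearson correlations the score functions need.

# Pearson correlation of two vectors without dispatch overhead
fastCorVec <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# column-wise Pearson correlations of two equally-shaped matrices
batchColCor <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  den <- sqrt(colSums(A^2) * colSums(B^2))
  r <- colSums(A * B)
  ifelse(den == 0, 0, r / den)
}

# canonical correlations of one centred trial against K stacked reference
# bases (Qyall = cbind of K orthonormal bases with m columns each)
batchCcaRho <- function(Xc, Qyall, m, K) {
  cx <- cholRidge(tcrossprod(Xc))
  M <- backsolve(cx$R, Xc %*% Qyall, transpose = TRUE)
  vapply(seq_len(K), function(k) {
    Mk <- M[, (k - 1L) * m + seq_len(m), drop = FALSE]
    d2 <- eigen(tcrossprod(Mk), symmetric = TRUE, only.values = TRUE)$values[1]
    min(sqrt(max(d2, 0)), 1)
  }, numeric(1))
}

# as batchCcaRho but also returns the leading trial-side filters (C x K)
batchCcaRhoFilters <- function(Xc, Qyall, m, K) {
  cx <- cholRidge(tcrossprod(Xc))
  M <- backsolve(cx$R, Xc %*% Qyall, transpose = TRUE)
  rho <- numeric(K)
  Wx <- matrix(0, nrow(Xc), K)
  for (k in seq_len(K)) {
    Mk <- M[, (k - 1L) * m + seq_len(m), drop = FALSE]
    sv <- svd(Mk, nu = 1, nv = 0)
    rho[k] <- min(max(sv$d[1], 0), 1)
    Wx[, k] <- fixSign(backsolve(cx$R, sv$u[, 1]))
  }
  list(rho = rho, Wx = Wx)
}

# batch eCCA/ttCCA classification over an epoch set with optional filter
# bank; the engine behind the high-level decoders
eccaClassifyEpochs <- function(test, templates, design, fb = NULL,
                               nHarmonics = NULL,
                               signed = TRUE, testBands = NULL) {
  if (is.null(testBands))
    testBands <- if (is.null(fb)) list(test) else filterbankDecompose(test, fb)
  K <- length(templates[[1]]@classes)
  n <- nTrials(test)
  C <- nChannels(test)
  N <- nSamples(test)
  refs <- referenceSet(design, test@fs, N, nHarmonics)
  bases <- lapply(refs, refBasis)
  Qyall <- do.call(cbind, bases)
  m <- ncol(bases[[1]])
  nb <- length(testBands)
  perBand <- vector("list", nb)
  for (b in seq_len(nb)) {
    tmpl <- templates[[min(b, length(templates))]]
    Tc <- lapply(tmpl@templates, rowCenter)
    W1 <- vapply(seq_len(K), function(k)
      suppressWarnings(ccaDecomp(Tc[[k]], refs[[k]])$wx), numeric(C))
    P1 <- vapply(seq_len(K), function(k)
      as.numeric(crossprod(Tc[[k]], W1[, k])), numeric(N))
    S <- matrix(0, n, K)
    for (i in seq_len(n)) {
      Xc <- rowCenter(testBands[[b]]@data[i, , ])
      cc <- batchCcaRhoFilters(Xc, Qyall, m, K)
      # r1: trial and template through the template-reference filter
      r1 <- batchColCor(crossprod(Xc, W1), P1)
      # r2: trial and template through the trial-reference filter
      PX2 <- crossprod(Xc, cc$Wx)
      r2 <- vapply(seq_len(K), function(k)
        fastCorVec(PX2[, k], as.numeric(crossprod(Tc[[k]], cc$Wx[, k]))),
        numeric(1))
      S[i, ] <- sign(r1) * r1^2 + sign(r2) * r2^2 + sign(cc$rho) * cc$rho^2
    }
    perBand[[b]] <- S
  }
  scores <- if (nb == 1L && is.null(fb)) perBand[[1]] else {
    fused <- matrix(0, n, K)
    for (i in seq_len(n))
      fused[i, ] <- combineSubbands(lapply(perBand, function(S) S[i, ]),
                                    fb, signed = signed)
    fused
  }
  pred <- apply(scores, 1, which.max)
  structure(as.integer(pred), scores = scores)
}
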