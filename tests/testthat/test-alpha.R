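# Subspace alignment operators (patterns, Procrustes, CORAL) and the
# align-and-pool decoder.

test_that("spatial patterns invert the filter matrix", {
  expect_equal(spatialPattern(diag(4)), diag(4))
  Q <- randomOrthogonal(4)
  expect_equal(spatialPattern(Q), Q, tolerance = 1e-10)
  set.seed(1)
  W <- matrix(rnorm(16), 4)
  A <- spatialPattern(W)
  expect_lt(max(abs(crossprod(W, A) - diag(4))), 1e-10)
})

test_that("Procrustes alignment recovers planted rotations optimally", {
  set.seed(2)
  A1 <- matrix(rnorm(8 * 3), 8)
  expect_lt(max(abs(aspAlign(A1, A1) - diag(3))), 1e-10)

  R <- randomOrthogonal(3)
  A2 <- A1 %*% R
  P <- aspAlign(A1, A2)
  expect_lt(norm(A1 - A2 %*% t(P), "F"), 1e-8)
  expect_lt(max(abs(tcrossprod(P) - diag(3))), 1e-10)

  # optimality against 1000 random orthogonal maps on a noisy instance
  A2n <- A1 %*% R + 0.3 * matrix(rnorm(24), 8)
  Pn <- aspAlign(A1, A2n)
  obj <- function(M) norm(A1 - A2n %*% t(M), "F")
  best <- obj(Pn)
  rand <- replicate(1000, obj(randomOrthogonal(3)))
  expect_true(all(best <= rand + 1e-12))

  expect_error(aspAlign(matrix(0, 4, 2), matrix(0, 4, 2)), "degenerate")
  expect_error(aspAlign(A1, A1[, 1:2]), "same shape")
})

test_that("applying the Procrustes map is an isometry", {
  set.seed(3)
  W2 <- matrix(rnorm(8 * 3), 8)
  P <- randomOrthogonal(3)
  expect_equal(applyAsp(W2, diag(3)), W2)
  expect_equal(norm(applyAsp(W2, P), "F"), norm(W2, "F"), tolerance = 1e-10)
  # square case: pattern of the aligned filter is the aligned pattern
  Wsq <- matrix(rnorm(9), 3)
  Psq <- randomOrthogonal(3)
  expect_equal(spatialPattern(applyAsp(Wsq, Psq)),
               spatialPattern(Wsq) %*% t(Psq), tolerance = 1e-8)
})

test_that("class covariances match the textbook sample covariance", {
  set.seed(4)
  X <- matrix(rnorm(4 * 100), 4)
  eps <- epochsFromMatrix(X, labels = 1L)
  cc <- classCovariances(eps, eps)
  expect_equal(cc$Cs[["1"]], cov(t(X)), tolerance = 1e-10)
  expect_equal(cc$Ct, cov(t(X)), tolerance = 1e-10)
  expect_lt(max(abs(cc$Ct - t(cc$Ct))), 1e-12)
  expect_true(min(eigen(cc$Ct, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-12)

  const <- epochsFromMatrix(matrix(5, 3, 50), labels = 1L)
  expect_lt(max(abs(classCovariances(const, const)$Ct)), 1e-12)
})

test_that("the CORAL map matches second moments exactly", {
  expect_equal(coralMap(diag(3), diag(3)), diag(3), tolerance = 1e-10)
  set.seed(5)
  Ct <- randomSPD(3)
  expect_equal(coralMap(diag(3), Ct), ssvepAlign:::symmPower(Ct, 0.5),
               tolerance = 1e-8)
  for (rep in 1:3) {
    Cs <- randomSPD(8); Ct <- randomSPD(8)
    Q <- coralMap(Cs, Ct)
    expect_lt(norm(t(Q) %*% Cs %*% Q - Ct, "F"), 1e-8)
  }
  bad <- matrix(rnorm(9), 3)
  expect_error(coralMap(bad, diag(3)), "symmetric")
})

test_that("applyCoral is linear and shape-checked", {
  set.seed(6)
  W <- matrix(rnorm(12), 4)
  Qc <- randomSPD(4)
  expect_equal(applyCoral(W, diag(4)), W)
  expect_equal(applyCoral(2.5 * W, Qc), 2.5 * applyCoral(W, Qc))
  expect_error(applyCoral(matrix(0, 3, 2), Qc), "shape mismatch")
})

test_that("alpha fitting is deterministic and classifies the degenerate
           transfer like eCCA", {
  des <- smallDesign(K = 6, step = 0.8)
  prof <- smallProfile(C = 4, amp = 1.2)
  eps <- simulateEpochs(prof, des, 4, 1, 250, seed = 7)
  fb1 <- makeFilterBankSpec(1)
  m1 <- alphaFit(eps, eps, des, fb1)
  m2 <- alphaFit(eps, eps, des, fb1)
  expect_equal(m1@bands[[1]]$WBall, m2@bands[[1]]$WBall)
  expect_equal(m1@bands[[1]]$w2s, m2@bands[[1]]$w2s)
  p1 <- alphaClassify(eps, m1)
  p2 <- alphaClassify(eps, m2)
  expect_identical(as.integer(p1), as.integer(p2))

  # target = source: alpha and ecca agree almost everywhere at an SNR
  # where ecca is strong
  test <- simulateEpochs(prof, des, 2, 1, 250, seed = 8)
  eccaPred <- decodeTransfer("ecca", eps, test, des)
  alphaPred <- decodeTransfer("alpha", eps, test, des)
  expect_gte(mean(eccaPred == epochLabels(test)), 0.9)
  expect_gte(mean(alphaPred == eccaPred), 0.95)

  expect_error(alphaFit(eps, eps[integer(0)], des, fb1), "empty target")
})

test_that("alpha recovers a planted rotation that degrades ttCCA", {
  des <- smallDesign(K = 8, step = 0.8)
  prof <- smallProfile(C = 6, amp = 0.55, nh = 3)
  R <- makeRotation(6, 0.8, seed = 20)
  dom <- makeDomainSpec(2, "dry", R, 2, 1, 6)
  src <- simulateEpochs(prof, des, 6, 1, 250, seed = 21)
  tgt <- simulateEpochs(applyDomainShift(prof, dom), des, 6, 1, 250,
                        seed = 22, day = 2, electrodeType = "dry")
  fb1 <- makeFilterBankSpec(2)
  lab <- epochLabels(tgt)
  ttccaAcc <- mean(decodeTransfer("ttcca", src, tgt, des, fb1) == lab)
  alphaAcc <- mean(decodeTransfer("alpha", src, tgt, des, fb1) == lab)
  expect_gt(alphaAcc, ttccaAcc)
})

test_that("alpha predictions survive a consistent channel permutation", {
  des <- smallDesign(K = 5, step = 0.9)
  prof <- smallProfile(C = 4, amp = 0.8)
  src <- simulateEpochs(prof, des, 3, 0.8, 250, seed = 23)
  tgt <- simulateEpochs(prof, des, 2, 0.8, 250, seed = 24)
  p <- c(4, 2, 1, 3)
  permute <- function(e) { e@data <- e@data[, p, , drop = FALSE]; e }
  fb1 <- makeFilterBankSpec(1)
  a <- decodeTransfer("alpha", src, tgt, des, fb1)
  b <- decodeTransfer("alpha", permute(src), permute(tgt), des, fb1)
  expect_identical(as.integer(a), as.integer(b))
})
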