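# Template building, eCCA/ttCCA scoring, TRCA training and classification.

test_that("templates are class means over training trials", {
  des <- smallDesign(K = 3)
  prof <- smallProfile()
  one <- simulateEpochs(prof, des, 1, 0.6, 250, seed = 1)
  tl <- buildTemplates(one)
  expect_equal(tl@templates[[2]], epochData(one)[2, , ])

  two <- combineEpochSets(list(one, one))
  tl2 <- buildTemplates(two)
  expect_equal(tl2@templates[[1]], tl@templates[[1]])

  short <- one[epochLabels(one) != 2]
  expect_error(buildTemplates(short, nClasses = 3), "incomplete training")
})

test_that("template averaging shrinks white-noise variance like 1/Nb", {
  set.seed(11)
  ratios <- replicate(100, {
    eps <- epochsFromMatrix(lapply(1:8, function(i) matrix(rnorm(2 * 50), 2)),
                            labels = 1L)
    tl <- buildTemplates(eps)
    var(as.numeric(tl@templates[[1]])) /
      mean(apply(epochData(eps), 1, function(m) var(as.numeric(m))))
  })
  expect_equal(mean(ratios), 1 / 8, tolerance = 0.2)
})

test_that("the sign-preserving squared sum pools features as specified", {
  sss <- ssvepAlign:::signedSquareSum
  expect_equal(sss(c(1, 1, 1)), 3)
  expect_equal(sss(c(-0.5, 0, 0.5)), 0)
  expect_equal(sss(c(-1, 0.5)), -0.75)
})

test_that("eCCA scores its own template perfectly and ttCCA degenerates", {
  des <- smallDesign(K = 3)
  prof <- smallProfile()
  train <- simulateEpochs(prof, des, 4, 0.8, 250, seed = 2)
  tl <- buildTemplates(train)
  refs <- ssvepAlign:::referenceSet(des, 250, nSamples(train))
  sc <- eccaScore(tl@templates[[2]], tl, refs)
  feats <- attr(sc, "features")
  expect_equal(feats[2, 1], 1, tolerance = 1e-8)
  expect_equal(feats[2, 2], 1, tolerance = 1e-8)
  expect_equal(which.max(sc), 2L)

  expect_warning(
    sc2 <- ttccaScore(tl@templates[[2]], tl, refs,
                      testDomain = list(day = 1L, electrode = "wet")),
    "degenerates")
  expect_equal(as.numeric(sc2), as.numeric(sc))

  emptyTl <- new("TemplateSet", templates = list(), classes = integer(),
                 domain = list(), nTrainingBlocks = 0L)
  expect_error(eccaScore(tl@templates[[1]], emptyTl, refs), "empty")
})

test_that("TRCA solves the Rayleigh problem and recovers planted sources", {
  des <- smallDesign(K = 2)
  prof <- smallProfile()
  train <- simulateEpochs(prof, des, 5, 0.8, 250, seed = 3)
  model <- trcaTrain(train)
  expect_equal(sqrt(colSums(model@filters^2)), rep(1, 2), tolerance = 1e-8)
  # returned filter attains the leading generalised eigenvalue
  for (k in 1:2) {
    S <- model@covariances[[k]]$S
    Q <- model@covariances[[k]]$Q
    w <- model@filters[, k]
    lam <- as.numeric((t(w) %*% S %*% w) / (t(w) %*% Q %*% w))
    ev <- eigen(solve(Q, S), only.values = TRUE)$values
    expect_lt(abs(lam - max(Re(ev))), 1e-8)
  }

  # planted shared component at 0 dB total SNR, 10 trials
  set.seed(7)
  C <- 6; N <- 400
  a <- rnorm(C); a <- a / sqrt(sum(a^2))
  s <- sin(2 * pi * 11 * seq_len(N) / 250) * sqrt(2)   # unit variance
  sigma <- 1 / sqrt(C)                                  # 0 dB total
  trials <- lapply(1:10, function(i)
    outer(a, s) + matrix(rnorm(C * N, sd = sigma), C))
  eps <- epochsFromMatrix(trials, labels = 1L)
  m1 <- trcaTrain(eps, 1)
  Q <- m1@covariances[[1]]$Q
  w <- m1@filters[, 1]
  # cosine between filter and planted direction in the Q-whitened space
  cosang <- abs(sum(w * a)) /
    sqrt(as.numeric(t(w) %*% Q %*% w) * as.numeric(t(a) %*% solve(Q, a)))
  expect_gt(cosang, 0.95)

  one <- train[epochBlocks(train) == 1]
  expect_error(trcaTrain(one), "insufficient trials")
})

test_that("TRCA training is invariant to trial order", {
  des <- smallDesign(K = 2)
  train <- simulateEpochs(smallProfile(), des, 4, 0.6, 250, seed = 4)
  perm <- rev(seq_len(nTrials(train)))
  m1 <- trcaTrain(train)
  m2 <- trcaTrain(train[perm])
  expect_equal(m1@filters, m2@filters, tolerance = 1e-10)
})

test_that("TRCA classification: self-match, noiseless ceiling, permutation", {
  des <- smallDesign(K = 8, step = 0.8)
  prof <- quietProfile(C = 4)
  train <- simulateEpochs(prof, des, 3, 1, 250, seed = 5)
  test <- simulateEpochs(prof, des, 3, 1, 250, seed = 6)
  model <- suppressWarnings(trcaTrain(train))
  # template of class k classifies as k
  tmplEps <- epochsFromMatrix(model@templates@templates, labels = 1L)
  tmplEps@labels <- model@classes
  expect_equal(as.integer(trcaClassify(tmplEps, model)),
               as.integer(model@classes))
  # noiseless simulation decodes perfectly
  expect_equal(mean(trcaClassify(test, model) == epochLabels(test)), 1)

  # consistent channel permutation leaves predictions unchanged
  p <- c(3, 1, 4, 2)
  permEps <- test
  permEps@data <- test@data[, p, , drop = FALSE]
  permModel <- model
  permModel@filters <- model@filters[p, ]
  permModel@templates@templates <-
    lapply(model@templates@templates, function(m) m[p, ])
  expect_equal(as.integer(trcaClassify(permEps, permModel)),
               as.integer(trcaClassify(test, model)))
})

test_that("CCA classification: noiseless hit, tie-break, FB consistency", {
  des <- smallDesign(K = 8, step = 0.8)
  prof <- quietProfile(C = 4)
  eps <- simulateEpochs(prof, des, 1, 1, 250, seed = 8)
  pred <- ccaClassify(eps, des)
  expect_equal(as.integer(pred), epochLabels(eps))
  expect_equal(pred[7], epochLabels(eps)[7])  # class 7 decodes as 7

  # identical classes (zero frequency step) tie exactly -> lowest index
  tieDesign <- makeStimulusDesign(3, 10, 0, 0, 0, 2)
  predTie <- ccaClassify(eps[1:3], tieDesign)
  expect_equal(as.integer(predTie), rep(1L, 3))

  # one-band filter bank preserves the plain-CCA ranking
  fb1 <- makeFilterBankSpec(1)
  noisy <- simulateEpochs(smallProfile(C = 4), des, 1, 1, 250, seed = 9)
  plain <- ccaClassify(noisy, des)
  banked <- ccaClassify(noisy, des, fb1)
  expect_equal(as.integer(banked), as.integer(plain))
})

test_that("transferred templates under rotation lose accuracy vs eCCA", {
  des <- smallDesign(K = 10, step = 0.8)
  prof <- smallProfile(C = 8, amp = 0.6)
  R <- makeRotation(8, 0.8, seed = 10)
  dom <- makeDomainSpec(2, "dry", R, 1, 1, 8)
  src <- simulateEpochs(prof, des, 6, 1, 250, seed = 11)
  tgtProf <- applyDomainShift(prof, dom)
  tgt <- simulateEpochs(tgtProf, des, 6, 1, 250, seed = 12,
                        day = 2, electrodeType = "dry")
  tgtTrain <- tgt[epochBlocks(tgt) <= 3]
  tgtTest <- tgt[epochBlocks(tgt) > 3]
  eccaAcc <- mean(decodeTransfer("ecca", tgtTrain, tgtTest, des) ==
                    epochLabels(tgtTest))
  ttccaAcc <- mean(decodeTransfer("ttcca", src, tgtTest, des) ==
                     epochLabels(tgtTest))
  expect_lt(ttccaAcc, eccaAcc)
})

test_that("supervised decoders are at chance on label-shuffled data", {
  des <- smallDesign(K = 6)
  prof <- smallProfile(C = 4, amp = 0.8)
  eps <- simulateEpochs(prof, des, 10, 0.6, 250, seed = 13)
  shuffled <- eps
  set.seed(14)
  shuffled@labels <- sample(eps@labels)
  train <- shuffled[epochBlocks(shuffled) <= 8]
  test <- shuffled[epochBlocks(shuffled) > 8]
  chance <- 1 / 6
  se <- sqrt(chance * (1 - chance) / nTrials(test))
  for (m in c("ecca", "trca")) {
    acc <- mean(suppressWarnings(
      decodeTransfer(m, train, test, des)) == epochLabels(test))
    expect_lt(acc, chance + 3 * se + 1e-9)
  }
})
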