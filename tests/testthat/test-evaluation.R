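# Evaluation protocols: directions, cross-validation, ITR, curves,
# similarity analyses, t-test and summary tables.

test_that("transfer-direction enumeration matches the protocol", {
  cross <- enumerateDirections(3, "cross", c("wet", "dry"))
  expect_equal(nrow(cross), 6L)
  expect_true(all(cross$sourceDay != cross$targetDay))
  expect_true(all(cross$type == "f"))

  within <- enumerateDirections(3, "within", c("wet", "dry"))
  expect_equal(nrow(within), 3L)
  expect_true(all(within$type == "c"))

  ww <- enumerateDirections(3, "cross", c("wet", "wet"))
  expect_true(all(ww$type == "d"))
  dd <- enumerateDirections(2, "cross", c("dry", "dry"))
  expect_true(all(dd$type == "e"))

  expect_warning(none <- enumerateDirections(1, "cross"), "at least 2")
  expect_equal(nrow(none), 0L)
})

test_that("leave-one-block-out cross-validation is block-deterministic", {
  des <- smallDesign(K = 5, step = 0.9)
  prof <- quietProfile(C = 4)
  eps <- simulateEpochs(prof, des, 6, 1, 250, seed = 1)
  acc <- crossvalSupervised("trca", eps, des, length = 0.6, latency = 0.1)
  expect_length(acc, 6L)
  expect_equal(acc, rep(100, 6))  # noiseless decoder is perfect
  acc2 <- crossvalSupervised("trca", eps, des, length = 0.6, latency = 0.1)
  expect_identical(acc, acc2)
  one <- eps[epochBlocks(eps) == 1]
  expect_error(crossvalSupervised("trca", one, des), ">= 2 blocks")
})

test_that("the information transfer rate follows the selection-time formula", {
  expect_equal(itr(1, 40, 1.2, 1), 60 * log2(40) / 2.2, tolerance = 1e-12)
  expect_equal(itr(1 / 40, 40, 1.2, 1), 0)
  expect_equal(itr(0.01, 40, 1.2, 1), 0)  # below chance clamps to zero
  # strictly increasing above chance
  p <- seq(1 / 40 + 1e-3, 1, by = 1e-3)
  v <- itr(p, 40, 1.2, 1)
  expect_true(all(diff(v) > 0))
  expect_error(itr(0.5, 1, 1.2), "Nf")
  expect_error(itr(1.2, 40, 1.2), "\\[0, 1\\]")
})

test_that("transfer evaluation reports accuracy and ITR per data length", {
  des <- smallDesign(K = 5, step = 0.9)
  prof <- quietProfile(C = 4)
  src <- simulateEpochs(prof, des, 2, 1.2, 250, seed = 2)
  tgt <- simulateEpochs(prof, des, 2, 1.2, 250, seed = 3)
  rep <- evaluateTransfer("trca", src, tgt, c(0.4, 0.8), des,
                          latency = 0.1, subject = "S1")
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$accuracyPct >= 0 & rep$accuracyPct <= 100))
  expect_true(all(rep$itrBpm >= 0))
  expect_equal(rep$accuracyPct, c(100, 100))
  expect_error(evaluateTransfer("trca", src, tgt, 5, des), "bounds error")
})

test_that("training-block curves subsample blocks reproducibly", {
  des <- smallDesign(K = 4, step = 1.0)
  prof <- smallProfile(C = 4, amp = 0.9)
  src <- simulateEpochs(prof, des, 6, 1, 250, seed = 4)
  tgt <- simulateEpochs(prof, des, 6, 1, 250, seed = 5)
  cv <- trainingBlockCurve("trca", src, tgt, des, nBlocksGrid = 2:3,
                           repeats = 3, seed = 9, length = 0.8,
                           latency = 0.1)
  expect_equal(cv$nTrainingBlocks, 2:3)
  cv2 <- trainingBlockCurve("trca", src, tgt, des, nBlocksGrid = 2:3,
                            repeats = 3, seed = 9, length = 0.8,
                            latency = 0.1)
  expect_identical(cv, cv2)
  expect_error(trainingBlockCurve("trca", src, tgt, des,
                                  nBlocksGrid = 2:7, seed = 1),
               "more training blocks")
  expect_error(trainingBlockCurve("trca", src, tgt, des), "seed")
})

test_that("amplitude topographies reflect the mixing pattern", {
  des <- smallDesign(K = 4, step = 1.0)
  prof <- quietProfile(C = 5)
  eps <- simulateEpochs(prof, des, 2, 2, 250, seed = 6)
  v <- amplitudeTopography(eps, 1, des)
  expect_equal(max(v), 1)
  p <- abs(prof@spatialPattern) / max(abs(prof@spatialPattern))
  expect_equal(v, p, tolerance = 1e-2)
  # duplicated block data give identical vectors
  dup <- eps
  dup@data[epochBlocks(eps) == 2, , ] <- eps@data[epochBlocks(eps) == 1, , ]
  expect_equal(amplitudeTopography(dup, 2, des),
               amplitudeTopography(dup, 1, des))
  expect_error(amplitudeTopography(eps, 9, des), "block not present")
})

test_that("similarity matrices bucket block pairs by domain relation", {
  set.seed(7)
  blocks <- lapply(1:4, function(i) rnorm(8))
  meta <- data.frame(day = c(1, 1, 2, 2),
                     electrode = c("wet", "dry", "wet", "dry"))
  sim <- similarityMatrix(blocks, meta)
  expect_equal(diag(sim$matrix), rep(1, 4))
  expect_equal(sim$matrix, t(sim$matrix))
  types <- sim$pairs$pairType[order(sim$pairs$blockA, sim$pairs$blockB)]
  expect_equal(types, c("WDCE", "CDWE", "CDCE", "CDCE", "CDWE", "WDCE"))
  expect_true(all(abs(sim$pairs$similarity) <= 1))
  # covariance-matrix variant uses the vectorised upper triangle
  mats <- lapply(1:3, function(i) randomSPD(4))
  simM <- similarityMatrix(mats, data.frame(day = c(1, 1, 2),
                                            electrode = rep("wet", 3)))
  expect_equal(dim(simM$matrix), c(3L, 3L))
  expect_error(similarityMatrix(blocks[1], meta[1, , drop = FALSE]),
               "at least 2")
})

test_that("the paired t-test matches the textbook formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pairedTTest(x, x), list(t = 0, p = 1, df = 3L,
                                       degenerate = FALSE))
  set.seed(8)
  a <- rnorm(12); b <- rnorm(12)
  got <- pairedTTest(a, b)
  d <- a - b
  tManual <- mean(d) / (sd(d) / sqrt(12))
  pManual <- 2 * pt(-abs(tManual), 11)
  expect_equal(got$t, tManual, tolerance = 1e-10)
  expect_equal(got$p, pManual, tolerance = 1e-10)

  deg <- pairedTTest(c(2, 3, 4), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  expect_error(pairedTTest(1, 2), "at least 2")
  expect_error(pairedTTest(1:3, 1:4), "equal length")
})

test_that("summary tables emit mean, SD and SE rows per method", {
  rep <- data.frame(subject = rep(c("S1", "S2", "S3"), 2),
                    method = rep(c("alpha", "trca"), each = 3),
                    accuracyPct = c(80, 90, 100, 70, 80, 90),
                    itrBpm = c(100, 110, 120, 90, 100, 110))
  tab <- summarizeTable(rep)
  alphaMean <- tab[tab$method == "alpha" & tab$statistic == "Mean", ]
  expect_equal(alphaMean$accuracyPct, 90)
  alphaSD <- tab[tab$method == "alpha" & tab$statistic == "SD", ]
  expect_equal(alphaSD$accuracyPct, 10)
  alphaSE <- tab[tab$method == "alpha" & tab$statistic == "SE", ]
  expect_equal(alphaSE$accuracyPct, 10 / sqrt(3))

  single <- summarizeTable(rep[rep$subject == "S1" &
                                 rep$method == "alpha", ])
  expect_true(is.na(single$accuracyPct[single$statistic == "SD"]))
  expect_error(summarizeTable(rep[0, ]), "empty report")
})

test_that("reported accuracies equal the per-trial prediction fraction", {
  des <- smallDesign(K = 4, step = 1.0)
  prof <- smallProfile(C = 4, amp = 0.8)
  eps <- simulateEpochs(prof, des, 3, 1, 250, seed = 10)
  win <- extractWindow(eps, 0.14, 0.8)
  accs <- crossvalSupervised("trca", eps, des, length = 0.8)
  manual <- vapply(1:3, function(bl) {
    train <- win[epochBlocks(win) != bl]
    test <- win[epochBlocks(win) == bl]
    pred <- decodeTransfer("trca", train, test, des)
    100 * mean(pred == epochLabels(test))
  }, numeric(1))
  expect_equal(accs, manual)
})
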