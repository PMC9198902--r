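# Synthetic SSVEP generator: stimulus grid, domain shifts, forward model.

test_that("JFPM grid produces the expected frequencies and phases", {
  d <- makeStimulusDesign()
  f <- stimulusFrequencies(d)
  expect_equal(f[1], 8)
  expect_equal(f[40], 15.8)
  expect_equal(diff(f), rep(0.2, 39))
  ph <- stimulusPhases(d)
  expect_equal(ph[1:5], c(0, 0.5 * pi, pi, 1.5 * pi, 0), tolerance = 1e-12)
  expect_true(all(ph >= 0 & ph < 2 * pi))

  d1 <- makeStimulusDesign(nTargets = 1L)
  expect_equal(stimulusFrequencies(d1), 8)
  expect_equal(stimulusPhases(d1), 0)

  expect_error(makeStimulusDesign(baseFreq = 0), "invalid design")
})

test_that("domain shifts act on pattern, noise and amplitude as specified", {
  prof <- smallProfile(C = 4)
  identitySpec <- makeDomainSpec(nChannels = 4)
  same <- applyDomainShift(prof, identitySpec)
  expect_equal(same@spatialPattern, prof@spatialPattern)
  expect_equal(same@noiseCov, prof@noiseCov)
  expect_equal(same@signalAmp, prof@signalAmp)

  R <- makeRotation(4, 0.5, seed = 7)
  expect_lt(max(abs(crossprod(R) - diag(4))), 1e-10)
  rot <- applyDomainShift(prof, makeDomainSpec(rotation = R, noiseGain = 3))
  expect_equal(sqrt(sum(rot@spatialPattern^2)), 1, tolerance = 1e-10)
  expect_equal(sum(diag(rot@noiseCov)), 3 * sum(diag(prof@noiseCov)))

  expect_error(applyDomainShift(prof, makeDomainSpec(nChannels = 5)),
               "shape error")
})

test_that("simulation is seed-deterministic and seed is mandatory", {
  prof <- smallProfile()
  des <- smallDesign()
  a <- simulateEpochs(prof, des, 2, 0.6, 250, seed = 5)
  b <- simulateEpochs(prof, des, 2, 0.6, 250, seed = 5)
  expect_identical(epochData(a), epochData(b))
  expect_equal(nTrials(a), 2 * nTargets(des))
  c <- simulateEpochs(prof, des, 2, 0.6, 250, seed = 6)
  expect_false(identical(epochData(a), epochData(c)))
  expect_error(simulateEpochs(prof, des, 2, 0.6, 250), "seed")
})

test_that("noise-free trials peak at their stimulus frequency", {
  des <- smallDesign(K = 4, step = 1.5)
  prof <- quietProfile()
  eps <- simulateEpochs(prof, des, 1, 2, 250, seed = 1)
  freqs <- stimulusFrequencies(des)
  ch <- which.max(abs(prof@spatialPattern))
  for (i in seq_len(nTrials(eps))) {
    x <- epochData(eps)[i, ch, ]
    x <- x - mean(x)
    sp <- abs(stats::fft(x))[2:200]
    fpk <- (which.max(sp)) * 250 / length(x)
    expect_equal(fpk, freqs[epochLabels(eps)[i]], tolerance = 0.3)
  }
})

test_that("zero-noise channel amplitudes are proportional to the pattern", {
  des <- smallDesign(K = 3, step = 1.5)
  prof <- quietProfile(C = 5)
  eps <- simulateEpochs(prof, des, 1, 2, 250, seed = 2)
  i <- 1
  f <- stimulusFrequencies(des)[epochLabels(eps)[i]]
  amps <- vapply(1:5, function(ch)
    fftMag(epochData(eps)[i, ch, ], f, 250), numeric(1))
  a <- amps / max(amps)
  p <- abs(prof@spatialPattern) / max(abs(prof@spatialPattern))
  expect_equal(a, p, tolerance = 1e-3)
})

test_that("an orthogonal shift preserves per-trial signal power", {
  des <- smallDesign(K = 3, step = 1.5)
  prof <- quietProfile(C = 5)
  R <- makeRotation(5, 0.7, seed = 3)
  shifted <- applyDomainShift(prof, makeDomainSpec(rotation = R,
                                                   nChannels = 5))
  a <- simulateEpochs(prof, des, 1, 1, 250, seed = 4)
  b <- simulateEpochs(shifted, des, 1, 1, 250, seed = 4)
  pa <- apply(epochData(a), 1, function(m) sum(m^2))
  pb <- apply(epochData(b), 1, function(m) sum(m^2))
  expect_equal(pa, pb, tolerance = 1e-4)  # signal-noise cross terms differ
})

test_that("zero-amplitude signal yields chance-level CCA accuracy", {
  des <- smallDesign(K = 10, step = 0.5)
  prof <- smallProfile(C = 4, amp = 0)
  eps <- simulateEpochs(prof, des, 200, 0.5, 250, seed = 8)  # 2000 trials
  pred <- ccaClassify(eps, des)
  acc <- mean(pred == epochLabels(eps))
  chance <- 1 / 10
  se <- sqrt(chance * (1 - chance) / nTrials(eps))
  expect_lt(abs(acc - chance), 3 * se)
})
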