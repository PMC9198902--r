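# Shared fixtures: small designs and profiles keep the unit tests fast;
# wider frequency spacing keeps short windows separable.

smallDesign <- function(K = 6L, step = 1.0, nh = 3L)
  makeStimulusDesign(K, 8, step, 0, 0.5 * pi, nh)

smallProfile <- function(C = 4L, amp = 1, noiseScale = 1, nh = 3L) {
  makeSubjectProfile(nChannels = C, harmonicAmps = (seq_len(nh))^-1.25,
                     signalAmp = amp,
                     noiseCov = noiseScale *
                       ssvepAlign:::defaultNoiseCov(C))
}

# nearly noiseless profile (validity requires SPD noise)
quietProfile <- function(C = 4L, amp = 1, nh = 3L)
  smallProfile(C, amp, noiseScale = 1e-8, nh = nh)

# an EpochSet wrapping one or more channels x samples matrices
epochsFromMatrix <- function(X, fs = 250, labels = 1L) {
  if (is.matrix(X)) X <- list(X)
  data <- array(0, c(length(X), nrow(X[[1]]), ncol(X[[1]])))
  for (i in seq_along(X)) data[i, , ] <- X[[i]]
  new("EpochSet", data = data, fs = fs,
      labels = rep(as.integer(labels), length.out = length(X)),
      block = seq_along(X), day = rep(1L, length(X)),
      electrode = rep("wet", length(X)), onsetIndex = 1L)
}

# spectral magnitude of a vector at frequency f
fftMag <- function(x, f, fs) {
  n <- length(x)
  abs(stats::fft(x))[round(f * n / fs) + 1]
}

randomOrthogonal <- function(d) {
  qr.Q(qr(matrix(rnorm(d * d), d)))
}

randomSPD <- function(d) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(d)
}
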