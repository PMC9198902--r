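# Zero-phase IIR filtering helpers.  Coefficients come from signal::butter
# (band-pass) and the standard constant-Q biquad design (notch); the
# forward-backward recursion itself runs in compiled code on whole matrices
# (time down the rows, one series per column) so that entire epoch sets can
# be filtered in a single call.

butterBandpass <- function(low, high, fs, order = 4L) {
  ny <- fs / 2
  if (high >= ny) stop("band edge at or above Nyquist")
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  list(b = bf$b, a = bf$a)
}

# constant-Q notch biquad (zeros on the unit circle at f0)
notchBiquad <- function(f0, fs, Q = 35) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * Q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + al),
       a = c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al)))
}

# zero-phase filtering of every column of X with odd-reflection padding
filtfiltMat <- function(coef, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  ord <- max(length(coef$a), length(coef$b)) - 1L
  pad <- min(n - 1L, 12L * ord)
  if (n <= ord * 3L)
    stop("too short: epoch shorter than the filter warm-up")
  pre  <- 2 * X[rep(1L, pad), , drop = FALSE] -
    X[pad + 1L - seq_len(pad), , drop = FALSE]
  post <- 2 * X[rep(n, pad), , drop = FALSE] -
    X[n - seq_len(pad), , drop = FALSE]
  Y <- iir_filter_mat(coef$b, coef$a, rbind(pre, X, post))
  Y <- iir_filter_mat(coef$b, coef$a, Y[nrow(Y):1, , drop = FALSE])
  Y[nrow(Y):1, , drop = FALSE][pad + seq_len(n), , drop = FALSE]
}

# apply a zero-phase filter to a trials x channels x samples array
filterEpochArray <- function(data, coef) {
  d <- dim(data)
  # samples x (trials*channels) matrix: one column per (trial, channel)
  X <- matrix(aperm(data, c(3, 1, 2)), nrow = d[3])
  Y <- filtfiltMat(coef, X)
  aperm(array(Y, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
}
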