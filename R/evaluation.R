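# Transfer evaluation protocols: direction enumeration, cross-validation,
# accuracy / information-transfer-rate metrics, training-block curves,
# similarity analyses, the planned paired t-test, and summary tables.

transferType <- function(sourceDay, sourceElectrode, targetDay,
                         targetElectrode) {
  within <- sourceDay == targetDay
  if (within) {
    if (sourceElectrode == "wet" && targetElectrode == "wet") return("a")
    if (sourceElectrode == "dry" && targetElectrode == "dry") return("b")
    if (sourceElectrode == "wet" && targetElectrode == "dry") return("c")
  } else {
    if (sourceElectrode == "wet" && targetElectrode == "wet") return("d")
    if (sourceElectrode == "dry" && targetElectrode == "dry") return("e")
    if (sourceElectrode == "wet" && targetElectrode == "dry") return("f")
  }
  NA_character_
}

#' Enumerate transfer directions
#'
#' Cross-day mode yields every ordered pair of distinct days (6 directions
#' for 3 days); within-day mode yields one task per day.  Each task is
#' annotated with its transfer type: a/b (within-day wet/dry, no transfer),
#' c (within-day wet-to-dry), d (cross-day wet-to-wet), e (cross-day
#' dry-to-dry), f (cross-day wet-to-dry).
#'
#' @param days number of recording days.
#' @param mode \code{"cross"} or \code{"within"}.
#' @param electrodePair length-2 character vector (source, target)
#'   electrode types.
#' @return data.frame with columns sourceDay, sourceElectrode, targetDay,
#'   targetElectrode, type.
#' @export
enumerateDirections <- function(days, mode = c("cross", "within"),
                                electrodePair = c("wet", "dry")) {
  mode <- match.arg(mode)
  stopifnot(length(electrodePair) == 2L)
  if (mode == "cross") {
    if (days < 2L) {
      warning("cross-day enumeration needs at least 2 days; returning empty")
      return(data.frame(sourceDay = integer(), sourceElectrode = character(),
                        targetDay = integer(), targetElectrode = character(),
                        type = character()))
    }
    grid <- expand.grid(sourceDay = seq_len(days), targetDay = seq_len(days))
    grid <- grid[grid$sourceDay != grid$targetDay, ]
  } else {
    grid <- data.frame(sourceDay = seq_len(days), targetDay = seq_len(days))
  }
  out <- data.frame(sourceDay = grid$sourceDay,
                    sourceElectrode = electrodePair[1],
                    targetDay = grid$targetDay,
                    targetElectrode = electrodePair[2],
                    stringsAsFactors = FALSE)
  out$type <- mapply(transferType, out$sourceDay, out$sourceElectrode,
                     out$targetDay, out$targetElectrode)
  rownames(out) <- NULL
  out
}

#' Information transfer rate of an Nf-class selection task
#'
#' Wolpaw-style throughput in bits/min from the identification accuracy P,
#' the class count and the selection time T = stimulus length + gaze-shift
#' time.  Accuracies at or below chance (1/Nf) return 0 (the formula is
#' negative or undefined there); P = 1 is handled by its analytic limit.
#'
#' @param P identification accuracy as a proportion in \[0, 1\].
#' @param Nf number of classes (>= 2).
#' @param stimLen stimulus (data) length (s).
#' @param gazeShift gaze-shifting time added to the selection time (s).
#' @return information transfer rate (bits/min).
#' @examples
#' itr(1, 40, 1.2)  # 60 * log2(40) / 2.2
#' @export
itr <- function(P, Nf, stimLen, gazeShift = 1) {
  if (Nf < 2) stop("Nf must be >= 2")
  if (any(P < 0 | P > 1)) stop("P must lie in [0, 1]")
  T <- stimLen + gazeShift
  vapply(P, function(p) {
    if (p <= 1 / Nf) return(0)
    bits <- if (p >= 1) log2(Nf)
    else log2(Nf) + p * log2(p) + (1 - p) * log2((1 - p) / (Nf - 1))
    max(bits, 0) * 60 / T
  }, numeric(1))
}

#' Leave-one-block-out cross-validation of a supervised decoder
#'
#' Fold f trains on all blocks except block f and tests on block f (the
#' six-fold protocol when the session has six blocks).
#'
#' @param method decoder name (see [decodeTransfer()]).
#' @param epochs a labelled, preprocessed [EpochSet-class] (full epochs).
#' @param design a [StimulusDesign-class].
#' @param length decoding-window length (s).
#' @param fb optional [FilterBankSpec-class].
#' @param latency visual latency skipped before the window (s).
#' @return numeric vector of per-fold accuracies (percent), one per block.
#' @export
crossvalSupervised <- function(method, epochs, design, length = 1.2,
                               fb = NULL, latency = 0.14) {
  blocks <- sort(unique(epochs@block))
  if (base::length(blocks) < 2L) stop("cross-validation needs >= 2 blocks")
  win <- extractWindow(epochs, latency, length)
  bands <- if (is.null(fb)) NULL else filterbankDecompose(win, fb)
  vapply(blocks, function(bl) {
    train <- win[win@block != bl]
    test <- win[win@block == bl]
    pred <- decodeTransfer(method, train, test, design, fb,
                           srcBands = subsetBands(bands, win@block != bl),
                           testBands = subsetBands(bands, win@block == bl))
    100 * mean(pred == test@labels)
  }, numeric(1))
}

#' Evaluate a transfer direction over a grid of data lengths
#'
#' Trains on the full source session and classifies every target trial,
#' once per decoding-window length, recording accuracy and ITR.
#'
#' @param method decoder name (see [decodeTransfer()]).
#' @param source labelled source-domain [EpochSet-class] (full epochs).
#' @param target labelled target-domain [EpochSet-class] (full epochs).
#' @param lengths numeric vector of window lengths (s).
#' @param design a [StimulusDesign-class].
#' @param fb optional [FilterBankSpec-class].
#' @param latency visual latency (s).
#' @param gazeShift gaze-shift time for the ITR (s).
#' @param subject subject identifier recorded in the report.
#' @return data.frame with one row per length: subject, method, source and
#'   target domain, lengthS, accuracyPct, itrBpm.
#' @export
evaluateTransfer <- function(method, source, target, lengths, design,
                             fb = NULL, latency = 0.14, gazeShift = 1,
                             subject = "S1") {
  do.call(rbind, lapply(lengths, function(len) {
    sw <- extractWindow(source, latency, len)
    tw <- extractWindow(target, latency, len)
    pred <- decodeTransfer(method, sw, tw, design, fb)
    acc <- 100 * mean(pred == tw@labels)
    data.frame(subject = subject, method = method,
               sourceDay = unique(source@day)[1],
               sourceElectrode = unique(source@electrode)[1],
               targetDay = unique(target@day)[1],
               targetElectrode = unique(target@electrode)[1],
               lengthS = len, accuracyPct = acc,
               itrBpm = itr(acc / 100, nTargets(design), len, gazeShift),
               stringsAsFactors = FALSE)
  }))
}

#' Accuracy as a function of the number of training blocks
#'
#' For each block count n, draws \code{repeats} distinct random subsets of
#' n source blocks (without replacement), trains on each subset, tests on
#' the full target session, and averages.
#'
#' @param method decoder name.
#' @param source,target full-epoch [EpochSet-class] objects.
#' @param design a [StimulusDesign-class].
#' @param nBlocksGrid block counts to evaluate.
#' @param repeats random subsets per block count (default 6).
#' @param seed RNG seed for the subset draws (mandatory).
#' @param length decoding-window length (s).
#' @param fb optional [FilterBankSpec-class].
#' @param latency visual latency (s).
#' @param gazeShift gaze-shift time (s).
#' @param subject subject identifier.
#' @return data.frame with one row per block count: nTrainingBlocks,
#'   accuracyPct (mean over repeats), itrBpm, plus the metadata columns of
#'   [evaluateTransfer()].
#' @export
trainingBlockCurve <- function(method, source, target, design,
                               nBlocksGrid = 2:5, repeats = 6L, seed,
                               length = 1.2, fb = NULL, latency = 0.14,
                               gazeShift = 1, subject = "S1") {
  if (missing(seed)) stop("a seed is required for the block subsampling")
  blocks <- sort(unique(source@block))
  if (max(nBlocksGrid) > base::length(blocks))
    stop("requested more training blocks than available")
  sw <- extractWindow(source, latency, length)
  tw <- extractWindow(target, latency, length)
  swBands <- if (is.null(fb)) NULL else filterbankDecompose(sw, fb)
  twBands <- if (is.null(fb)) NULL else filterbankDecompose(tw, fb)
  withSeed(seed, {
    do.call(rbind, lapply(nBlocksGrid, function(nb) {
      nSub <- choose(base::length(blocks), nb)
      draws <- min(repeats, nSub)
      seen <- character(0)
      accs <- numeric(draws)
      for (r in seq_len(draws)) {
        repeat {
          sub <- sort(sample(blocks, nb))
          key <- paste(sub, collapse = ",")
          if (!key %in% seen) { seen <- c(seen, key); break }
        }
        train <- sw[sw@block %in% sub]
        # when training and testing in the same domain, test on the
        # held-out blocks; for a genuine transfer the full target session
        # is the test set
        sameDomain <- setequal(unique(source@day), unique(target@day)) &&
          setequal(unique(source@electrode), unique(target@electrode))
        testIdx <- if (sameDomain) !(tw@block %in% sub)
                   else rep(TRUE, nTrials(tw))
        test <- tw[testIdx]
        pred <- decodeTransfer(method, train, test, design, fb,
                               srcBands = subsetBands(swBands,
                                                      sw@block %in% sub),
                               testBands = subsetBands(twBands, testIdx))
        accs[r] <- 100 * mean(pred == test@labels)
      }
      acc <- mean(accs)
      data.frame(subject = subject, method = method,
                 nTrainingBlocks = nb,
                 sourceDay = unique(source@day)[1],
                 sourceElectrode = unique(source@electrode)[1],
                 targetDay = unique(target@day)[1],
                 targetElectrode = unique(target@electrode)[1],
                 lengthS = length, accuracyPct = acc,
                 itrBpm = itr(acc / 100, nTargets(design), length,
                              gazeShift),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Per-channel SSVEP amplitude topography of one block
#'
#' For every trial of the block, takes the magnitude of the discrete
#' Fourier component nearest the trial's fundamental frequency on each
#' channel, averages over the block's trials, and normalises the maximum
#' to 1.
#'
#' @param epochs a labelled [EpochSet-class] (windowed to the analysis
#'   interval).
#' @param block block index.
#' @param design a [StimulusDesign-class].
#' @return unit-max channel amplitude vector.
#' @export
amplitudeTopography <- function(epochs, block, design) {
  idx <- which(epochs@block == block)
  if (!length(idx)) stop("block not present in the epoch set")
  freqs <- stimulusFrequencies(design)
  N <- nSamples(epochs)
  fs <- epochs@fs
  amps <- matrix(0, length(idx), nChannels(epochs))
  for (j in seq_along(idx)) {
    i <- idx[j]
    bin <- round(freqs[epochs@labels[i]] * N / fs) + 1L
    sp <- abs(stats::mvfft(t(epochs@data[i, , ])))
    amps[j, ] <- sp[bin, ] / N
  }
  v <- colMeans(amps)
  v / max(v)
}

#' Pairwise block similarity, bucketed by domain relation
#'
#' Computes Pearson correlations between all block pairs (amplitude
#' topographies, or covariance matrices vectorised as the upper triangle
#' including the diagonal) and buckets each pair as within/cross-day x
#' within/cross-electrode (WDWE, WDCE, CDWE, CDCE).
#'
#' @param blocks list of numeric vectors or of square matrices, one per
#'   block.
#' @param metadata data.frame with one row per block and columns
#'   \code{day} and \code{electrode}.
#' @return list with \code{matrix} (block x block similarity) and
#'   \code{pairs} (data.frame: blockA, blockB, pairType, similarity).
#' @export
similarityMatrix <- function(blocks, metadata) {
  nb <- length(blocks)
  if (nb < 2L) stop("at least 2 blocks are required")
  stopifnot(nrow(metadata) == nb)
  vecs <- lapply(blocks, function(b) {
    if (is.matrix(b)) b[upper.tri(b, diag = TRUE)] else as.numeric(b)
  })
  V <- do.call(cbind, vecs)
  M <- stats::cor(V)
  pairs <- do.call(rbind, lapply(seq_len(nb - 1L), function(i) {
    do.call(rbind, lapply((i + 1L):nb, function(j) {
      sameDay <- metadata$day[i] == metadata$day[j]
      sameEl <- metadata$electrode[i] == metadata$electrode[j]
      type <- paste0(if (sameDay) "WD" else "CD",
                     if (sameEl) "WE" else "CE")
      data.frame(blockA = i, blockB = j, pairType = type,
                 similarity = M[i, j], stringsAsFactors = FALSE)
    }))
  }))
  list(matrix = M, pairs = pairs)
}

#' Planned paired t-test
#'
#' Two-sided paired t-test of the hypothesis that the mean paired
#' difference is zero: \eqn{t = \bar d / (s_d / \sqrt n)} with n - 1
#' degrees of freedom.  Identical inputs give t = 0, p = 1; zero-variance
#' non-zero differences are degenerate and return p = 0 with
#' \code{degenerate = TRUE}.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with \code{t}, \code{p}, \code{df} and \code{degenerate}.
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("at least 2 pairs are required")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = n - 1L, degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Summarise an evaluation report per method
#'
#' Emits the per-subject rows plus a Mean row and two dispersion rows per
#' method: the sample standard deviation (SD) and the standard error
#' (SE = SD / sqrt(n)).  Both are labelled explicitly.
#'
#' @param report data.frame with columns \code{subject}, \code{method} and
#'   one or more numeric measure columns (e.g. \code{accuracyPct},
#'   \code{itrBpm}).
#' @param measures names of the numeric columns to aggregate.
#' @return data.frame with a \code{statistic} column:
#'   \code{"subject"} rows followed by \code{"Mean"}, \code{"SD"},
#'   \code{"SE"} rows per method.  Dispersion rows are \code{NA} for a
#'   single subject.
#' @export
summarizeTable <- function(report,
                           measures = intersect(c("accuracyPct", "itrBpm"),
                                                names(report))) {
  if (!nrow(report)) stop("empty report")
  out <- do.call(rbind, lapply(split(report, report$method), function(g) {
    base <- data.frame(method = g$method, subject = g$subject,
                       statistic = "subject", stringsAsFactors = FALSE)
    for (m in measures) base[[m]] <- g[[m]]
    n <- nrow(g)
    agg <- data.frame(method = g$method[1], subject = NA,
                      statistic = c("Mean", "SD", "SE"),
                      stringsAsFactors = FALSE)
    for (m in measures) {
      s <- if (n > 1L) sd(g[[m]]) else NA_real_
      agg[[m]] <- c(mean(g[[m]]), s, if (n > 1L) s / sqrt(n) else NA_real_)
    }
    rbind(base, agg)
  }))
  rownames(out) <- NULL
  out
}
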