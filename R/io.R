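# Epoch container I/O: a single-file hierarchical container holding a
# JSON header (sampling rate, dimensions, per-trial metadata, design
# parameters, config hash) followed by the trial data as little-endian
# float32, plus a JSON sidecar manifest.  The layout is trials-major
# (samples fastest) for streaming.

containerMagic <- "SSVEPEPOCHS1"

# small stable FNV-1a hash of a configuration list (hex string)
configHash <- function(config) {
  if (is.null(config)) return(NA_character_)
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = 10)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write an epoch container
#'
#' Serialises an [EpochSet-class] to a single binary container (JSON
#' header + little-endian float32 payload) and writes a JSON sidecar
#' manifest (\code{<path>.manifest.json}) describing the sessions it
#' holds.
#'
#' @param epochs an [EpochSet-class].
#' @param path output file path.
#' @param design optional [StimulusDesign-class]; stored so that labels
#'   can be validated on read.
#' @param config optional simulator configuration; its hash is stored.
#' @param subject subject identifier for the manifest.
#' @return \code{path}, invisibly.
#' @export
writeEpochs <- function(epochs, path, design = NULL, config = NULL,
                        subject = "S1") {
  d <- dim(epochs@data)
  header <- list(
    magic = containerMagic, version = 1L,
    fs = epochs@fs, nTrials = d[1], nChannels = d[2], nSamples = d[3],
    onsetIndex = epochs@onsetIndex,
    labels = epochs@labels, block = epochs@block, day = epochs@day,
    electrode = epochs@electrode,
    configHash = configHash(config))
  if (!is.null(design))
    header$design <- list(nTargets = nTargets(design),
                          baseFreq = design@baseFreq,
                          freqStep = design@freqStep,
                          basePhase = design@basePhase,
                          phaseStep = design@phaseStep,
                          nHarmonics = nHarmonics(design))
  hjson <- charToRaw(as.character(
    jsonlite::toJSON(header, auto_unbox = TRUE, digits = 10)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("%s %d\n", containerMagic, length(hjson))), con)
  writeBin(hjson, con)
  # samples fastest, then channels, then trials
  writeBin(as.numeric(aperm(epochs@data, c(3, 2, 1))), con, size = 4L,
           endian = "little")
  sessions <- unique(data.frame(day = epochs@day,
                                electrode = epochs@electrode,
                                stringsAsFactors = FALSE))
  sessions$nBlocks <- vapply(seq_len(nrow(sessions)), function(i)
    length(unique(epochs@block[epochs@day == sessions$day[i] &
                               epochs@electrode == sessions$electrode[i]])),
    1L)
  manifest <- list(subject = subject, container = basename(path),
                   sessions = sessions, configHash = configHash(config))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read an epoch container
#'
#' Validates the header (every required field must be present, labels must
#' lie within the stored design's class range) and reconstructs the
#' [EpochSet-class].
#'
#' @param path container path written by [writeEpochs()].
#' @return an [EpochSet-class]; the stored design parameters, if any, are
#'   attached as attribute \code{"design"}.
#' @export
readEpochs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  parts <- strsplit(first, " ")[[1]]
  if (length(parts) != 2L || parts[1] != containerMagic)
    stop("format error: not an epoch container (bad magic)")
  hlen <- as.integer(parts[2])
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  for (f in c("fs", "nTrials", "nChannels", "nSamples", "onsetIndex",
              "labels", "block", "day", "electrode"))
    if (is.null(header[[f]]))
      stop(sprintf("format error: missing field '%s'", f))
  n <- header$nTrials * header$nChannels * header$nSamples
  raw <- readBin(con, "numeric", n, size = 4L, endian = "little")
  if (length(raw) != n)
    stop("format error: truncated data payload")
  data <- aperm(array(raw, dim = c(header$nSamples, header$nChannels,
                                   header$nTrials)), c(3, 2, 1))
  if (!is.null(header$design)) {
    K <- header$design$nTargets
    if (any(header$labels < 1L | header$labels > K))
      stop("validation error: label outside [1, nTargets]")
  }
  out <- new("EpochSet", data = data, fs = header$fs,
             labels = as.integer(header$labels),
             block = as.integer(header$block),
             day = as.integer(header$day),
             electrode = as.character(header$electrode),
             onsetIndex = as.integer(header$onsetIndex))
  if (!is.null(header$design)) attr(out, "design") <- header$design
  out
}
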