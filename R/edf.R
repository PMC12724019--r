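# Compact EDF (European Data Format) I/O: fixed 256-byte header + one
# 256-byte header block per signal, 16-bit little-endian samples. Supports
# the single-fixed-sampling-rate, continuous-recording case this package
# produces and consumes.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a multichannel recording to an EDF file
#'
#' All channels share one sampling rate; samples are quantized to 16 bits
#' over the per-channel physical range (so values round-trip to within one
#' quantization step).
#'
#' @param path Output file path.
#' @param signals Numeric matrix samples x channels with column names.
#' @param fs Sampling rate in Hz.
#' @param record_seconds Data-record duration in seconds (default 1; the
#'   signal is zero-padded to a whole number of records).
#' @param physical_unit Unit label written per channel (default "uV").
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, fs, record_seconds = 1,
                      physical_unit = "uV") {
  signals <- as.matrix(signals)
  stopifnot(!is.null(colnames(signals)), fs > 0)
  ns <- ncol(signals)
  spr <- as.integer(round(fs * record_seconds))
  n_rec <- as.integer(ceiling(nrow(signals) / spr))
  pad_n <- n_rec * spr - nrow(signals)
  if (pad_n > 0) signals <- rbind(signals, matrix(0, pad_n, ns))

  phys_min <- apply(signals, 2, min)
  phys_max <- apply(signals, 2, max)
  flat <- phys_max - phys_min < 1e-9
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(format(record_seconds), 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(colnames(signals), edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),
    rep(edf_pad(physical_unit, 8), ns),
    vapply(phys_min, function(v) edf_pad(formatC(v, format = "g", digits = 7), 8), ""),
    vapply(phys_max, function(v) edf_pad(formatC(v, format = "g", digits = 7), 8), ""),
    rep(edf_pad(dig_min, 8), ns),
    rep(edf_pad(dig_max, 8), ns),
    rep(edf_pad("", 80), ns),
    rep(edf_pad(spr, 8), ns),
    rep(edf_pad("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    block <- vapply(seq_len(ns), function(j) {
      as.integer(round((signals[rows, j] - phys_min[j]) * scale[j]) + dig_min)
    }, integer(spr))
    writeBin(as.vector(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf] (or any fixed-rate EDF)
#'
#' @param path EDF file path.
#' @return List with `signals` (samples x channels matrix, physical units),
#'   `fs` (Hz), and `channels` (names).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                       # version
  readChar(con, 160, useBytes = TRUE)                     # patient + recording
  readChar(con, 16, useBytes = TRUE)                      # date + time
  readChar(con, 8, useBytes = TRUE)                       # header bytes
  readChar(con, 44, useBytes = TRUE)                      # reserved
  n_rec <- as.integer(readChar(con, 8, useBytes = TRUE))
  rec_dur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  ns <- as.integer(readChar(con, 4, useBytes = TRUE))

  rd <- function(w) vapply(seq_len(ns), function(i)
    trimws(readChar(con, w, useBytes = TRUE)), "")
  labels <- rd(16); rd(80); rd(8)
  phys_min <- as.numeric(rd(8)); phys_max <- as.numeric(rd(8))
  dig_min <- as.numeric(rd(8)); dig_max <- as.numeric(rd(8))
  rd(80); spr <- as.integer(rd(8)); rd(32)
  stopifnot(length(unique(spr)) == 1L)
  spr <- spr[1]
  fs <- spr / rec_dur

  raw <- readBin(con, integer(), n = n_rec * ns * spr, size = 2,
                 endian = "little")
  signals <- matrix(0, n_rec * spr, ns)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    off <- (r - 1) * ns * spr
    for (j in seq_len(ns)) {
      d <- raw[(off + (j - 1) * spr + 1):(off + j * spr)]
      signals[((r - 1) * spr + 1):(r * spr), j] <-
        (d - dig_min[j]) * scale[j] + phys_min[j]
    }
  }
  colnames(signals) <- labels
  list(signals = signals, fs = fs, channels = labels)
}
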