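#' Read and write EDF recordings
#'
#' Minimal European Data Format (EDF, 16-bit) I/O for continuous EEG.
#' The writer emits one 1-second data record per second of signal with a
#' symmetric physical range per channel (units microvolts); the reader
#' inverts the digital-to-physical mapping and returns an
#' [ms_recording()]. Only the subset of EDF used for plain continuous
#' recordings is supported: no annotations channel, equal sampling rate
#' across signals, 1-s records.
#'
#' @param rec An [ms_recording()] (microvolts). The number of samples
#'   must be a whole number of seconds; a trailing partial second is
#'   dropped with a warning.
#' @param path File path (`.edf`).
#' @param patient_id,recording_id Free-text header fields (ASCII,
#'   truncated to 80 bytes).
#' @return `write_edf()` returns `path` invisibly; `read_edf()` returns
#'   an [ms_recording()].
#' @name edf
NULL

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- sprintf("%.6g", x)
  if (nchar(s) > width) s <- sprintf("%.3g", x)
  if (nchar(s) > width) stop("EDF numeric field overflow: ", s, call. = FALSE)
  edf_pad(s, width)
}

#' @rdname edf
#' @export
write_edf <- function(rec, path, patient_id = "X", recording_id = "X") {
  assert_recording(rec)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("write_edf() requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  x <- rec$data
  nrec <- floor(ncol(x) / fs)
  if (nrec < 1) stop("Recording shorter than one data record", call. = FALSE)
  if (nrec * fs < ncol(x)) {
    warning("Dropping trailing partial second (", ncol(x) - nrec * fs,
            " samples)", call. = FALSE)
    x <- x[, seq_len(nrec * fs), drop = FALSE]
  }
  C <- nrow(x)
  # symmetric physical range per channel; at least 1 µV to avoid a
  # degenerate gain on silent channels
  pm <- pmax(apply(abs(x), 1, max) * 1.0001, 1)
  pm <- signif(pm, 4)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(patient_id, 80),
    edf_pad(recording_id, 80),
    edf_pad("01.01.20", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (C + 1), 8),
    edf_pad("", 44),
    edf_pad(nrec, 8),
    edf_pad("1", 8),
    edf_pad(C, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  fld(rec$channel_names, 16)
  fld(rep("", C), 80)                                  # transducer
  fld(rep("uV", C), 8)
  fld(vapply(-pm, edf_num, "", width = 8), 8)          # physical min
  fld(vapply(pm, edf_num, "", width = 8), 8)           # physical max
  fld(rep("-32767", C), 8)
  fld(rep("32767", C), 8)
  fld(rep("", C), 80)                                  # prefiltering
  fld(rep(fs, C), 8)
  fld(rep("", C), 32)

  gain <- 32767 / pm
  for (r in seq_len(nrec)) {
    sl <- ((r - 1) * fs + 1):(r * fs)
    block <- round(x[, sl, drop = FALSE] * gain)
    block <- pmin(pmax(block, -32767), 32767)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  version <- rd(8)
  if (version != "0") stop("Not an EDF file: ", path, call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                         # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  C <- as.integer(rd(4))
  labels <- vapply(seq_len(C), function(i) rd(16), "")
  for (i in seq_len(C)) rd(80)
  for (i in seq_len(C)) rd(8)   # physical dimension
  pmin_ <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(C)) rd(80)
  spr <- vapply(seq_len(C), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(C)) rd(32)
  if (length(unique(spr)) != 1) {
    stop("Mixed sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / dur
  out <- matrix(0, nrow = C, ncol = nrec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", n = C * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = spr[1], ncol = C)
    sl <- ((r - 1) * spr[1] + 1):(r * spr[1])
    out[, sl] <- t((block - matrix(dmin, spr[1], C, byrow = TRUE)) *
                     matrix(scale, spr[1], C, byrow = TRUE) +
                     matrix(pmin_, spr[1], C, byrow = TRUE))
  }
  ms_recording(out, fs = fs, channel_names = labels)
}
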