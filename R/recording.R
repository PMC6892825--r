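#' Multichannel EEG recording container
#'
#' Lightweight matrix-backed container for a continuous multichannel EEG
#' segment: a channels x samples matrix in microvolts plus sampling rate,
#' channel names, montage coordinates and a reference-state flag. Epoch
#' boundary indices (first sample of each epoch after concatenation) are
#' carried along so downstream stages can optionally split microstate
#' segments at concatenation seams.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one per row of `data`. Defaults
#'   to the rownames of `data` or the 10-20 names when the channel count
#'   matches.
#' @param montage Tibble of electrode positions (see [montage_1020()]);
#'   matched to `channel_names`.
#' @param reference Reference state, `"raw"` or `"average"`.
#' @param boundaries Integer vector of epoch-start sample indices
#'   (1-based); `integer(0)` for a recording never concatenated.
#' @param eyes_closed_onset_s Time (s) at which the eyes-closed condition
#'   starts; synthetic data carries 0.
#' @return An object of class `ms_recording`.
#' @export
ms_recording <- function(data, fs, channel_names = NULL, montage = NULL,
                         reference = c("raw", "average"),
                         boundaries = integer(0),
                         eyes_closed_onset_s = 0) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1 || ncol(data) < 1) {
    stop("`data` must be a non-empty numeric channels x samples matrix",
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a positive scalar", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- rownames(data)
    if (is.null(channel_names) && nrow(data) == 19) {
      channel_names <- montage_1020()$channel
    }
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(nrow(data)))
    }
  }
  stopifnot(length(channel_names) == nrow(data))
  rownames(data) <- channel_names
  if (is.null(montage) && all(channel_names %in% montage_1020()$channel)) {
    montage <- montage_1020(channel_names)
  }
  if (reference == "average") {
    mu <- colMeans(data)
    if (max(abs(mu)) > 1e-6) {
      stop("reference = \"average\" but per-sample channel means reach ",
           format(max(abs(mu))), " µV", call. = FALSE)
    }
  }
  structure(
    list(
      data = data,
      fs = fs,
      channel_names = channel_names,
      montage = montage,
      reference = reference,
      boundaries = as.integer(boundaries),
      eyes_closed_onset_s = eyes_closed_onset_s
    ),
    class = "ms_recording"
  )
}

#' @export
print.ms_recording <- function(x, ...) {
  cat(sprintf(
    "<ms_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference
  ))
  if (length(x$boundaries) > 0) {
    cat(sprintf("  %d epoch boundaries retained\n", length(x$boundaries) - 1L))
  }
  invisible(x)
}

#' @export
dim.ms_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

assert_recording <- function(rec) {
  if (!inherits(rec, "ms_recording")) {
    stop("Expected an `ms_recording` object", call. = FALSE)
  }
  invisible(rec)
}

assert_average_reference <- function(rec) {
  assert_recording(rec)
  if (!identical(rec$reference, "average")) {
    stop("Recording must be average-referenced (see average_reference())",
         call. = FALSE)
  }
  invisible(rec)
}

#' Set of fixed-length EEG epochs
#'
#' @param epochs List of channels x L numeric matrices, all the same shape.
#' @param fs Sampling rate (Hz).
#' @param channel_names,montage As in [ms_recording()].
#' @param subject_id Optional source subject identifier.
#' @param kept Integer indices of the source epochs that survive screening
#'   (identity on construction).
#' @param log Tibble describing per-epoch screening outcomes (may be empty).
#' @return An object of class `ms_epochs`.
#' @export
ms_epochs <- function(epochs, fs, channel_names = NULL, montage = NULL,
                      subject_id = NA_character_, kept = seq_along(epochs),
                      log = NULL) {
  stopifnot(is.list(epochs))
  if (length(epochs) > 0) {
    shp <- dim(epochs[[1]])
    ok <- vapply(epochs, function(e) identical(dim(e), shp), logical(1))
    if (!all(ok)) stop("All epochs must share the same shape", call. = FALSE)
    if (is.null(channel_names)) channel_names <- rownames(epochs[[1]])
  }
  if (is.null(log)) {
    log <- tibble::tibble(epoch = integer(0), n_bad = integer(0),
                          action = character(0))
  }
  structure(
    list(epochs = epochs, fs = fs, channel_names = channel_names,
         montage = montage, subject_id = subject_id,
         kept = as.integer(kept), log = log),
    class = "ms_epochs"
  )
}

#' @export
print.ms_epochs <- function(x, ...) {
  L <- if (length(x$epochs) > 0) ncol(x$epochs[[1]]) else 0L
  cat(sprintf("<ms_epochs> %d epochs of %d samples @ %g Hz\n",
              length(x$epochs), L, x$fs))
  invisible(x)
}

#' @export
length.ms_epochs <- function(x) length(x$epochs)
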