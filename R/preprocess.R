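#' Zero-phase FIR filtering
#'
#' Windowed-sinc (Hamming) FIR band filters applied by FFT convolution
#' with linear-phase delay compensation, so the net filter is zero-phase
#' and output length equals input length. The filter order follows the
#' Hamming rule of thumb `order = 3.3 * fs / transition_hz` (rounded up
#' to even).
#'
#' @param rec An [ms_recording()].
#' @param low,high Band edges in Hz. For `bandpass()` the passband is
#'   `[low, high]`; for `bandstop()` the stopband is `[low, high]`.
#' @param transition_hz Transition bandwidth of the design (Hz).
#' @return A filtered [ms_recording()] of identical shape.
#' @name filters
NULL

fir_band_kernel <- function(low, high, fs, type = c("pass", "stop"),
                            transition_hz = 1) {
  type <- match.arg(type)
  if (!(low > 0 && high > low && high < fs / 2)) {
    stop("Band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  ord <- ceiling(3.3 * fs / transition_hz)
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, c(low, high) * 2 / fs, type = type)
}

# FFT convolution of every channel with kernel b, compensating the
# (length(b)-1)/2 group delay of the linear-phase kernel
apply_fir <- function(x, b) {
  x <- as.matrix(x)
  Tn <- ncol(x)
  nb <- length(b)
  nfft <- stats::nextn(Tn + nb - 1, c(2, 3))
  B <- stats::fft(c(b, rep(0, nfft - nb)))
  X <- stats::mvfft(rbind(t(x), matrix(0, nfft - Tn, nrow(x))))
  y <- Re(stats::mvfft(X * B, inverse = TRUE)) / nfft
  delay <- (nb - 1) / 2
  t(y[delay + seq_len(Tn), , drop = FALSE])
}

#' @rdname filters
#' @export
bandpass <- function(rec, low, high, transition_hz = 1) {
  assert_recording(rec)
  b <- fir_band_kernel(low, high, rec$fs, "pass", transition_hz)
  out <- rec
  out$data <- apply_fir(rec$data, b)
  rownames(out$data) <- rec$channel_names
  # filtering perturbs the per-sample mean at the edges; average
  # reference must be re-asserted downstream
  if (identical(rec$reference, "average")) {
    out$data <- sweep(out$data, 2, colMeans(out$data))
  }
  out
}

#' @rdname filters
#' @export
bandstop <- function(rec, low = 45, high = 55, transition_hz = 2) {
  assert_recording(rec)
  b <- fir_band_kernel(low, high, rec$fs, "stop", transition_hz)
  out <- rec
  out$data <- apply_fir(rec$data, b)
  rownames(out$data) <- rec$channel_names
  if (identical(rec$reference, "average")) {
    out$data <- sweep(out$data, 2, colMeans(out$data))
  }
  out
}

#' Re-reference to the common average montage
#'
#' Subtracts the across-channel mean from every sample and flags the
#' recording as average-referenced. Idempotent.
#'
#' @param rec An [ms_recording()] with at least 2 channels.
#' @return An average-referenced [ms_recording()].
#' @export
average_reference <- function(rec) {
  assert_recording(rec)
  if (n_channels(rec) < 2) {
    stop("Average reference needs at least 2 channels", call. = FALSE)
  }
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out$reference <- "average"
  out
}

#' Cut a recording into non-overlapping 1-second epochs
#'
#' @param rec An [ms_recording()].
#' @return An [ms_epochs()] with `floor(T/fs)` epochs; a trailing
#'   partial second is discarded. Shorter-than-1-s input yields an
#'   empty epoch set (not an error).
#' @export
epoch_1s <- function(rec) {
  assert_recording(rec)
  L <- as.integer(round(rec$fs))
  n <- floor(n_samples(rec) / L)
  eps <- lapply(seq_len(n), function(i) {
    rec$data[, ((i - 1) * L + 1):(i * L), drop = FALSE]
  })
  ms_epochs(eps, fs = rec$fs, channel_names = rec$channel_names,
            montage = rec$montage)
}

#' Amplitude-threshold epoch screening with channel interpolation
#'
#' Automated surrogate for visual artifact inspection: in each epoch a
#' channel is bad when its peak absolute amplitude exceeds
#' `amp_thresh`; epochs with at most `max_interp` bad channels have
#' them reconstructed by spherical-spline interpolation, epochs with
#' more are rejected. Clean epochs pass through untouched.
#'
#' @param es An [ms_epochs()] with montage available.
#' @param amp_thresh Peak-amplitude threshold in microvolts (> 0).
#' @param max_interp Maximum number of channels interpolated per epoch
#'   before the epoch is rejected instead (default 2: three or more bad
#'   channels reject the epoch).
#' @return An [ms_epochs()]; `$kept` holds the surviving source-epoch
#'   indices and `$log` one row per input epoch.
#' @export
screen_epochs <- function(es, amp_thresh = 100, max_interp = 2) {
  stopifnot(inherits(es, "ms_epochs"))
  if (!is.numeric(amp_thresh) || amp_thresh <= 0) {
    stop("`amp_thresh` must be positive", call. = FALSE)
  }
  out <- list()
  kept <- integer(0)
  log <- vector("list", length(es$epochs))
  for (i in seq_along(es$epochs)) {
    e <- es$epochs[[i]]
    bad <- which(apply(abs(e), 1, max) > amp_thresh)
    if (length(bad) == 0) {
      out[[length(out) + 1]] <- e
      kept <- c(kept, i)
      act <- "clean"
    } else if (length(bad) <= max_interp) {
      if (is.null(es$montage)) {
        stop("Montage required to interpolate bad channels", call. = FALSE)
      }
      out[[length(out) + 1]] <-
        spherical_interpolate(e, bad, es$montage)
      kept <- c(kept, i)
      act <- "interpolated"
    } else {
      act <- "rejected"
    }
    log[[i]] <- tibble::tibble(epoch = i, n_bad = length(bad), action = act)
  }
  ms_epochs(out, fs = es$fs, channel_names = es$channel_names,
            montage = es$montage, subject_id = es$subject_id,
            kept = kept, log = dplyr::bind_rows(log))
}

#' Subject inclusion rule
#'
#' A subject enters the analysis only when at least `min_epochs` clean
#' 1-s epochs survive screening.
#'
#' @param es An [ms_epochs()].
#' @param min_epochs Minimum surviving epoch count (default 30).
#' @return Logical scalar.
#' @export
include_subject <- function(es, min_epochs = 30) {
  stopifnot(inherits(es, "ms_epochs"))
  length(es$epochs) >= min_epochs
}

#' Concatenate epochs into one continuous recording
#'
#' Epochs are abutted in order into a single continuous file; the first
#' sample index of every epoch is retained in `$boundaries` so that
#' downstream stages can treat concatenation seams specially if asked.
#'
#' @param es A non-empty [ms_epochs()].
#' @return An [ms_recording()].
#' @export
concatenate <- function(es) {
  stopifnot(inherits(es, "ms_epochs"))
  if (length(es$epochs) == 0) {
    stop("Cannot concatenate an empty epoch set", call. = FALSE)
  }
  L <- ncol(es$epochs[[1]])
  dat <- do.call(cbind, es$epochs)
  ms_recording(dat, fs = es$fs, channel_names = es$channel_names,
               montage = es$montage,
               boundaries = seq(1L, by = L, length.out = length(es$epochs)))
}
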