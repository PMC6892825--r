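# Small cohorts and recordings used across the suite.

tiny_spec <- function(n = c(DS = 2L, `DS-AD` = 2L), seed = 11,
                      epochs = 35, snr = 4, ...) {
  simulation_spec(
    n_subjects = n, seed = seed, snr = snr,
    epochs_mean = stats::setNames(rep(epochs, length(n)), names(n)),
    epochs_sd = stats::setNames(rep(0.1, length(n)), names(n)),
    ...
  )
}

# recording holding an arbitrary matrix with the 10-20 montage
rec_from <- function(data, fs = 1000, reference = "raw") {
  ms_recording(data, fs = fs,
               channel_names = montage_1020()$channel[seq_len(nrow(data))],
               montage = montage_1020()[seq_len(nrow(data)), ],
               reference = reference)
}

# sine-carrier recording on all 19 channels (distinct per-channel gains
# so the signal is not spatially degenerate)
sine_recording <- function(freq, dur_s = 20, fs = 1000, amp = 10) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  gains <- seq(0.5, 1.5, length.out = 19)
  rec_from(outer(gains, amp * sin(2 * pi * freq * t)))
}

central_rms <- function(x, frac = 0.5) {
  n <- length(x)
  lo <- floor(n * (1 - frac) / 2) + 1
  sqrt(mean(x[lo:(lo + floor(n * frac) - 1)]^2))
}

# labels object wrapping an explicit correlation matrix (for smoothing
# tests that construct fits by hand)
labels_from_corr <- function(corr, fs = 1000) {
  labels <- max.col(corr, ties.method = "first")
  structure(
    list(labels = labels,
         fit = corr[cbind(seq_len(nrow(corr)), labels)],
         corr = corr, fs = fs, boundaries = integer(0),
         class_labels = LETTERS[seq_len(ncol(corr))]),
    class = "ms_labels"
  )
}

# iid observed/expected pair per subject under the exchangeable null
null_transition_tables <- function(n_subjects, K = 4) {
  lapply(seq_len(n_subjects), function(i) {
    draw <- function() {
      M <- matrix(0, K, K)
      off <- row(M) != col(M)
      v <- stats::rexp(sum(off))
      M[off] <- v / sum(v)
      M
    }
    list(observed = draw(), expected = draw(),
         subject_id = sprintf("s%02d", i))
  })
}
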