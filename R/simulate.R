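#' Simulation specification for a synthetic resting-state cohort
#'
#' Bundles every knob of the synthetic EEG generator. The defaults are
#' the study conditions the pipeline is validated under: two groups
#' (DS, DS-AD) of 10 and 15 subjects, K = 4 microstate classes whose
#' per-group mean segment durations and relative occurrence rates
#' differ between groups (DS-AD with a longer class-A and shorter
#' class-D duration than DS), 19-channel 10-20 montage at 1 kHz, a
#' 10 Hz alpha carrier, broadband amplitude SNR 4, and per-subject
#' epoch counts drawn from per-group normal distributions truncated
#' to 30-170 one-second epochs.
#'
#' @param n_subjects Named integer vector of subjects per group.
#' @param K Number of microstate classes (2-8).
#' @param mean_durations_ms Group x class matrix of mean segment
#'   durations (ms), rownames the group names.
#' @param occurrence_bias Group x class matrix of relative
#'   next-class weights (need not be normalised).
#' @param fs Sampling rate (Hz).
#' @param alpha_freq Carrier frequency (Hz).
#' @param snr Broadband amplitude signal-to-noise ratio (> 0; `Inf`
#'   disables noise).
#' @param amplitude Alpha carrier scale in microvolts.
#' @param epochs_mean,epochs_sd Named per-group mean/SD of the
#'   per-subject 1-s epoch count.
#' @param epochs_range Truncation bounds on the epoch count.
#' @param age_mean,age_sd,dsqiid_mean,dsqiid_sd Named per-group
#'   demographic parameters (DSQIID truncated to 0-53).
#' @param epoch_length_s Epoch length (fixed at 1 s).
#' @param seed Integer master seed; every draw is a pure function of it.
#' @return An object of class `ms_simspec`.
#' @export
simulation_spec <- function(
    n_subjects = c(DS = 10L, `DS-AD` = 15L),
    K = 4L,
    mean_durations_ms = NULL,
    occurrence_bias = NULL,
    fs = 1000,
    alpha_freq = 10,
    snr = 4,
    amplitude = 30,
    epochs_mean = c(DS = 108.3, `DS-AD` = 86.8),
    epochs_sd = c(DS = 57.72, `DS-AD` = 52.85),
    epochs_range = c(30L, 170L),
    age_mean = c(DS = 47.1, `DS-AD` = 51.8),
    age_sd = c(DS = 9.49, `DS-AD` = 5.13),
    dsqiid_mean = c(DS = 2.60, `DS-AD` = 21.6),
    dsqiid_sd = c(DS = 2.84, `DS-AD` = 5.72),
    epoch_length_s = 1,
    seed = 1L) {
  groups <- names(n_subjects)
  if (is.null(groups) || any(groups == "")) {
    stop("`n_subjects` must be a named vector (one entry per group)",
         call. = FALSE)
  }
  K <- as.integer(K)
  if (K < 2 || K > 8) stop("K must be between 2 and 8", call. = FALSE)
  class_labels <- LETTERS[seq_len(K)]

  if (is.null(mean_durations_ms)) {
    # default group-mean durations for A-D; neutral 80 ms beyond D
    base <- rbind(DS = c(65.94, 70.79, 91.61, 81.52, 80, 80, 80, 80),
                  `DS-AD` = c(73.19, 71.08, 89.77, 75.79, 80, 80, 80, 80))
    mean_durations_ms <- base[groups, seq_len(K), drop = FALSE]
  }
  if (is.null(occurrence_bias)) {
    base <- rbind(DS = c(2.75, 2.74, 3.66, 3.37, 3, 3, 3, 3),
                  `DS-AD` = c(3.03, 2.88, 3.59, 3.19, 3, 3, 3, 3))
    occurrence_bias <- base[groups, seq_len(K), drop = FALSE]
  }
  mean_durations_ms <- as.matrix(mean_durations_ms)
  occurrence_bias <- as.matrix(occurrence_bias)
  colnames(mean_durations_ms) <- class_labels
  colnames(occurrence_bias) <- class_labels
  stopifnot(
    nrow(mean_durations_ms) == length(groups),
    ncol(mean_durations_ms) == K,
    all(mean_durations_ms > 0),
    all(occurrence_bias >= 0),
    is.numeric(snr), snr > 0,
    epochs_range[1] >= 30
  )
  structure(
    list(n_subjects = n_subjects, groups = groups, K = K,
         class_labels = class_labels,
         mean_durations_ms = mean_durations_ms,
         occurrence_bias = occurrence_bias,
         fs = fs, alpha_freq = alpha_freq, snr = snr,
         amplitude = amplitude,
         epochs_mean = epochs_mean, epochs_sd = epochs_sd,
         epochs_range = as.integer(epochs_range),
         age_mean = age_mean, age_sd = age_sd,
         dsqiid_mean = dsqiid_mean, dsqiid_sd = dsqiid_sd,
         epoch_length_s = epoch_length_s,
         seed = as.integer(seed)),
    class = "ms_simspec"
  )
}

#' @export
print.ms_simspec <- function(x, ...) {
  cat(sprintf(
    "<ms_simspec> %s subjects (%s), K = %d, fs = %g Hz, snr = %g, seed = %d\n",
    paste(x$n_subjects, collapse = "+"),
    paste(x$groups, collapse = "/"), x$K, x$fs, x$snr, x$seed
  ))
  invisible(x)
}

# deterministic per-subject, per-purpose substream (kept < 2^31)
subject_seed <- function(spec, subject, purpose) {
  h <- c(labels = 1L, eeg = 2L, meta = 3L)[[purpose]]
  (as.double(spec$seed) * 48271 + subject * 7919 + h * 104729) %% 2147483647
}

#' Group membership of a subject index
#'
#' Subjects are numbered 1..N across groups in the order of
#' `spec$n_subjects`; this returns the group name a given index
#' belongs to.
#'
#' @param spec An [simulation_spec()].
#' @param subject Subject index (1-based).
#' @return The group name (character).
#' @export
subject_group <- function(spec, subject) {
  idx <- rep(seq_along(spec$groups), spec$n_subjects)
  if (subject < 1 || subject > length(idx)) {
    stop("Subject index out of range", call. = FALSE)
  }
  spec$groups[idx[subject]]
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lower && v <= upper) break
    }
    out[i] <- v
  }
  out
}

# per-subject demographic and length draws (pure function of spec$seed)
subject_params <- function(spec, subject) {
  g <- subject_group(spec, subject)
  withr_seed(subject_seed(spec, subject, "meta"), {
    n_epochs <- round(rtruncnorm1(1, spec$epochs_mean[[g]],
                                  spec$epochs_sd[[g]],
                                  spec$epochs_range[1], spec$epochs_range[2]))
    age <- round(rtruncnorm1(1, spec$age_mean[[g]], spec$age_sd[[g]], 25, 75), 1)
    gender <- stats::rbinom(1, 1, 0.5)
    dsqiid <- round(rtruncnorm1(1, spec$dsqiid_mean[[g]],
                                spec$dsqiid_sd[[g]], 0, 53), 1)
    list(subject = subject, group = g, n_epochs = as.integer(n_epochs),
         age = age, gender = gender, dsqiid = dsqiid)
  })
}

#' Simulate a microstate label sequence for one subject
#'
#' Semi-Markov class dynamics: segment dwell times are gamma-distributed
#' with shape 2 and the subject group's per-class mean duration (floored
#' at 10 ms), and the next class is drawn proportionally to the group's
#' occurrence bias with self-transitions excluded. The sequence is
#' contiguous across epoch boundaries.
#'
#' @param spec An [simulation_spec()].
#' @param subject Subject index (1-based, across groups in order).
#' @param n_samples Optional sequence length; defaults to the subject's
#'   drawn epoch count times `fs`.
#' @return Integer vector of class indices (1..K), one per sample.
#' @export
simulate_labels <- function(spec, subject, n_samples = NULL) {
  stopifnot(inherits(spec, "ms_simspec"))
  g <- subject_group(spec, subject)
  if (is.null(n_samples)) {
    n_samples <- subject_params(spec, subject)$n_epochs *
      round(spec$fs * spec$epoch_length_s)
  }
  mu <- spec$mean_durations_ms[g, ]
  w <- spec$occurrence_bias[g, ]
  if (all(w <= 0)) stop("occurrence_bias must have a positive entry",
                        call. = FALSE)
  K <- spec$K
  floor_samp <- max(1L, round(10 * spec$fs / 1000))
  withr_seed(subject_seed(spec, subject, "labels"), {
    labels <- integer(n_samples)
    pos <- 1L
    cur <- sample.int(K, 1, prob = w)
    while (pos <= n_samples) {
      d_ms <- stats::rgamma(1, shape = 2, scale = mu[cur] / 2)
      len <- max(floor_samp, round(d_ms * spec$fs / 1000))
      end <- min(pos + len - 1L, n_samples)
      labels[pos:end] <- cur
      pos <- end + 1L
      if (sum(w[-cur]) > 0) {
        nxt <- sample.int(K, 1, prob = replace(w, cur, 0))
      } else {
        nxt <- cur  # single active class: no other class to move to
      }
      cur <- nxt
    }
    labels
  })
}

#' Synthesize multichannel EEG from a label sequence
#'
#' Builds `v(t) = a(t) * map[s(t), ] + e(t)`: an alpha-band sinusoid
#' with a slowly varying log-normal random envelope rides on the active
#' template topography, plus spatially correlated Gaussian noise scaled
#' so the broadband amplitude SNR (signal RMS / noise RMS over all
#' channels and samples) equals `spec$snr`. The result is
#' average-referenced per sample.
#'
#' @param templates An `ms_maps` template set with the same channel
#'   count as the montage.
#' @param labels Integer label sequence (values in 1..K).
#' @param spec An [simulation_spec()].
#' @param subject Subject index, used only to seed the noise/envelope
#'   substream.
#' @return An average-referenced [ms_recording()].
#' @export
synthesize_eeg <- function(templates, labels, spec, subject = 1) {
  stopifnot(inherits(templates, "ms_maps"), inherits(spec, "ms_simspec"))
  maps <- templates$maps
  if (nrow(maps) < max(labels)) {
    stop("Label sequence references more classes than templates",
         call. = FALSE)
  }
  Tn <- length(labels)
  C <- ncol(maps)
  fs <- spec$fs
  withr_seed(subject_seed(spec, subject, "eeg"), {
    # slowly varying envelope: log-normal interpolation of 5 Hz controls
    n_ctrl <- max(2L, ceiling(Tn / (0.2 * fs)) + 1L)
    zc <- stats::rnorm(n_ctrl, sd = 0.4)
    env <- exp(stats::approx(seq(0, Tn - 1, length.out = n_ctrl),
                             zc, xout = 0:(Tn - 1))$y)
    phase <- stats::runif(1, 0, 2 * pi)
    a <- spec$amplitude * env *
      sin(2 * pi * spec$alpha_freq * (0:(Tn - 1)) / fs + phase)
    sig <- t(maps[labels, , drop = FALSE] * a)   # C x T
    if (is.finite(spec$snr)) {
      pos <- montage_matrix(templates$montage)
      pos <- pos / sqrt(rowSums(pos^2))
      d2 <- as.matrix(stats::dist(pos))^2
      Ks <- exp(-d2 / (2 * 0.5^2)) + diag(1e-8, C)
      Lc <- t(chol(Ks))
      eps <- Lc %*% matrix(stats::rnorm(C * Tn), C, Tn)
      eps <- eps * (sqrt(mean(sig^2)) / spec$snr / sqrt(mean(eps^2)))
      v <- sig + eps
    } else {
      v <- sig
    }
    v <- sweep(v, 2, colMeans(v))
    rownames(v) <- templates$montage$channel
    ms_recording(v, fs = fs, channel_names = templates$montage$channel,
                 montage = templates$montage, reference = "average")
  })
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws every subject's metadata, label sequence and EEG under the
#' study conditions in `spec`; optionally writes one EDF per subject, a
#' metadata CSV (`subject_id,group,age,gender,dsqiid`) and a gzipped
#' one-column-per-subject ground-truth label CSV under `out_dir`.
#'
#' @param spec An [simulation_spec()].
#' @param out_dir Output directory (created if needed), or `NULL` to
#'   keep everything in memory.
#' @param templates Template set; defaults to
#'   `make_templates(spec$K, seed = spec$seed)`.
#' @param keep_recordings Keep the recordings in the returned object
#'   (default `TRUE` when `out_dir` is `NULL`).
#' @return A list of class `ms_cohort`: `metadata` tibble, `templates`,
#'   per-subject `labels`, ground-truth `features` tibble (from the
#'   true label sequences), `recordings` (optional), `files` (optional).
#' @export
generate_cohort <- function(spec, out_dir = NULL, templates = NULL,
                            keep_recordings = is.null(out_dir)) {
  stopifnot(inherits(spec, "ms_simspec"))
  if (is.null(templates)) {
    templates <- make_templates(spec$K, seed = spec$seed)
  }
  n_total <- sum(spec$n_subjects)
  write_out <- !is.null(out_dir)
  if (write_out && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  meta <- vector("list", n_total)
  labels <- vector("list", n_total)
  recs <- if (keep_recordings) vector("list", n_total) else NULL
  files <- character(0)
  for (i in seq_len(n_total)) {
    p <- subject_params(spec, i)
    sid <- sprintf("sub%02d", i)
    labels[[i]] <- simulate_labels(spec, i)
    rec <- synthesize_eeg(templates, labels[[i]], spec, subject = i)
    if (keep_recordings) recs[[i]] <- rec
    if (write_out) {
      f <- file.path(out_dir, paste0(sid, ".edf"))
      write_edf(rec, f, patient_id = sid)
      files <- c(files, f)
    }
    meta[[i]] <- tibble::tibble(
      subject_id = sid, group = p$group, age = p$age,
      gender = p$gender, dsqiid = p$dsqiid, n_epochs = p$n_epochs
    )
  }
  meta <- if (n_total > 0) {
    dplyr::bind_rows(meta)
  } else {
    tibble::tibble(subject_id = character(0), group = character(0),
                   age = numeric(0), gender = integer(0),
                   dsqiid = numeric(0), n_epochs = integer(0))
  }
  truth <- if (n_total > 0) {
    purrr::map2_dfr(labels, meta$subject_id, function(l, id) {
      ms_features(l, fs = spec$fs, K = spec$K,
                  class_labels = spec$class_labels) |>
        dplyr::mutate(subject_id = id, .before = 1)
    })
  } else {
    tibble::tibble()
  }
  if (write_out) {
    readr::write_csv(meta[, c("subject_id", "group", "age", "gender",
                              "dsqiid")],
                     file.path(out_dir, "metadata.csv"))
    if (n_total > 0) {
      maxlen <- max(lengths(labels))
      lab_df <- tibble::as_tibble(
        stats::setNames(lapply(labels, function(l) {
          c(l, rep(NA_integer_, maxlen - length(l)))
        }), meta$subject_id)
      )
      readr::write_csv(lab_df, file.path(out_dir, "true_labels.csv.gz"))
    }
  }
  structure(
    list(spec = spec, templates = templates, metadata = meta,
         labels = labels, features = truth, recordings = recs,
         files = if (write_out) files else NULL),
    class = "ms_cohort"
  )
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf("<ms_cohort> %d subjects (%s), K = %d\n",
              nrow(x$metadata),
              paste(sprintf("%s: %d", names(table(x$metadata$group)),
                            table(x$metadata$group)), collapse = ", "),
              x$spec$K))
  invisible(x)
}
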