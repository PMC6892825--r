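#' Pipeline configuration
#'
#' Aggregates every tunable setting of the end-to-end analysis:
#' preprocessing band (1-70 Hz) and notch (45-55 Hz), microstate band
#' (2-20 Hz), number of maps K, GFP-peak settings (10 ms minimum
#' distance, 2 SD amplitude exclusion, shortest-file peak cap),
#' 30 ms smoothing, permutation count, artifact threshold and subject
#' inclusion rule.
#'
#' @param preproc_band,notch_band,ms_band Filter bands (Hz).
#' @param K Number of microstate classes.
#' @param min_peak_dist_ms Minimum GFP-peak separation (ms).
#' @param sd_mult GFP-peak amplitude exclusion multiplier.
#' @param peak_cap Per-subject pooled-peak cap (`"auto"` = smallest
#'   subject's peak count).
#' @param smooth_ms Minimum microstate segment duration (ms).
#' @param n_perm Permutations for the syntax test.
#' @param amp_thresh Epoch screening peak-amplitude threshold (µV).
#' @param min_epochs Subject inclusion threshold (1-s epochs).
#' @param eyes_closed_window_s Optional cap on seconds of eyes-closed
#'   data used per subject (`NULL` = all).
#' @param syntax_by_group Run the syntax test per group (default) or
#'   pooled.
#' @param seed Integer seed for the stochastic stages.
#' @return A list of class `ms_config`.
#' @export
pipeline_config <- function(preproc_band = c(1, 70),
                            notch_band = c(45, 55),
                            ms_band = c(2, 20),
                            K = 4,
                            min_peak_dist_ms = 10,
                            sd_mult = 2,
                            peak_cap = "auto",
                            smooth_ms = 30,
                            n_perm = 5000,
                            amp_thresh = 100,
                            min_epochs = 30,
                            eyes_closed_window_s = NULL,
                            syntax_by_group = TRUE,
                            seed = 1L) {
  cfg <- list(preproc_band = preproc_band, notch_band = notch_band,
              ms_band = ms_band, K = as.integer(K),
              min_peak_dist_ms = min_peak_dist_ms, sd_mult = sd_mult,
              peak_cap = peak_cap, smooth_ms = smooth_ms,
              n_perm = as.integer(n_perm), amp_thresh = amp_thresh,
              min_epochs = as.integer(min_epochs),
              eyes_closed_window_s = eyes_closed_window_s,
              syntax_by_group = isTRUE(syntax_by_group),
              seed = as.integer(seed))
  stopifnot(cfg$K >= 2, cfg$K <= 8, cfg$min_peak_dist_ms > 0,
            cfg$smooth_ms >= 0, cfg$n_perm >= 1, cfg$amp_thresh > 0,
            cfg$min_epochs >= 0)
  structure(cfg, class = "ms_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are
#'   [pipeline_config()] arguments.
#' @return An `ms_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(pipeline_config)))
  do.call(pipeline_config, vals[keep])
}

#' Preprocess one recording to concatenated clean eyes-closed data
#'
#' 1-70 Hz bandpass, 45-55 Hz bandstop, common average reference,
#' optional eyes-closed windowing, 1-s epoching, amplitude screening
#' with spherical-spline channel repair, subject inclusion check, and
#' concatenation with retained epoch boundaries.
#'
#' @param rec An [ms_recording()].
#' @param config An [pipeline_config()].
#' @return A list: `recording` (concatenated, average-referenced; NULL
#'   when the subject is excluded), `included`, `kept_epochs`,
#'   `screen_log`.
#' @export
preprocess_subject <- function(rec, config = pipeline_config()) {
  assert_recording(rec)
  rec <- bandpass(rec, config$preproc_band[1], config$preproc_band[2])
  rec <- bandstop(rec, config$notch_band[1], config$notch_band[2])
  rec <- average_reference(rec)
  if (!is.null(config$eyes_closed_window_s)) {
    onset <- round(rec$eyes_closed_onset_s * rec$fs)
    span <- round(config$eyes_closed_window_s * rec$fs)
    idx <- seq(onset + 1, min(onset + span, n_samples(rec)))
    rec$data <- rec$data[, idx, drop = FALSE]
  }
  es <- epoch_1s(rec)
  es <- screen_epochs(es, amp_thresh = config$amp_thresh)
  inc <- include_subject(es, min_epochs = config$min_epochs)
  list(
    recording = if (inc) average_reference(concatenate(es)) else NULL,
    included = inc,
    kept_epochs = es$kept,
    screen_log = es$log
  )
}

#' Run the full microstate analysis
#'
#' Executes simulate (optional) -> preprocess -> microstate-band
#' filtering -> GFP-peak extraction -> pooled TAAHC segmentation ->
#' archetype ordering -> back-fitting with smoothing -> features and
#' transition tables -> syntax permutation test -> group statistics,
#' and optionally writes all tabular outputs plus a reproducibility
#' manifest to `out_dir`.
#'
#' @param config An [pipeline_config()].
#' @param spec An [simulation_spec()] to generate the cohort (its seed
#'   governs the data; `config$seed` governs the permutation test), or
#'   `NULL` to read EDFs from `in_dir`.
#' @param in_dir Directory holding per-subject `.edf` files and a
#'   `metadata.csv` (used when `spec` is `NULL`).
#' @param out_dir Optional output directory.
#' @param keep_recordings Keep the per-subject microstate-band
#'   recordings in the result (needed only for downstream inspection).
#' @return A list of class `ms_pipeline`: `maps` (ordered `ms_maps`),
#'   `features` (tidy tibble incl. per-subject GEV), `transitions`,
#'   `syntax`, `report`, `labels` (per-subject `ms_labels`),
#'   `kept_epochs`, `metadata`, `config`, and `cohort` when simulated.
#' @export
run_pipeline <- function(config = pipeline_config(), spec = NULL,
                         in_dir = NULL, out_dir = NULL,
                         keep_recordings = FALSE) {
  stopifnot(inherits(config, "ms_config"))
  cohort <- NULL
  if (!is.null(spec)) {
    cohort <- generate_cohort(spec, keep_recordings = TRUE)
    recs <- cohort$recordings
    cohort$recordings <- NULL   # per-subject release below frees the data
    meta <- cohort$metadata
  } else {
    if (is.null(in_dir)) stop("Need `spec` or `in_dir`", call. = FALSE)
    meta <- readr::read_csv(file.path(in_dir, "metadata.csv"),
                            show_col_types = FALSE)
    recs <- lapply(meta$subject_id, function(sid) {
      read_edf(file.path(in_dir, paste0(sid, ".edf")))
    })
  }
  n <- length(recs)

  # stage 1-2: preprocessing + microstate band + GFP peaks, per subject
  ms_recs <- vector("list", n)
  peaks <- vector("list", n)
  kept <- vector("list", n)
  included <- logical(n)
  for (i in seq_len(n)) {
    pp <- preprocess_subject(recs[[i]], config)
    included[i] <- pp$included
    kept[[i]] <- pp$kept_epochs
    if (!pp$included) next
    mrec <- average_reference(
      bandpass(pp$recording, config$ms_band[1], config$ms_band[2])
    )
    ms_recs[[i]] <- mrec
    peaks[[i]] <- extract_gfp_peaks(
      mrec, min_dist_ms = config$min_peak_dist_ms,
      sd_mult = config$sd_mult, subject_id = meta$subject_id[i]
    )
    recs[i] <- list(NULL)   # release raw data as we go
  }
  if (!any(included)) stop("No subject passed inclusion", call. = FALSE)
  inc_idx <- which(included)
  meta_inc <- meta[inc_idx, , drop = FALSE]

  # stage 3: pooled TAAHC segmentation + archetype ordering
  pooled <- pool_peaks(peaks[inc_idx], per_subject_cap = config$peak_cap)
  seg <- taahc(pooled, K_target = config$K)
  canonical <- make_templates(config$K, seed = 1, jitter = 0)
  maps <- order_maps(seg, canonical)

  # stage 4: back-fitting, smoothing, features, transitions
  labels <- vector("list", n)
  feats <- vector("list", n)
  trans <- vector("list", n)
  for (i in inc_idx) {
    ls <- smooth_labels(backfit(maps, ms_recs[[i]]),
                        min_ms = config$smooth_ms)
    gv <- gev(ms_recs[[i]], maps, ls)
    feats[[i]] <- ms_features(ls) |>
      dplyr::mutate(subject_id = meta$subject_id[i],
                    gev = gv$gev, .before = 1)
    trans[[i]] <- transition_table(ls, subject_id = meta$subject_id[i])
    labels[[i]] <- ls
    if (!keep_recordings) ms_recs[i] <- list(NULL)
  }
  features <- dplyr::bind_rows(feats[inc_idx])

  # stage 5: syntax permutation test (per group by default)
  syntax <- if (config$syntax_by_group) {
    purrr::map_dfr(unique(meta_inc$group), function(g) {
      idx <- inc_idx[meta_inc$group == g]
      syntax_permutation_test(trans[idx], n_perm = config$n_perm,
                              seed = config$seed) |>
        dplyr::mutate(group = g, .before = 1)
    })
  } else {
    syntax_permutation_test(trans[inc_idx], n_perm = config$n_perm,
                            seed = config$seed) |>
      dplyr::mutate(group = "all", .before = 1)
  }

  # stage 6: group statistics
  report <- ms_report(features, meta_inc, out_dir = out_dir)

  trans_long <- purrr::map_dfr(trans[inc_idx], function(tt) {
    K <- nrow(tt$observed)
    cl <- rownames(tt$observed)
    grid <- expand.grid(from = seq_len(K), to = seq_len(K))
    grid <- grid[grid$from != grid$to, ]
    tibble::tibble(subject_id = tt$subject_id,
                   from = cl[grid$from], to = cl[grid$to],
                   observed = tt$observed[cbind(grid$from, grid$to)],
                   expected = tt$expected[cbind(grid$from, grid$to)])
  })

  out <- structure(
    list(maps = maps, features = features, transitions = trans_long,
         transition_tables = trans[inc_idx], syntax = syntax,
         report = report, labels = labels, kept_epochs = kept,
         included = included, metadata = meta, config = config,
         pooled_cap = pooled$cap, cohort = cohort,
         ms_recordings = if (keep_recordings) ms_recs else NULL),
    class = "ms_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mp <- res$maps$maps
  readr::write_csv(
    tibble::as_tibble(mp, rownames = "class"),
    file.path(out_dir, "maps.csv")
  )
  readr::write_csv(res$features, file.path(out_dir, "features.csv"))
  readr::write_csv(res$transitions, file.path(out_dir, "transitions.csv"))
  readr::write_csv(res$syntax, file.path(out_dir, "syntax.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("microstatr")),
    r_version = R.version.string,
    config = unclass(res$config),
    n_subjects = nrow(res$metadata),
    n_included = sum(res$included),
    pooled_peak_cap = res$pooled_cap,
    map_archetype_corr = as.numeric(attr(res$maps, "match_corr"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ms_pipeline <- function(x, ...) {
  cat(sprintf(
    "<ms_pipeline> %d/%d subjects, K = %d, mean GEV = %.1f%%\n",
    sum(x$included), length(x$included), x$config$K,
    100 * mean(unique(x$features[, c("subject_id", "gev")])$gev)
  ))
  invisible(x)
}

#' Score a pipeline run against the planted ground truth
#'
#' For a simulated cohort: sample-wise label accuracy (after archetype
#' ordering, over the epochs that survived screening) and the
#' correlation of every recovered map with its planted template.
#'
#' @param res An `ms_pipeline` run with `spec` (so `res$cohort` holds
#'   the truth).
#' @return A list: `map_corr` (per class), `accuracy` (overall
#'   sample-wise), `per_subject` tibble.
#' @export
evaluate_against_truth <- function(res) {
  stopifnot(inherits(res, "ms_pipeline"))
  if (is.null(res$cohort)) {
    stop("Pipeline was not run on a simulated cohort", call. = FALSE)
  }
  tpl <- res$cohort$templates$maps
  est <- res$maps$maps
  map_corr <- vapply(seq_len(nrow(tpl)), function(k) {
    spatial_correlation(tpl[k, ], est[k, ])
  }, 0)
  names(map_corr) <- rownames(tpl)
  fs <- res$cohort$spec$fs
  L <- round(fs * res$cohort$spec$epoch_length_s)
  per_subject <- purrr::map_dfr(which(res$included), function(i) {
    truth <- res$cohort$labels[[i]]
    keep <- res$kept_epochs[[i]]
    truth_kept <- unlist(lapply(keep, function(e) {
      truth[((e - 1) * L + 1):(e * L)]
    }))
    pred <- res$labels[[i]]$labels
    tibble::tibble(subject_id = res$metadata$subject_id[i],
                   n = length(pred),
                   accuracy = mean(pred == truth_kept))
  })
  list(map_corr = map_corr,
       accuracy = sum(per_subject$accuracy * per_subject$n) /
         sum(per_subject$n),
       per_subject = per_subject)
}
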