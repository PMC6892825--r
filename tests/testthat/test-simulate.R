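test_that("segment dwell times reproduce the requested mean duration", {
  spec <- simulation_spec(
    n_subjects = c(DS = 1L),
    mean_durations_ms = matrix(80, 1, 4, dimnames = list("DS", NULL)),
    occurrence_bias = matrix(1, 1, 4, dimnames = list("DS", NULL)),
    seed = 5
  )
  labels <- simulate_labels(spec, 1, n_samples = 60000)   # 60 x 1-s epochs
  runs <- run_length_encode(labels)
  # drop the truncated final run
  mean_ms <- mean(runs$length[-nrow(runs)])
  expect_lt(abs(mean_ms - 80) / 80, 0.10)
})

test_that("a single active class yields a constant label sequence", {
  spec <- simulation_spec(
    n_subjects = c(DS = 1L),
    occurrence_bias = matrix(c(1, 0, 0, 0), 1, 4,
                             dimnames = list("DS", NULL)),
    seed = 2
  )
  labels <- simulate_labels(spec, 1, n_samples = 5000)
  expect_true(all(labels == 1))
})

test_that("label simulation is seeded and deterministic", {
  spec <- tiny_spec(seed = 9)
  expect_identical(simulate_labels(spec, 2), simulate_labels(spec, 2))
  expect_false(identical(simulate_labels(spec, 1), simulate_labels(spec, 2)))
})

test_that("synthesized EEG is average-referenced and map-faithful", {
  spec <- tiny_spec(seed = 4, snr = Inf)
  tpl <- make_templates(4, seed = 4)
  labels <- simulate_labels(spec, 1, n_samples = 4000)
  rec <- synthesize_eeg(tpl, labels, spec, subject = 1)
  expect_equal(max(abs(colMeans(rec$data))), 0, tolerance = 1e-9)
  # noiseless limit: back-fitting the true templates recovers the truth
  # at every GFP peak
  pk <- find_gfp_peaks(gfp(rec))
  bf <- backfit(tpl, rec)
  expect_true(all(bf$labels[pk] == labels[pk]))
})

test_that("at snr 4 the GFP-peak topographies track the active map", {
  spec <- tiny_spec(seed = 6, snr = 4)
  tpl <- make_templates(4, seed = 6)
  labels <- simulate_labels(spec, 1, n_samples = 60000)   # 60 s
  rec <- synthesize_eeg(tpl, labels, spec, subject = 1)
  pk <- find_gfp_peaks(gfp(rec))
  r <- vapply(as.integer(pk), function(i) {
    spatial_correlation(rec$data[, i], tpl$maps[labels[i], ])
  }, 0)
  expect_gt(median(r), 0.8)
})

test_that("the default cohort matches the study group sizes on disk", {
  spec <- tiny_spec(n = c(DS = 10L, `DS-AD` = 15L), seed = 8, epochs = 30)
  dir <- withr::local_tempdir()
  co <- generate_cohort(spec, out_dir = dir, keep_recordings = FALSE)
  expect_length(list.files(dir, pattern = "\\.edf$"), 25)
  expect_equal(nrow(co$metadata), 25)
  expect_equal(as.integer(table(co$metadata$group)[c("DS", "DS-AD")]),
               c(10L, 15L))
  meta <- readr::read_csv(file.path(dir, "metadata.csv"),
                          show_col_types = FALSE)
  expect_named(meta, c("subject_id", "group", "age", "gender", "dsqiid"))
  # DS-AD draws DSQIID from the higher distribution
  expect_gt(mean(meta$dsqiid[meta$group == "DS-AD"]),
            mean(meta$dsqiid[meta$group == "DS"]))
})

test_that("an empty cohort is produced without error", {
  spec <- tiny_spec(n = c(DS = 0L, `DS-AD` = 0L), seed = 1)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$metadata), 0)
  expect_length(co$labels, 0)
})

test_that("cohort metadata files are byte-identical across runs", {
  spec <- tiny_spec(n = c(DS = 2L), seed = 13, epochs = 30)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(spec, out_dir = d1, keep_recordings = FALSE)
  generate_cohort(spec, out_dir = d2, keep_recordings = FALSE)
  expect_identical(unname(tools::md5sum(file.path(d1, "metadata.csv"))),
                   unname(tools::md5sum(file.path(d2, "metadata.csv"))))
})

test_that("ground-truth features satisfy the coverage identities", {
  spec <- tiny_spec(seed = 21, epochs = 31)
  co <- generate_cohort(spec, keep_recordings = FALSE)
  sums <- co$features |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(cov = sum(coverage))
  expect_equal(sums$cov, rep(1, nrow(sums)), tolerance = 1e-12)
  expect_equal(co$features$duration_ms * co$features$occurrence_hz / 1000,
               co$features$coverage, tolerance = 1e-12)
})

test_that("the simulation spec enforces its domain constraints", {
  expect_error(simulation_spec(n_subjects = c(3L)), "named")
  expect_error(tiny_spec(snr = 0), "snr")
  expect_error(simulation_spec(epochs_range = c(10, 170)))
  bad_dur <- matrix(-1, 2, 4, dimnames = list(c("DS", "DS-AD"), NULL))
  expect_error(simulation_spec(mean_durations_ms = bad_dur))
})
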