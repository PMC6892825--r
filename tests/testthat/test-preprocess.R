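test_that("the microstate band keeps 10 Hz and rejects 50 Hz", {
  in50 <- sine_recording(50)
  in10 <- sine_recording(10)
  out50 <- bandpass(in50, 2, 20)
  out10 <- bandpass(in10, 2, 20)
  expect_lt(central_rms(out50$data[10, ]), 0.05 * central_rms(in50$data[10, ]))
  expect_equal(central_rms(out10$data[10, ]),
               central_rms(in10$data[10, ]), tolerance = 0.05)
  # a DC offset lies outside the 1-70 Hz band
  dc <- rec_from(matrix(5, 19, 8000))
  expect_lt(max(abs(bandpass(dc, 1, 70)$data[, 2000:6000])), 0.05)
})

test_that("the 45-55 Hz notch removes line noise and passes alpha", {
  out50 <- bandstop(sine_recording(50), 45, 55)
  out10 <- bandstop(sine_recording(10), 45, 55)
  atten_db <- 20 * log10(central_rms(sine_recording(50)$data[10, ]) /
                           central_rms(out50$data[10, ]))
  expect_gt(atten_db, 20)
  expect_equal(central_rms(out10$data[10, ]),
               central_rms(sine_recording(10)$data[10, ]), tolerance = 0.05)
  z <- bandstop(rec_from(matrix(0, 19, 5000)))
  expect_equal(max(abs(z$data)), 0)
})

test_that("filtering is zero-phase", {
  rec <- sine_recording(10, dur_s = 10)
  out <- bandpass(rec, 2, 20)
  mid <- 3000:7000
  cc <- ccf(out$data[10, mid], rec$data[10, mid], lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band edges outside Nyquist are rejected", {
  rec <- sine_recording(10, dur_s = 2)
  expect_error(bandpass(rec, 2, 600), "Nyquist|fs/2")
  expect_error(bandpass(rec, -1, 20), "fs/2")
})

test_that("average referencing removes offsets, is idempotent and closed-form", {
  x <- matrix(rnorm(19 * 100), 19, 100) + seq_len(19)
  rec <- average_reference(rec_from(x))
  expect_equal(max(abs(colMeans(rec$data))), 0, tolerance = 1e-12)
  again <- average_reference(rec)
  expect_equal(again$data, rec$data, tolerance = 1e-12)
  two <- average_reference(ms_recording(rbind(a = c(4, 2), b = c(0, 6)),
                                        fs = 10))
  expect_equal(unname(two$data), rbind(c(2, -2), c(-2, 2)))
  expect_error(average_reference(ms_recording(matrix(1, 1, 10), fs = 10)),
               "at least 2")
})

test_that("1-s epoching floors to whole epochs", {
  expect_length(epoch_1s(rec_from(matrix(rnorm(19 * 30700), 19))), 30)
  expect_length(epoch_1s(rec_from(matrix(rnorm(19 * 1000), 19))), 1)
  expect_length(epoch_1s(rec_from(matrix(rnorm(19 * 500), 19))), 0)
})

test_that("epoch screening interpolates up to 2 bad channels and rejects 3+", {
  set.seed(31)
  tpl <- make_templates(4, seed = 2)
  base <- 10 * tpl$maps[1, ] %o% sin(2 * pi * 10 * (0:999) / 1000)
  es <- epoch_1s(rec_from(cbind(base, base, base)))

  spiked <- es
  spiked$epochs[[2]][5, 300] <- 500            # one bad channel
  spiked$epochs[[3]][c(1, 7, 12), 100] <- 500  # three bad channels
  out <- screen_epochs(spiked, amp_thresh = 100)
  expect_equal(out$kept, c(1L, 2L))
  expect_equal(out$log$action, c("clean", "interpolated", "rejected"))
  # the interpolated channel no longer holds the spike and approximates
  # the underlying smooth topography
  expect_lt(max(abs(out$epochs[[2]][5, ])), 100)
  rel <- abs(out$epochs[[2]][5, 300] - base[5, 300])
  expect_lt(rel, 0.15 * max(abs(base[, 300])))

  # a threshold above all amplitudes is the identity
  clean <- screen_epochs(es, amp_thresh = 1e6)
  expect_equal(clean$epochs, es$epochs)
  expect_error(screen_epochs(es, amp_thresh = 0), "positive")
})

test_that("spherical-spline interpolation reconstructs smooth topographies", {
  tpl <- make_templates(4, seed = 9)
  topo <- 10 * tpl$maps[2, ]
  epoch <- matrix(topo, 19, 5)
  out <- spherical_interpolate(epoch, bad = 4, montage = montage_1020())
  expect_lt(abs(out[4, 1] - topo[4]), 0.15 * max(abs(topo)))
  expect_equal(out[-4, ], epoch[-4, ])              # good channels untouched
  expect_identical(spherical_interpolate(epoch, integer(0), montage_1020()),
                   epoch)                           # no bad channels: identity
  const <- matrix(3.7, 19, 2)
  out_c <- spherical_interpolate(const, bad = 10, montage = montage_1020())
  expect_equal(out_c[10, ], c(3.7, 3.7), tolerance = 1e-6)
  expect_error(
    spherical_interpolate(epoch, bad = 1:16, montage = montage_1020()),
    "Too few good"
  )
})

test_that("subjects need at least 30 surviving epochs", {
  mk <- function(n) ms_epochs(replicate(n, matrix(0, 2, 10),
                                        simplify = FALSE), fs = 10)
  expect_true(include_subject(mk(30)))
  expect_false(include_subject(mk(29)))
  expect_false(include_subject(mk(0)))
})

test_that("concatenation preserves order and records epoch boundaries", {
  ramps <- lapply(1:30, function(i) matrix(i + (0:999) / 1000, 19, 1000,
                                           byrow = TRUE))
  es <- ms_epochs(ramps, fs = 1000,
                  channel_names = montage_1020()$channel)
  rec <- concatenate(es)
  expect_equal(ncol(rec$data), 30000)
  expect_length(rec$boundaries, 30)       # 29 interior + the first sample
  expect_equal(sum(rec$boundaries > 1), 29)
  expect_equal(rec$data[1, ], unlist(lapply(1:30, function(i) {
    i + (0:999) / 1000
  })))
  one <- concatenate(ms_epochs(ramps[1], fs = 1000))
  expect_equal(unname(one$data), ramps[[1]])
  expect_equal(sum(one$boundaries > 1), 0)
  expect_error(concatenate(ms_epochs(list(), fs = 1000)), "empty")
})
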