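test_that("run-length encoding is lossless", {
  expect_equal(run_length_encode(c(1, 1, 2, 2, 1)),
               tibble::tibble(class = c(1, 2, 1), start = c(1L, 3L, 5L),
                              length = c(2L, 2L, 1L)))
  expect_equal(nrow(run_length_encode(rep(3L, 10))), 1)
  for (s in 1:10) {
    set.seed(s)
    x <- sample.int(4, 200, replace = TRUE)
    expect_identical(run_length_decode(run_length_encode(x)), x)
  }
  expect_error(run_length_encode(integer(0)), "Empty")
})

test_that("duration, occurrence and coverage follow their definitions", {
  # 1 s at 1 kHz alternating 100-sample runs A,B,A,B,...
  lab <- rep(rep(1:2, 5), each = 100)
  f <- ms_features(lab, fs = 1000, K = 2)
  expect_equal(f$duration_ms, c(100, 100))
  expect_equal(f$occurrence_hz, c(5, 5))
  expect_equal(f$coverage, c(0.5, 0.5))

  allA <- ms_features(rep(1L, 2500), fs = 1000, K = 4)
  expect_equal(allA$coverage, c(1, 0, 0, 0))
  expect_equal(allA$occurrence_hz[1], 1 / 2.5)
  expect_equal(allA$duration_ms[2], 0)
  expect_false(allA$present[2])

  # duration x occurrence / 1000 = coverage on arbitrary sequences
  for (s in 1:10) {
    set.seed(s)
    x <- sample.int(4, 500, replace = TRUE)
    f2 <- ms_features(x, fs = 250, K = 4)
    expect_equal(f2$duration_ms * f2$occurrence_hz / 1000, f2$coverage,
                 tolerance = 1e-12)
    expect_equal(sum(f2$coverage), 1, tolerance = 1e-12)
  }
})

test_that("observed transition probabilities are globally normalised", {
  # A,B,A,B runs: counts A->B twice, B->A once
  lab <- rep(c(1, 2, 1, 2), each = 10)
  M <- observed_transitions(lab, K = 2)
  expect_equal(M[1, 2], 2 / 3)
  expect_equal(M[2, 1], 1 / 3)

  # 1,2,3 cycling 4 times: 11 run transitions = 4 + 4 + 3
  cyc <- rep(rep(1:3, 4), each = 5)
  Mc <- observed_transitions(cyc, K = 3)
  expect_equal(sum(Mc > 0), 3)
  expect_equal(Mc[1, 2], 4 / 11)
  expect_equal(Mc[2, 3], 4 / 11)
  expect_equal(Mc[3, 1], 3 / 11)
  expect_equal(unname(diag(Mc)), rep(0, 3))
  expect_equal(sum(Mc), 1)
  expect_error(observed_transitions(rep(1L, 10), K = 2), "at least 2 runs")
})

test_that("expected transitions implement the occurrence-independence null", {
  E <- expected_transitions(rep(2.5, 4))
  off <- row(E) != col(E)
  expect_equal(E[off], rep(1 / 12, 12))

  E2 <- expected_transitions(c(0.5, 0.5, 0, 0))
  expect_equal(E2[1, 2], 0.5)
  expect_equal(E2[2, 1], 0.5)
  expect_equal(sum(E2), 1)

  set.seed(3)
  E3 <- expected_transitions(runif(5))
  expect_equal(sum(E3), 1, tolerance = 1e-12)
  expect_equal(unname(diag(E3)), rep(0, 5))
  expect_error(expected_transitions(c(0, 0)), "not all zero")
})

test_that("the chi-square distance matches hand arithmetic", {
  E <- expected_transitions(rep(1, 4))
  expect_equal(chi_square_distance(E, E), 0)

  obs <- matrix(0, 2, 2); obs[1, 2] <- 0.6; obs[2, 1] <- 0.4
  exp_ <- matrix(0, 2, 2); exp_[1, 2] <- 0.5; exp_[2, 1] <- 0.5
  expect_equal(chi_square_distance(obs, exp_), 0.01 / 0.5 * 2)

  set.seed(4)
  O <- expected_transitions(runif(4)); E4 <- expected_transitions(runif(4))
  expect_gte(chi_square_distance(O, E4), 0)
  bad <- exp_; bad[1, 2] <- 0
  expect_error(chi_square_distance(obs, bad), "zero-expectation")
})

test_that("the syntax permutation test is degenerate-safe and seeded", {
  set.seed(10)
  tabs <- null_transition_tables(8)
  same <- lapply(tabs, function(tt) {
    list(observed = tt$expected, expected = tt$expected,
         subject_id = tt$subject_id)
  })
  res <- syntax_permutation_test(same, n_perm = 200, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  r1 <- syntax_permutation_test(tabs, n_perm = 500, seed = 42)
  r2 <- syntax_permutation_test(tabs, n_perm = 500, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(syntax_permutation_test(tabs, n_perm = 0), "n_perm")
  expect_error(syntax_permutation_test(tabs[1]))
})

test_that("transition tables couple observed counts with occurrence nulls", {
  set.seed(11)
  lab <- sample.int(4, 3000, replace = TRUE)
  tt <- transition_table(lab, fs = 1000, K = 4, subject_id = "s1")
  expect_s3_class(tt, "ms_transitions")
  expect_equal(sum(tt$observed), 1)
  expect_equal(sum(tt$expected), 1)
  expect_equal(unname(diag(tt$observed)), rep(0, 4))
  expect_equal(unname(diag(tt$expected)), rep(0, 4))
})
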