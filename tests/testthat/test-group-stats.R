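test_that("the exact rank-sum p-value matches brute-force enumeration", {
  a <- c(1.1, 2.3, 9.7)
  b <- c(3.2, 4.4, 5.1, 6.9)
  res <- rank_sum_test(a, b)
  expect_equal(res$method, "exact")
  # enumerate all assignments of ranks to group a
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[1:3]) - 3 * 4 / 2
  combs <- utils::combn(7, 3)
  ws <- apply(combs, 2, function(ix) sum(r[ix])) - 3 * 4 / 2
  mu <- mean(ws)
  p_exact <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  expect_equal(res$statistic, w_obs)

  # symmetric nesting: statistic at its null mean, p = 1
  expect_equal(rank_sum_test(c(1, 4), c(2, 3))$p_value, 1)
  # shift invariance of the statistic
  expect_equal(rank_sum_test(a + 100, b + 100)$statistic, res$statistic)
  # large / tied samples fall back to the normal approximation
  expect_equal(rank_sum_test(rep(1:6, 2), rep(4:9, 2))$method,
               "normal approximation")
  expect_error(rank_sum_test(numeric(0), b), "non-empty")
})

test_that("log-ANCOVA without informative covariates reduces to a t-test", {
  set.seed(21)
  d <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:24),
    group = rep(c("DS", "DS-AD"), each = 12),
    age = 50,                      # zero variance: must be dropped
    gender = "F",                  # zero variance: must be dropped
    duration_ms = exp(rnorm(24, mean = log(70), sd = 0.2) +
                        rep(c(0, 0.3), each = 12))
  )
  fit <- ms_ancova(d, "duration_ms")
  tt <- t.test(log(duration_ms) ~ group, data = d, var.equal = TRUE)
  expect_equal(fit$result$p_value, tt$p.value, tolerance = 1e-9)
  expect_equal(abs(fit$result$estimate),
               abs(diff(rev(tt$estimate))), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit$result$dropped, "age+gender")
  expect_equal(fit$result$covariates, "")
  expect_equal(fit$result$df, 22)
})

test_that("log-ANCOVA recovers a planted multiplicative group effect", {
  set.seed(22)
  n <- 2000
  d <- tibble::tibble(
    group = rep(c("a", "b"), each = n / 2),
    age = rnorm(n, 50, 8),
    gender = sample(c("F", "M"), n, replace = TRUE),
    y = exp(log(70) + 0.01 * (rnorm(n, 50, 8) - 50) +
              rep(c(0, log(1.3)), each = n / 2) + rnorm(n, sd = 0.2))
  )
  fit <- ms_ancova(d, "y")
  expect_lt(abs(fit$result$estimate - log(1.3)), 0.05)
  expect_lt(fit$result$p_value, 1e-10)

  # null: no effect, estimate near zero
  d0 <- d
  d0$y <- exp(log(70) + rnorm(n, sd = 0.2))
  fit0 <- ms_ancova(d0, "y")
  expect_lt(abs(fit0$result$estimate), 0.1)

  # tidy / glance accessors
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, n)
})

test_that("log-ANCOVA rejects non-positive responses naming the subject", {
  d <- tibble::tibble(subject_id = c("s1", "s2", "s3", "s4"),
                      group = c("a", "a", "b", "b"),
                      age = c(40, 50, 60, 70), gender = c("F", "M", "F", "M"),
                      y = c(1, 0, 2, 3))
  expect_error(ms_ancova(d, "y"), "s2")
  d$y <- c(1, 2, 3, 4)
  d$group <- "a"
  expect_error(ms_ancova(d, "y"), "2 levels")
})

test_that("Spearman correlation matches rank arithmetic", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10)^3)$rho, -1)
  # hand-computed rho = 1 - 6*sum(d^2)/(n(n^2-1)) without ties
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  d2 <- sum((rank(x) - rank(y))^2)
  expect_equal(spearman(x, y)$rho, 1 - 6 * d2 / (5 * 24))
  expect_equal(spearman(x, y)$rho, 0.8)
  # invariance under a monotone transform of either argument
  set.seed(23)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman(exp(a), b)$rho, spearman(a, b)$rho)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:4, 1:3), "equal-length")
})

test_that("the group report summarises features and runs the comparisons", {
  set.seed(24)
  n <- 16
  meta <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("DS", "DS-AD"), each = n / 2),
    age = round(rnorm(n, 50, 5)),
    gender = sample(c("F", "M"), n, replace = TRUE),
    dsqiid = c(round(runif(n / 2, 0, 8)), round(runif(n / 2, 15, 30)))
  )
  features <- tidyr::expand_grid(subject_id = meta$subject_id,
                                 class = c("A", "B", "C", "D")) |>
    dplyr::mutate(duration_ms = exp(rnorm(n * 4, log(75), 0.15)),
                  occurrence_hz = exp(rnorm(n * 4, log(3), 0.15)),
                  coverage = runif(n * 4, 0.1, 0.4))
  rep1 <- ms_report(features, meta)
  expect_s3_class(rep1, "ms_report")
  expect_equal(nrow(rep1$table), 3)   # two group rows + p-value row
  expect_equal(rep1$table$group, c("DS", "DS-AD", "p-value"))
  expect_equal(ncol(rep1$table), 1 + 3 * 4)
  expect_equal(nrow(rep1$ancova), 12)
  expect_true(all(rep1$ancova$p_value >= 0 & rep1$ancova$p_value <= 1))
  expect_equal(rep1$correlations$class, c("A", "D"))
  expect_named(rep1$scatter, c("A", "D"))

  # hand-check one table cell
  durA_DS <- features$duration_ms[features$class == "A" &
                                    features$subject_id %in%
                                    meta$subject_id[meta$group == "DS"]]
  expect_equal(rep1$table$duration_A[1],
               sprintf("%.2f (%.2f)", mean(durA_DS), sd(durA_DS)))

  # determinism
  rep2 <- ms_report(features, meta)
  expect_identical(rep1$table, rep2$table)

  # files written on request (skip PNG rendering cost by checking CSVs)
  td <- withr::local_tempdir()
  ms_report(features, meta, out_dir = td)
  expect_true(all(file.exists(file.path(
    td, c("table1.csv", "ancova.csv", "correlations.csv",
          "dsqiid_duration_A.png", "dsqiid_duration_D.png")
  ))))

  expect_error(ms_report(features, meta[-1, ]), "missing from metadata")
})
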