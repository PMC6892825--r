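#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Wilcoxon rank-sum test: exact enumeration when both
#' samples have at most 10 observations and no ties, otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return A tibble with `statistic` (W), `p_value`, `method`.
#' @export
rank_sum_test <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("Both samples must be non-empty", call. = FALSE)
  }
  no_ties <- !anyDuplicated(c(values_a, values_b))
  exact <- length(values_a) <= 10 && length(values_b) <= 10 && no_ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 method = if (exact) "exact" else "normal approximation")
}

#' Log-scale ANCOVA of a microstate feature on group
#'
#' Ordinary least squares of `log(value)` on the group indicator plus
#' covariates (age and gender by default). The group effect is
#' reported as its coefficient (log scale), t statistic and two-sided
#' p-value from the residual-df t distribution. Covariates with zero
#' variance are dropped (and flagged) rather than breaking the fit.
#'
#' @param data Data frame with one row per subject.
#' @param response Name of the (strictly positive) feature column.
#' @param group Name of the two-level group column.
#' @param covariates Character vector of covariate column names.
#' @return An object of class `ms_ancova` (also a fitted `lm` in
#'   `$fit`); use [generics::tidy()] / [generics::glance()] or read
#'   `$result` (tibble: `response`, `estimate`, `statistic`,
#'   `p_value`, `df`, `covariates`, `dropped`).
#' @export
ms_ancova <- function(data, response, group = "group",
                      covariates = c("age", "gender")) {
  stopifnot(is.data.frame(data), response %in% names(data),
            group %in% names(data))
  y <- data[[response]]
  if (any(!is.finite(y)) || any(y <= 0)) {
    bad <- which(!is.finite(y) | y <= 0)
    id <- if ("subject_id" %in% names(data)) {
      data$subject_id[bad]
    } else bad
    stop("Non-positive feature value for subject(s): ",
         paste(id, collapse = ", "), " (log-ANCOVA requires > 0)",
         call. = FALSE)
  }
  gl <- unique(data[[group]])
  if (length(gl) != 2) {
    stop("`group` must have exactly 2 levels", call. = FALSE)
  }
  if (any(table(data[[group]]) < 2)) {
    stop("Need at least 2 subjects per group", call. = FALSE)
  }
  covariates <- intersect(covariates, names(data))
  dropped <- covariates[vapply(covariates, function(cv) {
    length(unique(data[[cv]])) < 2
  }, logical(1))]
  used <- setdiff(covariates, dropped)
  df_fit <- data.frame(
    .logy = log(y),
    .group = factor(data[[group]], levels = sort(as.character(gl)))
  )
  for (cv in used) {
    df_fit[[cv]] <- if (is.numeric(data[[cv]])) {
      data[[cv]]
    } else {
      factor(data[[cv]])
    }
  }
  fm <- stats::reformulate(c(".group", used), response = ".logy")
  fit <- stats::lm(fm, data = df_fit)
  cf <- summary(fit)$coefficients
  grow <- grep("^\\.group", rownames(cf))
  if (length(grow) != 1 || anyNA(stats::coef(fit))) {
    stop("Rank-deficient design: group effect not estimable", call. = FALSE)
  }
  result <- tibble::tibble(
    response = response,
    estimate = cf[grow, "Estimate"],
    statistic = cf[grow, "t value"],
    p_value = cf[grow, "Pr(>|t|)"],
    df = fit$df.residual,
    covariates = paste(used, collapse = "+"),
    dropped = paste(dropped, collapse = "+")
  )
  structure(list(fit = fit, result = result, response = response,
                 reference_level = levels(df_fit$.group)[1]),
            class = "ms_ancova")
}

#' @export
print.ms_ancova <- function(x, ...) {
  cat(sprintf(
    "<ms_ancova> log(%s) ~ group%s: beta = %.4f, t = %.3f, p = %.4g (df = %d)\n",
    x$response,
    if (nzchar(x$result$covariates)) paste0(" + ", x$result$covariates) else "",
    x$result$estimate, x$result$statistic, x$result$p_value, x$result$df
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ms_ancova <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf),
                 estimate = cf[, "Estimate"],
                 std.error = cf[, "Std. Error"],
                 statistic = cf[, "t value"],
                 p.value = cf[, "Pr(>|t|)"])
}

#' @export
glance.ms_ancova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared,
                 adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma,
                 df.residual = x$fit$df.residual,
                 nobs = length(x$fit$residuals))
}

#' Spearman rank correlation
#'
#' Spearman's rho with average ranks for ties; two-sided p-value from
#' the t approximation.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return A tibble with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("Need equal-length vectors of at least 3 values", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("Spearman correlation undefined for a constant vector",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Group-level microstate report
#'
#' Builds the summary table of the analysis: per-group mean (SD) of
#' duration, occurrence and coverage for every class, a p-value row
#' from the log-ANCOVA with age and gender covariates, plus the
#' Spearman correlations between DSQIID and the durations of the
#' classes of interest.
#'
#' @param features Tidy features tibble (`subject_id`, `class`,
#'   `duration_ms`, `occurrence_hz`, `coverage`, optionally `gev`).
#' @param meta Metadata tibble (`subject_id`, `group`, `age`, `gender`,
#'   `dsqiid`).
#' @param correlate_classes Classes whose durations are correlated with
#'   DSQIID (default A and D).
#' @param out_dir Optional directory: writes `table1.csv`,
#'   `ancova.csv`, `correlations.csv` and one scatterplot PNG per
#'   correlated class.
#' @return A list of class `ms_report`: `table` (group rows x feature
#'   columns plus p row), `ancova`, `correlations`, `scatter` (list of
#'   ggplots).
#' @export
ms_report <- function(features, meta, correlate_classes = c("A", "D"),
                      out_dir = NULL) {
  missing_ids <- setdiff(unique(features$subject_id), meta$subject_id)
  if (length(missing_ids) > 0) {
    stop("Subject(s) missing from metadata: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  long <- features |>
    tidyr::pivot_longer(cols = c("duration_ms", "occurrence_hz", "coverage"),
                        names_to = "feature", values_to = "value") |>
    dplyr::mutate(feature = paste(
      c(duration_ms = "duration", occurrence_hz = "occurrence",
        coverage = "coverage")[.data$feature], .data$class, sep = "_")) |>
    dplyr::select("subject_id", "feature", "value") |>
    dplyr::left_join(meta, by = "subject_id")

  summ <- long |>
    dplyr::group_by(.data$group, .data$feature) |>
    dplyr::summarise(cell = sprintf("%.2f (%.2f)", mean(.data$value),
                                    stats::sd(.data$value)),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "cell")

  anc <- long |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(d, key) {
      ms_ancova(d, response = "value")$result[, c("estimate", "statistic",
                                                  "p_value", "dropped")]
    }) |>
    dplyr::ungroup()

  prow <- anc |>
    dplyr::transmute(.data$feature, cell = sprintf("%.3f", .data$p_value)) |>
    tidyr::pivot_wider(names_from = "feature", values_from = "cell") |>
    dplyr::mutate(group = "p-value", .before = 1)
  tab <- dplyr::bind_rows(summ, prow)

  dur <- features |>
    dplyr::filter(.data$class %in% correlate_classes) |>
    dplyr::left_join(meta, by = "subject_id")
  cors <- dur |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(d, key) {
      spearman(d$dsqiid, d$duration_ms)
    }) |>
    dplyr::ungroup()

  scatter <- lapply(correlate_classes, function(k) {
    d <- dur[dur$class == k, ]
    ggplot2::ggplot(d, ggplot2::aes(x = .data$dsqiid,
                                    y = .data$duration_ms)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "grey40", linewidth = 0.5) +
      ggplot2::labs(x = "DSQIID score",
                    y = sprintf("Microstate %s duration (ms)", k),
                    title = sprintf("DSQIID vs duration of microstate %s", k)) +
      ggplot2::theme_minimal()
  })
  names(scatter) <- correlate_classes

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(tab, file.path(out_dir, "table1.csv"))
    readr::write_csv(anc, file.path(out_dir, "ancova.csv"))
    readr::write_csv(cors, file.path(out_dir, "correlations.csv"))
    for (k in names(scatter)) {
      ggplot2::ggsave(file.path(out_dir, sprintf("dsqiid_duration_%s.png", k)),
                      scatter[[k]], width = 5, height = 4, dpi = 120)
    }
  }
  structure(list(table = tab, ancova = anc, correlations = cors,
                 scatter = scatter),
            class = "ms_report")
}

#' @export
print.ms_report <- function(x, ...) {
  cat("<ms_report>\n")
  print(x$table)
  invisible(x)
}
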