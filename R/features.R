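#' Run-length encode a label sequence
#'
#' @param labels An `ms_labels` or plain integer vector.
#' @return A tibble with columns `class`, `start` (1-based), `length`;
#'   losslessly invertible with [run_length_decode()].
#' @export
run_length_encode <- function(labels) {
  if (inherits(labels, "ms_labels")) labels <- labels$labels
  if (length(labels) == 0) stop("Empty label sequence", call. = FALSE)
  runs_of(labels)[, c("class", "start", "length")]
}

#' @rdname run_length_encode
#' @param runs A tibble as returned by [run_length_encode()].
#' @export
run_length_decode <- function(runs) {
  rep(runs$class, runs$length)
}

#' Per-class microstate features from a label sequence
#'
#' Duration (mean run length, ms), occurrence (runs per second) and
#' coverage (fraction of samples) per class. The three are tied by the
#' identity `duration * occurrence / 1000 = coverage` on any sequence.
#' Classes absent from the sequence get duration 0 and `present =
#' FALSE`.
#'
#' @param labels An `ms_labels` or plain integer vector of class
#'   indices.
#' @param fs Sampling rate (taken from `ms_labels` input when absent).
#' @param K Number of classes (inferred as the max label when absent).
#' @param class_labels Optional class names (default LETTERS).
#' @return A tibble with one row per class: `class`, `duration_ms`,
#'   `occurrence_hz`, `coverage`, `n_runs`, `present`.
#' @export
ms_features <- function(labels, fs = NULL, K = NULL, class_labels = NULL) {
  if (inherits(labels, "ms_labels")) {
    if (is.null(fs)) fs <- labels$fs
    if (is.null(K)) K <- ncol(labels$corr)
    if (is.null(class_labels)) class_labels <- labels$class_labels
    labels <- labels$labels
  }
  if (length(labels) == 0) stop("Empty label sequence", call. = FALSE)
  if (is.null(fs)) stop("Sampling rate `fs` required", call. = FALSE)
  if (is.null(K)) K <- max(labels)
  if (is.null(class_labels)) class_labels <- LETTERS[seq_len(K)]
  rr <- runs_of(labels)
  total_s <- length(labels) / fs
  purrr::map_dfr(seq_len(K), function(k) {
    rk <- rr[rr$class == k, ]
    n_runs <- nrow(rk)
    tibble::tibble(
      class = class_labels[k],
      duration_ms = if (n_runs > 0) mean(rk$length) * 1000 / fs else 0,
      occurrence_hz = n_runs / total_s,
      coverage = sum(rk$length) / length(labels),
      n_runs = n_runs,
      present = n_runs > 0
    )
  })
}

#' Observed microstate transition probabilities
#'
#' Counts transitions between consecutive distinct runs and normalises
#' by the total transition count, giving a K x K matrix with zero
#' diagonal whose off-diagonal entries sum to 1.
#'
#' @inheritParams ms_features
#' @return K x K numeric matrix (rows = from, cols = to).
#' @export
observed_transitions <- function(labels, K = NULL, class_labels = NULL) {
  if (inherits(labels, "ms_labels")) {
    if (is.null(K)) K <- ncol(labels$corr)
    if (is.null(class_labels)) class_labels <- labels$class_labels
    labels <- labels$labels
  }
  if (is.null(K)) K <- max(labels)
  if (is.null(class_labels)) class_labels <- LETTERS[seq_len(K)]
  seqs <- rle(labels)$values
  if (length(seqs) < 2) {
    stop("Need at least 2 runs to count transitions", call. = FALSE)
  }
  from <- seqs[-length(seqs)]
  to <- seqs[-1]
  M <- matrix(0, K, K, dimnames = list(class_labels, class_labels))
  for (i in seq_along(from)) M[from[i], to[i]] <- M[from[i], to[i]] + 1
  M / sum(M)
}

#' Expected transition probabilities under occurrence independence
#'
#' The null used by the syntax analysis: with `p_k` the occurrence
#' rates normalised to sum 1, `E_ij = p_i p_j / sum_{k != l} p_k p_l`
#' for `i != j` — independent class draws with self-transitions
#' excluded.
#'
#' @param occurrence Numeric vector of per-class occurrence rates, or
#'   a features tibble from [ms_features()] (column `occurrence_hz`).
#' @param class_labels Optional class names for dimnames.
#' @return K x K numeric matrix with zero diagonal, off-diagonal
#'   entries summing to 1.
#' @export
expected_transitions <- function(occurrence, class_labels = NULL) {
  if (is.data.frame(occurrence)) {
    if (is.null(class_labels)) class_labels <- occurrence$class
    occurrence <- occurrence$occurrence_hz
  }
  if (any(occurrence < 0) || all(occurrence == 0)) {
    stop("Occurrence rates must be non-negative and not all zero",
         call. = FALSE)
  }
  K <- length(occurrence)
  if (is.null(class_labels)) class_labels <- LETTERS[seq_len(K)]
  p <- occurrence / sum(occurrence)
  E <- outer(p, p)
  diag(E) <- 0
  E <- E / sum(E)
  dimnames(E) <- list(class_labels, class_labels)
  E
}

#' Chi-square distance between transition matrices
#'
#' `sum_{i != j} (obs_ij - exp_ij)^2 / exp_ij` over the off-diagonal
#' cells; cells with both entries zero contribute 0.
#'
#' @param obs,exp Same-shape numeric matrices.
#' @return Non-negative scalar.
#' @export
chi_square_distance <- function(obs, exp) {
  stopifnot(all(dim(obs) == dim(exp)))
  off <- row(obs) != col(obs)
  o <- obs[off]
  e <- exp[off]
  if (any(e == 0 & o > 0)) {
    stop("Chi-square distance undefined: observed mass on a zero-expectation cell",
         call. = FALSE)
  }
  ok <- e > 0
  sum((o[ok] - e[ok])^2 / e[ok])
}

#' Observed and expected transition table for one subject
#'
#' @inheritParams ms_features
#' @return A list of class `ms_transitions`: `observed`, `expected`
#'   (K x K matrices), `subject_id`.
#' @param subject_id Carried into the result.
#' @export
transition_table <- function(labels, fs = NULL, K = NULL,
                             class_labels = NULL,
                             subject_id = NA_character_) {
  feats <- ms_features(labels, fs = fs, K = K, class_labels = class_labels)
  obs <- observed_transitions(labels, K = K, class_labels = class_labels)
  structure(
    list(observed = obs,
         expected = expected_transitions(feats),
         subject_id = subject_id),
    class = "ms_transitions"
  )
}

#' Syntax permutation test on transition probabilities
#'
#' Tests whether the across-subject mean observed transition matrix
#' deviates from the mean occurrence-expected matrix. The statistic is
#' the chi-square distance between the two means; the null
#' distribution swaps each subject's observed/expected pair
#' independently with probability 1/2, `n_perm` times; the p-value uses
#' the permutation-inclusive (add-one) estimator.
#'
#' @param tables List of `ms_transitions` (>= 2 subjects).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed for the permutation draws.
#' @return A tibble with `statistic`, `p_value`, `n_subjects`,
#'   `n_perm`.
#' @export
syntax_permutation_test <- function(tables, n_perm = 5000, seed = 1) {
  stopifnot(length(tables) >= 2)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  K <- nrow(tables[[1]]$observed)
  off <- which(row(diag(K)) != col(diag(K)))
  O <- t(vapply(tables, function(tt) tt$observed[off], numeric(length(off))))
  E <- t(vapply(tables, function(tt) tt$expected[off], numeric(length(off))))
  n <- nrow(O)
  chi_off <- function(mo, me) {
    if (any(me == 0 & mo > 0)) {
      stop("Observed mass on zero-expectation cell", call. = FALSE)
    }
    ok <- me > 0
    sum((mo[ok] - me[ok])^2 / me[ok])
  }
  t_obs <- chi_off(colMeans(O), colMeans(E))
  D <- E - O
  withr_seed(seed, {
    # swapping subject i's pair shifts both means by +/- d_i / n
    S <- matrix(stats::runif(n_perm * n) < 0.5, n_perm, n)
    shift <- (S %*% D) / n
    MO <- matrix(colMeans(O), n_perm, ncol(O), byrow = TRUE) + shift
    ME <- matrix(colMeans(E), n_perm, ncol(E), byrow = TRUE) - shift
    if (any(ME == 0 & MO > 0)) {
      stop("Observed mass on zero-expectation cell", call. = FALSE)
    }
    X <- (MO - ME)^2 / ME
    X[ME == 0] <- 0
    exceed <- sum(rowSums(X) >= t_obs)
  })
  tibble::tibble(statistic = t_obs,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_subjects = n, n_perm = as.integer(n_perm))
}
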