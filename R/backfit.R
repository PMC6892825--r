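#' Back-fit microstate maps to a recording
#'
#' Labels every sample with the class whose map has the highest
#' polarity-invariant spatial correlation with the instantaneous
#' topography. The full sample x class correlation matrix is retained
#' for temporal smoothing.
#'
#' @param maps An `ms_maps` (K unit-norm, zero-mean rows) over the same
#'   channels as `rec`.
#' @param rec An average-referenced [ms_recording()].
#' @return An object of class `ms_labels`: `labels` (integer, 1..K),
#'   `fit` (per-sample correlation to the assigned map), `corr`
#'   (T x K correlation matrix), `fs`, `boundaries`, `class_labels`.
#' @export
backfit <- function(maps, rec) {
  stopifnot(inherits(maps, "ms_maps"))
  assert_average_reference(rec)
  if (ncol(maps$maps) != n_channels(rec)) {
    stop("Channel count mismatch between maps and recording",
         call. = FALSE)
  }
  M <- maps$maps - rowMeans(maps$maps)
  M <- M / sqrt(rowSums(M^2))
  A <- abs(crossprod(rec$data, t(M)))     # T x K, |v_t . m_k|
  nv <- sqrt(colSums(rec$data^2))
  corr <- A / ifelse(nv > 0, nv, Inf)     # zero-GFP samples get fit 0
  labels <- max.col(corr, ties.method = "first")
  structure(
    list(labels = labels,
         fit = corr[cbind(seq_along(labels), labels)],
         corr = corr,
         fs = rec$fs,
         boundaries = rec$boundaries,
         class_labels = maps$labels),
    class = "ms_labels"
  )
}

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf("<ms_labels> %d samples @ %g Hz, %d classes, mean fit %.3f\n",
              length(x$labels), x$fs, ncol(x$corr), mean(x$fit)))
  invisible(x)
}

runs_of <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  tibble::tibble(class = r$values,
                 start = ends - r$lengths + 1L,
                 length = r$lengths,
                 end = ends)
}

#' Relabel sub-threshold microstate segments
#'
#' Temporal smoothing of a back-fitted label sequence: every maximal
#' run shorter than `min_ms` has each of its samples relabelled to that
#' sample's next most likely class (lowest global map dissimilarity,
#' i.e. next-highest correlation, excluding the run's current class),
#' left to right, repeated until a pass changes nothing. Any run still
#' below threshold after the fixpoint (the per-sample rule can cycle on
#' pathological fits) is then absorbed whole into the adjacent run's
#' class with the higher mean correlation, which terminates with no
#' sub-threshold run remaining.
#'
#' @param ls An `ms_labels` from [backfit()].
#' @param min_ms Minimum segment duration in ms (0 disables smoothing).
#' @param max_passes Safety cap on relabelling passes.
#' @return An `ms_labels` with updated `labels` and `fit`.
#' @export
smooth_labels <- function(ls, min_ms = 30, max_passes = 20) {
  stopifnot(inherits(ls, "ms_labels"))
  if (min_ms < 0) stop("`min_ms` must be >= 0", call. = FALSE)
  min_len <- round(min_ms * ls$fs / 1000)
  labels <- ls$labels
  corr <- ls$corr
  K <- ncol(corr)
  Tn <- length(labels)
  if (min_len <= 1 || Tn == 0 || K < 2) return(ls)

  for (pass in seq_len(max_passes)) {
    rr <- runs_of(labels)
    short <- which(rr$length < min_len)
    if (nrow(rr) == 1 || length(short) == 0) break
    changed <- FALSE
    for (i in short) {
      sl <- rr$start[i]:rr$end[i]
      cur <- rr$class[i]
      sub <- corr[sl, -cur, drop = FALSE]
      pick <- (seq_len(K)[-cur])[max.col(sub, ties.method = "first")]
      if (any(pick != labels[sl])) changed <- TRUE
      labels[sl] <- pick
    }
    if (!changed) break
  }

  # terminating absorption of residual short runs into a neighbour
  repeat {
    rr <- runs_of(labels)
    if (nrow(rr) == 1) break
    short <- which(rr$length < min_len)
    if (length(short) == 0) break
    i <- short[which.min(rr$length[short])]
    sl <- rr$start[i]:rr$end[i]
    cand <- integer(0)
    if (i > 1) cand <- c(cand, rr$class[i - 1])
    if (i < nrow(rr)) cand <- c(cand, rr$class[i + 1])
    cand <- unique(cand)
    mc <- vapply(cand, function(k) mean(corr[sl, k]), 0)
    labels[sl] <- cand[which.max(mc)]
  }

  ls$labels <- labels
  ls$fit <- corr[cbind(seq_len(Tn), labels)]
  ls
}

#' Global explained variance of a labelled recording
#'
#' Fraction of GFP-weighted variance explained by assigning every
#' sample to its labelled map:
#' `GEV = sum((GFP_t * r_t)^2) / sum(GFP_t^2)`, with `r_t` the
#' polarity-invariant correlation between the sample topography and
#' its assigned map. Also returns the per-class partition (summing to
#' the total).
#'
#' @param rec An average-referenced [ms_recording()].
#' @param maps An `ms_maps`.
#' @param ls An `ms_labels` over the same samples.
#' @return A list: `gev` (scalar in `[0, 1]`) and `per_class` (named
#'   numeric, one entry per class).
#' @export
gev <- function(rec, maps, ls) {
  assert_average_reference(rec)
  stopifnot(inherits(maps, "ms_maps"), inherits(ls, "ms_labels"),
            length(ls$labels) == n_samples(rec))
  g2 <- colMeans(rec$data^2)              # GFP^2 per sample
  denom <- sum(g2)
  if (denom == 0) stop("GEV undefined for all-zero data", call. = FALSE)
  M <- maps$maps - rowMeans(maps$maps)
  M <- M / sqrt(rowSums(M^2))
  A <- abs(crossprod(rec$data, t(M)))
  nv <- sqrt(colSums(rec$data^2))
  r <- A[cbind(seq_along(ls$labels), ls$labels)] / ifelse(nv > 0, nv, Inf)
  num <- g2 * r^2                          # (GFP_t * r_t)^2
  per_class <- vapply(seq_len(nrow(M)), function(k) {
    sum(num[ls$labels == k]) / denom
  }, 0)
  names(per_class) <- maps$labels
  list(gev = sum(num) / denom, per_class = per_class)
}
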