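#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the scalp potential at
#' each sample: `sqrt(mean(v(t)^2))` across channels for
#' average-referenced data.
#'
#' @param rec An average-referenced [ms_recording()].
#' @return An object of class `ms_gfp`: numeric vector of per-sample
#'   GFP values (µV) with the sampling rate attached.
#' @export
gfp <- function(rec) {
  assert_average_reference(rec)
  structure(sqrt(colMeans(rec$data^2)), fs = rec$fs, class = "ms_gfp")
}

#' Locate GFP peaks with minimum-distance and amplitude exclusion
#'
#' Local maxima of the GFP series with an enforced minimum separation
#' (larger peaks win ties greedily); peaks whose GFP exceeds the mean
#' plus `sd_mult` standard deviations of the GFP-at-peaks distribution
#' are excluded as likely artifacts; if more than `max_peaks` remain,
#' the largest-GFP peaks are kept.
#'
#' @param g An `ms_gfp` series (or plain numeric vector with `fs`
#'   supplied).
#' @param min_dist_ms Minimum peak separation in ms (default 10).
#' @param max_peaks Cap on the number of returned peaks (default
#'   unlimited).
#' @param sd_mult Amplitude exclusion multiplier (default 2; `Inf`
#'   disables exclusion).
#' @param fs Sampling rate, required when `g` is a plain vector.
#' @return Sorted integer vector of peak sample indices, with the peak
#'   GFP values in attribute `"gfp"`.
#' @export
find_gfp_peaks <- function(g, min_dist_ms = 10, max_peaks = Inf,
                           sd_mult = 2, fs = attr(g, "fs")) {
  if (is.null(fs)) stop("Sampling rate unknown; pass `fs`", call. = FALSE)
  if (min_dist_ms <= 0) stop("`min_dist_ms` must be positive", call. = FALSE)
  v <- as.numeric(g)
  n <- length(v)
  if (n < 3) return(structure(integer(0), gfp = numeric(0)))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (length(cand) == 0) return(structure(integer(0), gfp = numeric(0)))
  min_dist <- max(1L, round(min_dist_ms * fs / 1000))
  # greedy: largest peaks claim their exclusion window first
  ord <- cand[order(v[cand], decreasing = TRUE)]
  keep <- logical(length(ord))
  taken <- rep(FALSE, n)
  for (j in seq_along(ord)) {
    i <- ord[j]
    if (!taken[i]) {
      keep[j] <- TRUE
      lo <- max(1L, i - min_dist + 1L)
      hi <- min(n, i + min_dist - 1L)
      taken[lo:hi] <- TRUE
    }
  }
  pk <- sort(ord[keep])
  if (is.finite(sd_mult) && length(pk) > 1) {
    thr <- mean(v[pk]) + sd_mult * stats::sd(v[pk])
    pk <- pk[v[pk] <= thr]
  }
  if (length(pk) > max_peaks) {
    pk <- sort(pk[order(v[pk], decreasing = TRUE)][seq_len(max_peaks)])
  }
  structure(pk, gfp = v[pk])
}

#' Extract GFP-peak topographies from a recording
#'
#' Convenience wrapper: computes the GFP series, locates peaks under
#' the standard settings, and returns the peak topographies.
#'
#' @inheritParams find_gfp_peaks
#' @param rec An average-referenced [ms_recording()].
#' @param subject_id Carried into the result for pooling.
#' @return A list of class `ms_peaks`: `maps` (P x C matrix), `index`,
#'   `gfp`, `subject_id`, `montage`.
#' @export
extract_gfp_peaks <- function(rec, min_dist_ms = 10, max_peaks = Inf,
                              sd_mult = 2, subject_id = NA_character_) {
  g <- gfp(rec)
  pk <- find_gfp_peaks(g, min_dist_ms = min_dist_ms,
                       max_peaks = max_peaks, sd_mult = sd_mult)
  structure(
    list(maps = t(rec$data[, pk, drop = FALSE]),
         index = as.integer(pk), gfp = attr(pk, "gfp"),
         subject_id = subject_id, montage = rec$montage),
    class = "ms_peaks"
  )
}

#' @export
print.ms_peaks <- function(x, ...) {
  cat(sprintf("<ms_peaks> %d peaks x %d channels (subject %s)\n",
              nrow(x$maps), ncol(x$maps), x$subject_id))
  invisible(x)
}

#' Polarity-invariant spatial correlation between two topographies
#'
#' Absolute Pearson correlation across channels; both maps must be
#' zero-mean (average-reference consistent) with nonzero norm.
#'
#' @param u,v Numeric topography vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
spatial_correlation <- function(u, v) {
  stopifnot(length(u) == length(v))
  u <- u - mean(u)
  v <- v - mean(v)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("Spatial correlation undefined for a zero-norm topography",
         call. = FALSE)
  }
  abs(sum(u * v)) / (nu * nv)
}

#' Global map dissimilarity
#'
#' GMD between two GFP-normalised topographies, minimised over
#' polarity: `min over s of sqrt(mean((u/GFP_u - s * v/GFP_v)^2))`.
#' Satisfies `GMD^2 = 2 (1 - r)` with `r` the polarity-invariant
#' spatial correlation.
#'
#' @inheritParams spatial_correlation
#' @return Scalar in `[0, sqrt(2)]`.
#' @export
gmd <- function(u, v) {
  stopifnot(length(u) == length(v))
  u <- u - mean(u)
  v <- v - mean(v)
  gu <- sqrt(mean(u^2))
  gv <- sqrt(mean(v^2))
  if (gu == 0 || gv == 0) {
    stop("GMD undefined for a zero-norm topography", call. = FALSE)
  }
  un <- u / gu
  vn <- v / gv
  min(sqrt(mean((un - vn)^2)), sqrt(mean((un + vn)^2)))
}
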