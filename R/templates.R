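#' Canonical microstate template topographies
#'
#' Builds K smooth dipolar scalp topographies qualitatively matching the
#' archetypes reported across the resting-state microstate literature:
#' A (left-posterior / right-anterior diagonal), B (right-posterior /
#' left-anterior diagonal), C (anterior-posterior with posterior-midline
#' maximum), D (fronto-central versus periphery). For K of 5 or 6 an
#' occipital-focal and a left-right lateral pattern are appended (and
#' temporal-focal patterns up to K = 8). A small seeded perturbation is
#' added so distinct seeds give distinct (but archetype-faithful)
#' template sets; every row is average-reference consistent (zero mean
#' across channels) and unit L2 norm.
#'
#' @param K Number of templates, between 2 and 8.
#' @param montage Electrode positions ([montage_1020()] by default; at
#'   least 8 electrodes, no coincident positions).
#' @param seed Integer seed for the perturbation.
#' @param jitter Standard deviation of the perturbation relative to the
#'   topography scale (0 disables it).
#' @return An object of class `ms_maps`: list with `maps` (K x C
#'   matrix, rownames the archetype labels), `montage`, `labels`, and
#'   `provenance = "template"`.
#' @examples
#' tpl <- make_templates(K = 4, seed = 1)
#' rowSums(tpl$maps^2) # unit norm
#' @export
make_templates <- function(K = 4, montage = montage_1020(), seed = 1,
                           jitter = 0.05) {
  if (!is.numeric(K) || K < 2 || K > 8) {
    stop("K must be between 2 and 8", call. = FALSE)
  }
  K <- as.integer(K)
  if (nrow(montage) < 8) {
    stop("Montage needs at least 8 electrodes", call. = FALSE)
  }
  check_montage(montage)
  pos <- montage_matrix(montage)
  pos <- pos / sqrt(rowSums(pos^2))
  x <- pos[, 1]; y <- pos[, 2]; z <- pos[, 3]
  focal <- function(p0, width = 0.6) {
    d2 <- rowSums(sweep(pos, 2, p0)^2)
    exp(-d2 / (2 * width^2))
  }
  base <- rbind(
    A = -(x + y) / sqrt(2),                 # left-posterior vs right-anterior
    B = (x - y) / sqrt(2),                  # right-posterior vs left-anterior
    C = -y + 0.3 * focal(c(0, -0.64, 0.77)),# anterior-posterior, post. midline
    D = focal(c(0, 0.5, 0.866)) - 0.35,     # fronto-central vs periphery
    E = focal(c(0, -0.85, 0.53)) - 0.3,     # occipital focal
    F = x,                                  # left-right lateral
    G = focal(c(0.94, 0.21, 0.28)) - 0.3,   # right temporal focal
    H = focal(c(-0.94, 0.21, 0.28)) - 0.3   # left temporal focal
  )[seq_len(K), , drop = FALSE]

  withr_seed(seed, {
    maps <- base + matrix(stats::rnorm(length(base), sd = jitter),
                          nrow = K) * stats::sd(base)
  })
  maps <- maps - rowMeans(maps)
  maps <- maps / sqrt(rowSums(maps^2))
  colnames(maps) <- montage$channel

  r <- abs(stats::cor(t(maps)))
  diag(r) <- 0
  if (max(r) >= 0.9) {
    stop("Generated templates are not distinct enough (max |r| = ",
         format(max(r), digits = 3), ")", call. = FALSE)
  }
  new_ms_maps(maps, montage = montage, labels = rownames(maps),
              provenance = "template")
}

new_ms_maps <- function(maps, montage, labels, provenance) {
  rownames(maps) <- labels
  structure(
    list(maps = maps, montage = montage, labels = labels,
         provenance = provenance),
    class = "ms_maps"
  )
}

#' @export
print.ms_maps <- function(x, ...) {
  cat(sprintf("<ms_maps> %d maps x %d channels (%s): %s\n",
              nrow(x$maps), ncol(x$maps), x$provenance,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# local seed scope so generators do not disturb the caller's RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
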