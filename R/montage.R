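#' Standard 10-20 electrode montage
#'
#' Nominal unit-sphere positions for the 19-channel International 10-20
#' montage (BESA-style spherical angles: inclination from the vertex,
#' azimuth from the anterior midline, positive towards the right ear).
#' These static coordinates stand in for per-subject electrode
#' localisation; all topographic operations (spherical-spline
#' interpolation, template construction, map plotting) read positions
#' from this table.
#'
#' @param channels Optional character vector of channel names to subset
#'   (and order) the montage by. Default: all 19 channels.
#' @return A tibble with columns `channel`, `x`, `y`, `z` (unit sphere;
#'   x right, y anterior, z superior).
#' @examples
#' montage_1020()
#' montage_1020(c("Fp1", "Cz", "O2"))
#' @export
montage_1020 <- function(channels = NULL) {
  # inclination (deg from Cz), azimuth (deg from front midline, + = right)
  tab <- tibble::tribble(
    ~channel, ~inc, ~az,
    "Fp1", 90, -18,
    "Fp2", 90,  18,
    "F7",  90, -54,
    "F3",  60, -39,
    "Fz",  45,   0,
    "F4",  60,  39,
    "F8",  90,  54,
    "T3",  90, -90,
    "C3",  45, -90,
    "Cz",   0,   0,
    "C4",  45,  90,
    "T4",  90,  90,
    "T5",  90, -126,
    "P3",  60, -141,
    "Pz",  45, 180,
    "P4",  60, 141,
    "T6",  90, 126,
    "O1",  90, -162,
    "O2",  90, 162
  )
  inc <- tab$inc * pi / 180
  az <- tab$az * pi / 180
  out <- tibble::tibble(
    channel = tab$channel,
    x = sin(inc) * sin(az),
    y = sin(inc) * cos(az),
    z = cos(inc)
  )
  if (!is.null(channels)) {
    miss <- setdiff(channels, out$channel)
    if (length(miss) > 0) {
      stop("Unknown channel(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    out <- out[match(channels, out$channel), ]
  }
  out
}

#' @keywords internal
montage_matrix <- function(montage) {
  stopifnot(all(c("x", "y", "z") %in% names(montage)))
  m <- as.matrix(montage[, c("x", "y", "z")])
  rownames(m) <- montage$channel
  m
}

check_montage <- function(montage, n_channels = NULL) {
  m <- montage_matrix(montage)
  if (!is.null(n_channels) && nrow(m) != n_channels) {
    stop("Montage has ", nrow(m), " electrodes; expected ", n_channels,
         call. = FALSE)
  }
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  if (any(d < 1e-6)) {
    stop("Degenerate montage: coincident electrodes", call. = FALSE)
  }
  invisible(montage)
}
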