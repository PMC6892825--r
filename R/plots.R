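#' Topographic plot of microstate maps
#'
#' Renders each map as an interpolated scalp topography (azimuthal
#' equidistant projection, spherical-spline interpolation onto a grid,
#' head outline, electrode dots), faceted by class label.
#'
#' @param object An `ms_maps`.
#' @param resolution Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ms_maps
#' @export
autoplot.ms_maps <- function(object, resolution = 60, ...) {
  maps <- object$maps
  montage <- object$montage
  if (is.null(montage)) stop("Maps carry no montage", call. = FALSE)
  pos <- montage_matrix(montage)
  pos <- pos / sqrt(rowSums(pos^2))
  # azimuthal equidistant projection: radius = inclination
  inc <- acos(pmin(pmax(pos[, 3], -1), 1))
  az <- atan2(pos[, 1], pos[, 2])
  e2d <- tibble::tibble(channel = montage$channel,
                        px = inc / (pi / 2) * sin(az),
                        py = inc / (pi / 2) * cos(az))

  gr <- expand.grid(px = seq(-1.05, 1.05, length.out = resolution),
                    py = seq(-1.05, 1.05, length.out = resolution))
  gr <- gr[gr$px^2 + gr$py^2 <= 1.05^2, ]
  # back-project grid points onto the upper sphere
  r <- pmin(sqrt(gr$px^2 + gr$py^2), 1) * pi / 2
  gaz <- atan2(gr$px, gr$py)
  gpos <- cbind(sin(r) * sin(gaz), sin(r) * cos(gaz), cos(r))

  cosang <- gpos %*% t(pos)
  cosang <- pmin(pmax(cosang, -1), 1)
  Gg <- spline_kernel(pmin(pmax(tcrossprod(pos), -1), 1)) +
    diag(1e-5, nrow(pos))
  A <- rbind(cbind(Gg, 1), c(rep(1, nrow(pos)), 0))
  Gt <- spline_kernel(cosang)

  df <- purrr::map_dfr(seq_len(nrow(maps)), function(k) {
    sol <- solve(A, c(maps[k, ], 0))
    vals <- Gt %*% sol[seq_len(nrow(pos))] + sol[nrow(pos) + 1]
    tibble::tibble(class = object$labels[k], px = gr$px, py = gr$py,
                   value = as.numeric(vals))
  })
  df$class <- factor(df$class, levels = object$labels)
  circle <- tibble::tibble(theta = seq(0, 2 * pi, length.out = 181))

  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_path(data = tibble::tibble(px = 1.02 * cos(circle$theta),
                                             py = 1.02 * sin(circle$theta)),
                       linewidth = 0.4) +
    ggplot2::geom_point(data = e2d, size = 0.6, colour = "black") +
    ggplot2::facet_wrap(~class, nrow = 1) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Microstate maps (%s)",
                                  object$provenance))
}

#' @export
plot.ms_maps <- function(x, ...) print(autoplot.ms_maps(x, ...))

#' GFP trace plot with detected peaks
#'
#' @param object An `ms_gfp` series.
#' @param peaks Optional peak indices from [find_gfp_peaks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ms_gfp
#' @export
autoplot.ms_gfp <- function(object, peaks = NULL, ...) {
  fs <- attr(object, "fs")
  df <- tibble::tibble(t = seq_along(object) / fs,
                       gfp = as.numeric(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$gfp)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "GFP (µV)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_point(
      data = df[as.integer(peaks), , drop = FALSE],
      colour = "#B2182B", size = 0.8
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
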