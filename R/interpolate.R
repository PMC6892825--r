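#' Spherical-spline interpolation of scalp potentials
#'
#' Perrin-style spherical-spline interpolation on the unit sphere:
#' the potential is modelled as a constant plus a weighted sum of the
#' spline kernel g(cos theta) with stiffness order m = 4, a truncated
#' Legendre expansion, and Tikhonov regularisation on the kernel matrix.
#' Used to reconstruct bad channels inside artifact screening and to
#' rasterise topographic maps for plotting.
#'
#' @param epoch Numeric channels x samples matrix.
#' @param bad Integer indices (or channel names) of channels to
#'   reconstruct.
#' @param montage Electrode positions as returned by [montage_1020()],
#'   in the row order of `epoch`.
#' @param m Spline stiffness order (4, the standard choice for EEG).
#' @param n_legendre Number of Legendre terms in the kernel expansion.
#' @param lambda Ridge regularisation added to the kernel matrix
#'   diagonal.
#' @return `epoch` with the bad rows replaced by their spline
#'   reconstruction; good rows untouched.
#' @export
spherical_interpolate <- function(epoch, bad, montage, m = 4,
                                  n_legendre = 20, lambda = 1e-5) {
  epoch <- as.matrix(epoch)
  C <- nrow(epoch)
  if (is.character(bad)) bad <- match(bad, montage$channel)
  bad <- sort(unique(as.integer(bad)))
  if (length(bad) == 0) return(epoch)
  if (any(is.na(bad)) || any(bad < 1) || any(bad > C)) {
    stop("`bad` indices out of range", call. = FALSE)
  }
  good <- setdiff(seq_len(C), bad)
  if (length(good) < 4 || length(bad) >= C - 3) {
    stop("Too few good channels for spherical interpolation",
         call. = FALSE)
  }
  pos <- montage_matrix(montage)
  stopifnot(nrow(pos) == C)
  pos <- pos / sqrt(rowSums(pos^2))

  cosang <- tcrossprod(pos)            # C x C matrix of cos(theta)
  cosang <- pmin(pmax(cosang, -1), 1)
  G <- spline_kernel(cosang, m = m, n_legendre = n_legendre)

  Gg <- G[good, good, drop = FALSE] + diag(lambda, length(good))
  # bordered system enforcing sum(c) = 0 with a free constant term
  A <- rbind(cbind(Gg, 1), c(rep(1, length(good)), 0))
  rhs <- rbind(epoch[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  cc <- sol[seq_along(good), , drop = FALSE]
  c0 <- sol[length(good) + 1, , drop = FALSE]

  Gb <- G[bad, good, drop = FALSE]
  epoch[bad, ] <- Gb %*% cc + matrix(1, length(bad), 1) %*% c0
  epoch
}

# g(x) = (1/4pi) sum_{n=1}^{N} (2n+1) / (n(n+1))^m P_n(x)
spline_kernel <- function(x, m = 4, n_legendre = 20) {
  p_prev <- array(1, dim = dim(as.matrix(x)))   # P_0
  p_cur <- as.matrix(x)                         # P_1
  out <- 3 / (2^m) * p_cur
  for (n in 2:n_legendre) {
    p_next <- ((2 * n - 1) * as.matrix(x) * p_cur - (n - 1) * p_prev) / n
    out <- out + (2 * n + 1) / ((n * (n + 1))^m) * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  out / (4 * pi)
}
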