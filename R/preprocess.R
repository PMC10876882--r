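#' High-pass filter by discrete-cosine drift regression
#'
#' Removes the per-voxel mean and all discrete-cosine basis functions with
#' frequency below `cutoff` (the fMRIPrep-style confound-regression approach;
#' a projection, hence idempotent and free of phase distortion).
#'
#' @param series a [voxel_ts].
#' @param cutoff high-pass cutoff in Hz; must lie below the Nyquist frequency.
#' @return the filtered [voxel_ts] (zero-mean voxels).
#' @export
highpass <- function(series, cutoff = 0.01) {
  nyq <- nyquist(series)
  if (cutoff >= nyq)
    stop(sprintf("cutoff %.3g Hz is not below the Nyquist frequency %.3g Hz",
                 cutoff, nyq))
  n <- n_timepoints(series)
  X <- dct_basis(n, series$tr, cutoff)
  v <- series$values
  v <- v - rowMeans(v)
  if (ncol(X) > 0) {
    # project out the drift basis (columns are orthonormal)
    v <- v - (v %*% X) %*% t(X)
  }
  out <- series
  out$values <- v
  out
}

# Orthonormal DCT-II basis columns with frequency k/(2*n*tr) <= cutoff, k >= 1.
dct_basis <- function(n, tr, cutoff) {
  kmax <- floor(2 * n * tr * cutoff)
  if (kmax < 1) return(matrix(numeric(0), n, 0))
  t_idx <- seq_len(n) - 0.5
  X <- vapply(seq_len(kmax), function(k) cos(pi * k * t_idx / n), numeric(n))
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  X
}

#' Volume-wise Gaussian spatial smoothing
#'
#' Separable Gaussian kernel of the stated full width at half maximum applied
#' to each timepoint's volume.  `fwhm = 0` is the identity.  Series without a
#' spatial grid (ROI-course mode) are returned unchanged with a message.
#'
#' @param series a [voxel_ts] with grid information.
#' @param fwhm kernel full width at half maximum, millimetres.
#' @param voxel_size isotropic voxel edge length, millimetres.
#' @return smoothed [voxel_ts].
#' @export
smooth_volume <- function(series, fwhm = 5, voxel_size = 4) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (fwhm == 0) return(series)
  if (is.null(series$grid_shape) || is.null(series$coords)) {
    message("series carries no spatial grid; smoothing skipped")
    return(series)
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size   # in voxels
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  g <- series$grid_shape
  out <- series$values
  for (t in seq_len(ncol(out))) {
    vol <- vec_to_vol(out[, t], series$coords, g)
    vol <- conv_axis(vol, kern, 1L)
    vol <- conv_axis(vol, kern, 2L)
    vol <- conv_axis(vol, kern, 3L)
    out[, t] <- vol[series$coords]
  }
  res <- series
  res$values <- out
  res
}

# 1-D convolution of a 3-D array along one axis, zero-padded boundaries.
conv_axis <- function(vol, kern, ax) {
  d <- dim(vol)
  half <- (length(kern) - 1L) / 2L
  out <- array(0, d)
  for (j in seq_along(kern)) {
    off <- j - half - 1L
    src <- seq_len(d[ax]) + off
    ok <- src >= 1L & src <= d[ax]
    if (!any(ok)) next
    idx_dst <- lapply(d, seq_len); idx_src <- lapply(d, seq_len)
    idx_dst[[ax]] <- which(ok); idx_src[[ax]] <- src[ok]
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      kern[j] * vol[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

#' Framewise displacement from realignment parameters
#'
#' Sum of absolute backward differences of the six realignment parameters,
#' with rotations converted to arc length on a sphere of the given radius
#' (the Power et al. convention, 50 mm by default).  The first volume's FD is
#' defined as 0.
#'
#' @param motion numeric matrix/data frame with 6 columns: three translations
#'   (mm) then three rotations (rad).
#' @param radius sphere radius in mm for the rotation-to-arc conversion.
#' @return an `fd_series`: list with `fd` (mm per volume), `mean_fd`, `max_fd`.
#' @export
framewise_displacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion table must have exactly 6 columns (3 translations, 3 rotations)")
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * radius
  fd <- c(0, rowSums(d))
  structure(list(fd = fd, mean_fd = mean(fd), max_fd = max(fd)),
            class = "fd_series")
}

#' Temporal signal-to-noise ratio
#'
#' Per-voxel mean divided by standard deviation of each time series.
#' Zero-variance voxels are flagged rather than producing infinities, and are
#' excluded from region means.
#'
#' @param series a [voxel_ts].
#' @param by optional character: `"tissue"` to add region means per tissue.
#' @return list with `tsnr` (per-voxel, `NA` where flagged), `flagged`
#'   (logical), and optionally `region_means`.
#' @export
tsnr <- function(series, by = c("tissue", "none")) {
  by <- match.arg(by)
  m <- rowMeans(series$values)
  s <- apply(series$values, 1, stats::sd)
  flagged <- s < .Machine$double.eps
  val <- ifelse(flagged, NA_real_, m / s)
  val[!flagged & abs(m) < .Machine$double.eps] <- 0
  out <- list(tsnr = val, flagged = flagged)
  if (by == "tissue" && !is.null(series$tissue)) {
    keep <- !flagged & series$tissue != "BG"
    out$region_means <- tapply(val[keep], series$tissue[keep], mean)
  }
  out
}
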