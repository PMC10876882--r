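# Symmetric FastICA with tanh contrast on pre-whitened data.
# X: components-by-samples whitened matrix is produced internally from the
# n x p input (rows = observations).  Returns unmixing applied estimates.
fastica_core <- function(Z, n_comp, max_iter = 500, tol = 1e-4) {
  # Z: n_comp x n_samples, whitened (identity covariance)
  p <- ncol(Z)
  W <- matrix(stats::rnorm(n_comp * n_comp), n_comp)
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z                       # n_comp x p
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Z)) / p - diag(rowMeans(Gp)) %*% W
    W_new <- sym_orth(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) return(list(W = W, converged = TRUE, iter = it))
  }
  list(W = W, converged = FALSE, iter = max_iter)
}

# Spatial ICA of a voxels x time matrix: PCA-reduce to n_comp dimensions over
# time, then rotate so the spatial maps are maximally independent.
# Returns maps (voxels x k) and time courses (time x k), each component's
# map scaled to unit variance.
spatial_ica <- function(values, n_comp, max_retries = 5, seed = NULL) {
  v <- values - rowMeans(values)
  v <- sweep(v, 2, colMeans(v))
  # PCA over time: temporal basis from the thin SVD
  sv <- svd(v, nu = n_comp, nv = n_comp)
  # drop directions at the white-noise eigenvalue floor: independence is
  # undefined there and the symmetric iteration oscillates without settling
  floor_ev <- 2 * stats::quantile(sv$d^2, 0.75)
  keep <- seq_len(max(2L, min(n_comp, sum(sv$d^2 > floor_ev))))
  U <- sv$u[, keep, drop = FALSE]       # voxels x k spatial basis
  D <- sv$d[keep]
  Vt <- sv$v[, keep, drop = FALSE]      # time x k
  # whitened spatial sources: rows of t(U) have identity covariance up to 1/V
  Z <- t(U) * sqrt(nrow(U))             # k x voxels, approx. white
  if (!is.null(seed)) set.seed(seed)
  res <- NULL
  for (r in seq_len(max_retries)) {
    res <- fastica_core(Z, length(keep))
    if (res$converged) break
  }
  if (is.null(res) || !res$converged)
    stop("spatial ICA failed to converge after retries")
  S <- res$W %*% Z                      # k x voxels, independent maps
  # time course of component i: project data onto its map
  A <- t(v) %*% t(S) / nrow(U)          # time x k mixing courses
  maps <- t(S)
  # fix sign: positive skew of each map
  sgn <- sign(colSums(maps^3))
  sgn[sgn == 0] <- 1
  maps <- sweep(maps, 2, sgn, "*")
  A <- sweep(A, 2, sgn, "*")
  list(maps = maps, courses = A, converged = res$converged)
}

# High-frequency content: the fraction of the Nyquist range above which half
# of the spectral power of a time course lies (frequencies below f_min are
# ignored, as in the canonical motion-artifact classifier).
high_frequency_content <- function(course, tr, f_min = 0.01) {
  spec <- periodogram(course, tr, taper = "none")
  sel <- spec$frequency > f_min
  f <- spec$frequency[sel]
  p <- spec$power[sel]
  cum <- cumsum(p) / sum(p)
  f50 <- f[which(cum >= 0.5)[1]]
  f50 / (1 / (2 * tr))
}

#' ICA decomposition with motion/physiology component classification
#'
#' Spatial ICA of the BOLD series followed by the four spatio-temporal
#' features of the canonical automatic motion-artifact classifier:
#' maximum absolute correlation with the motion parameters and their
#' backward-difference derivatives, high-frequency content of the component
#' time course, brain-edge weight fraction, and CSF weight fraction.  A
#' component is classified as noise if its CSF fraction exceeds `theta_csf`,
#' or its high-frequency content exceeds `theta_hfc`, or the pair (motion
#' correlation, edge fraction) falls on the noise side of the linear boundary
#' `motion/boundary_motion + edge/boundary_edge > 1`.
#'
#' @param series a [voxel_ts] with tissue labels and grid information.
#' @param motion 6-column motion-parameter table (see
#'   [framewise_displacement()]).
#' @param n_components number of components, or `"auto"`
#'   (`min(20, timepoints - 1, voxels - 1)`).
#' @param theta_csf,theta_hfc scalar feature thresholds.
#' @param boundary_motion,boundary_edge axis intercepts of the 2-D linear
#'   decision boundary.
#' @param seed RNG seed for the ICA initialization (recorded in the result).
#' @return an `ica_component_report`: list with `maps`, `courses`, `features`
#'   (data frame: max_motion_cor, hfc, edge_fraction, csf_fraction,
#'   classification), and the thresholds used.
#' @export
aroma_like_components <- function(series, motion, n_components = "auto",
                                  theta_csf = 0.10, theta_hfc = 0.35,
                                  boundary_motion = 0.8, boundary_edge = 0.85,
                                  seed = 42L) {
  v <- series$values
  if (identical(n_components, "auto"))
    n_components <- min(20L, ncol(v) - 1L, nrow(v) - 1L)
  if (ncol(v) <= n_components)
    stop("need more timepoints than components")
  ica <- spatial_ica(v, n_components, seed = seed)
  k <- ncol(ica$maps)

  motion <- as.matrix(motion)
  mot_design <- cbind(motion, rbind(0, diff(motion)))
  in_brain <- brain_mask(series)
  rim <- rim_mask(in_brain, series$coords, series$grid_shape)
  csf <- tissue_mask(series, "CSF")

  feats <- data.frame(
    max_motion_cor = vapply(seq_len(k), function(i)
      max(abs(suppressWarnings(stats::cor(ica$courses[, i], mot_design))),
          na.rm = TRUE), numeric(1)),
    hfc = vapply(seq_len(k), function(i)
      high_frequency_content(ica$courses[, i], series$tr), numeric(1)),
    edge_fraction = vapply(seq_len(k), function(i) {
      w <- abs(ica$maps[in_brain, i])
      sum(abs(ica$maps[rim, i])) / sum(w)
    }, numeric(1)),
    csf_fraction = vapply(seq_len(k), function(i) {
      w <- abs(ica$maps[in_brain, i])
      sum(abs(ica$maps[csf & in_brain, i])) / sum(w)
    }, numeric(1)))
  feats$classification <- ifelse(
    feats$csf_fraction > theta_csf |
      feats$hfc > theta_hfc |
      feats$max_motion_cor / boundary_motion +
        feats$edge_fraction / boundary_edge > 1,
    "noise", "signal")

  structure(list(maps = ica$maps, courses = ica$courses, features = feats,
                 thresholds = list(theta_csf = theta_csf,
                                   theta_hfc = theta_hfc,
                                   boundary_motion = boundary_motion,
                                   boundary_edge = boundary_edge),
                 seed = seed),
            class = "ica_component_report")
}

#' @export
print.ica_component_report <- function(x, ...) {
  cat(sprintf("<ica_component_report> %d components, %d classified as noise\n",
              nrow(x$features), sum(x$features$classification == "noise")))
  invisible(x)
}

#' Build the AROMA nuisance set from a component report
#'
#' Noise-classified component time courses become the regressors; by default
#' the removal mode is non-aggressive (the full component set is fitted
#' jointly and only the noise contribution subtracted).
#'
#' @param report an `ica_component_report`.
#' @param mode `"nonaggressive"` (default) or `"aggressive"`.
#' @return a `nuisance_set` (method `"AROMA"`).
#' @export
aroma_nuisance <- function(report, mode = c("nonaggressive", "aggressive")) {
  mode <- match.arg(mode)
  noise_idx <- which(report$features$classification == "noise")
  reg <- report$courses[, noise_idx, drop = FALSE]
  if (ncol(reg) > 0)
    colnames(reg) <- sprintf("aroma_motion_%02d", noise_idx)
  nuisance_set("AROMA", reg, mode = mode,
               metadata = list(all_regressors = report$courses,
                               noise_idx = noise_idx,
                               features = report$features))
}
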