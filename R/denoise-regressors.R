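#' Nuisance regressor container
#'
#' @param method one of `"GSR"`, `"WM-CSF"`, `"aCompCor"`, `"tCompCor"`,
#'   `"AROMA"`, `"none"`.
#' @param regressors timepoints x k numeric matrix (columns zero-mean).
#' @param mode `"aggressive"` (full OLS residual) or `"nonaggressive"`
#'   (partial removal; ICA only).
#' @param metadata free-form list (masks used, explained variance, component
#'   features, full design for non-aggressive removal).
#' @return a `nuisance_set`.
#' @export
nuisance_set <- function(method, regressors, mode = "aggressive",
                         metadata = list()) {
  method <- match.arg(method, c("GSR", "WM-CSF", "aCompCor", "tCompCor",
                                "AROMA", "none"))
  regressors <- as.matrix(regressors)
  if (method == "none" && ncol(regressors) != 0L)
    stop("method 'none' must carry zero regressors")
  if (ncol(regressors) > 0)
    regressors <- sweep(regressors, 2, colMeans(regressors))
  structure(list(method = method, regressors = regressors, mode = mode,
                 metadata = metadata),
            class = "nuisance_set")
}

#' @export
print.nuisance_set <- function(x, ...) {
  cat(sprintf("<nuisance_set> %s: %d regressor(s), %s removal\n",
              x$method, ncol(x$regressors), x$mode))
  invisible(x)
}

#' Empty nuisance set: the no-correction baseline
#' @param series a [voxel_ts] (only its length is used).
#' @return a `nuisance_set` with zero regressors.
#' @export
no_correction <- function(series) {
  nuisance_set("none", matrix(numeric(0), n_timepoints(series), 0))
}

#' Global-signal regressor
#'
#' Mean time course over the brain mask excluding CSF, demeaned.
#'
#' @param series a [voxel_ts].
#' @param brain,csf logical per-voxel masks; defaults come from the series'
#'   tissue labels.
#' @return a `nuisance_set` (method `"GSR"`, one column).
#' @export
gsr_regressor <- function(series, brain = brain_mask(series),
                          csf = tissue_mask(series, "CSF")) {
  keep <- brain & !csf
  if (!any(keep)) stop("empty mask: no brain voxels remain after excluding CSF")
  g <- colMeans(series$values[keep, , drop = FALSE])
  if (all(abs(g - mean(g)) < .Machine$double.eps))
    warning("global signal is constant (all-zero data?)")
  nuisance_set("GSR", matrix(g - mean(g), ncol = 1,
                             dimnames = list(NULL, "global_signal")),
               metadata = list(n_voxels = sum(keep)))
}

#' White-matter and CSF mean regressors
#'
#' Mean time courses over eroded WM and CSF masks (6-neighbour binary
#' erosion, depth `erosion_voxels`), demeaned.
#'
#' @param series a [voxel_ts] with grid information.
#' @param wm,csf logical per-voxel masks (defaults from tissue labels).
#' @param erosion_voxels erosion depth in voxels (0 = plain mask means).
#' @return a `nuisance_set` (method `"WM-CSF"`, two columns).
#' @export
wmcsf_regressors <- function(series, wm = tissue_mask(series, "WM"),
                             csf = tissue_mask(series, "CSF"),
                             erosion_voxels = 1L) {
  masks <- list(white_matter = wm, csf = csf)
  courses <- lapply(names(masks), function(nm) {
    m <- erode_mask(masks[[nm]], series$coords, series$grid_shape,
                    erosion_voxels)
    if (!any(m))
      stop(sprintf("erosion by %d voxel(s) empties the %s mask",
                   erosion_voxels, nm))
    colMeans(series$values[m, , drop = FALSE])
  })
  reg <- do.call(cbind, courses)
  colnames(reg) <- names(masks)
  nuisance_set("WM-CSF", reg,
               metadata = list(erosion_voxels = erosion_voxels))
}

# PCA time courses of a row-demeaned, variance-normalized voxel x time matrix;
# constant rows dropped.  Returns list(courses = T x k, explained, dropped).
compcor_pca <- function(values, k = NULL, variance_target = NULL) {
  values <- values - rowMeans(values)
  sds <- sqrt(rowSums(values^2) / (ncol(values) - 1))
  const <- sds < .Machine$double.eps * 100
  values <- values[!const, , drop = FALSE] / sds[!const]
  if (nrow(values) == 0) stop("no non-constant voxels in the noise mask")
  sv <- svd(t(values), nu = min(dim(values)), nv = 0)
  expl <- sv$d^2 / sum(sv$d^2)
  if (!is.null(variance_target)) {
    k <- which(cumsum(expl) >= variance_target)[1]
    if (is.na(k)) k <- length(expl)
  }
  k <- min(k, ncol(sv$u))
  list(courses = sv$u[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)], all_explained = expl,
       dropped = sum(const))
}

#' Anatomical CompCor regressors
#'
#' Principal-component time courses of the demeaned, variance-normalized
#' voxel x time matrix restricted to the combined eroded WM+CSF mask; the
#' `n_components` components with highest explained variance are returned.
#'
#' @inheritParams wmcsf_regressors
#' @param n_components number of components to keep (default 5).
#' @param combined if `TRUE` (default) one decomposition on the combined
#'   WM+CSF mask; if `FALSE`, separate per-tissue decompositions are stacked.
#' @return a `nuisance_set` (method `"aCompCor"`); metadata records explained
#'   variance and dropped constant voxels.
#' @export
acompcor_regressors <- function(series, wm = tissue_mask(series, "WM"),
                                csf = tissue_mask(series, "CSF"),
                                n_components = 5L, erosion_voxels = 1L,
                                combined = TRUE) {
  ewm <- erode_mask(wm, series$coords, series$grid_shape, erosion_voxels)
  ecsf <- erode_mask(csf, series$coords, series$grid_shape, erosion_voxels)
  if (combined) {
    mask <- ewm | ecsf
    if (sum(mask) <= n_components)
      stop(sprintf("only %d eroded WM+CSF voxels for %d components",
                   sum(mask), n_components))
    pca <- compcor_pca(series$values[mask, , drop = FALSE], k = n_components)
    reg <- pca$courses
    meta <- list(explained = pca$explained, dropped = pca$dropped,
                 n_voxels = sum(mask))
  } else {
    parts <- lapply(list(wm = ewm, csf = ecsf), function(m)
      compcor_pca(series$values[m, , drop = FALSE],
                  k = ceiling(n_components / 2)))
    reg <- cbind(parts$wm$courses, parts$csf$courses)[, seq_len(
      min(n_components, sum(vapply(parts, function(p) ncol(p$courses), 1L)))),
      drop = FALSE]
    meta <- list(explained = lapply(parts, `[[`, "explained"))
  }
  colnames(reg) <- sprintf("a_comp_cor_%02d", seq_len(ncol(reg)) - 1L)
  nuisance_set("aCompCor", reg, metadata = meta)
}

#' Temporal CompCor regressors
#'
#' The noise ROI is the set of brain voxels whose temporal standard deviation
#' exceeds the `std_percentile` percentile, irrespective of tissue.  The
#' leading principal components up to a cumulative explained variance of
#' `variance_target` are all returned for removal.
#'
#' @param series a [voxel_ts].
#' @param brain logical per-voxel mask (default: non-background tissue).
#' @param std_percentile percentile (0-100) of temporal sd defining the
#'   high-variance noise ROI.
#' @param variance_target cumulative explained-variance cut for component
#'   selection (1.0 keeps the full rank).
#' @return a `nuisance_set` (method `"tCompCor"`).
#' @export
tcompcor_regressors <- function(series, brain = brain_mask(series),
                                std_percentile = 98, variance_target = 0.5) {
  v <- series$values[brain, , drop = FALSE]
  sds <- apply(v, 1, stats::sd)
  thr <- stats::quantile(sds, std_percentile / 100)
  sel <- sds > thr
  if (!any(sel)) {
    warning("degenerate variance profile; falling back to top-k voxels")
    sel <- rank(-sds, ties.method = "first") <= max(2, ceiling(0.02 * length(sds)))
  }
  pca <- compcor_pca(v[sel, , drop = FALSE], variance_target = variance_target)
  reg <- pca$courses
  colnames(reg) <- sprintf("t_comp_cor_%02d", seq_len(ncol(reg)) - 1L)
  nuisance_set("tCompCor", reg,
               metadata = list(explained = pca$explained,
                               n_voxels = sum(sel),
                               variance_target = variance_target))
}

#' Remove nuisance regressors from a BOLD series
#'
#' Aggressive mode: per-voxel ordinary-least-squares residual against an
#' intercept plus the regressors; residuals are orthogonal to every removed
#' regressor, and per-voxel variance never increases.  Non-aggressive mode
#' (ICA methods): the full component set in
#' `nuisance$metadata$all_regressors` is fitted jointly and only the
#' noise-classified columns' contribution is subtracted.
#'
#' @param series a [voxel_ts].
#' @param nuisance a `nuisance_set`; `method = "none"` returns the demeaned
#'   series unchanged apart from the mean.
#' @return denoised [voxel_ts].
#' @export
regress_nuisance <- function(series, nuisance) {
  v <- series$values
  out <- series
  if (nuisance$mode == "nonaggressive") {
    M <- nuisance$metadata$all_regressors
    if (is.null(M)) stop("non-aggressive removal needs metadata$all_regressors")
    noise_idx <- nuisance$metadata$noise_idx
    if (is.null(noise_idx)) stop("non-aggressive removal needs metadata$noise_idx")
    X <- cbind(1, M)
    X <- drop_collinear(X)
    B <- solve(crossprod(X), t(X) %*% t(v))          # (k+1) x V
    keep_cols <- match_noise_cols(X, M, noise_idx)
    fitted_noise <- X[, keep_cols, drop = FALSE] %*%
      B[keep_cols, , drop = FALSE]
    out$values <- v - t(fitted_noise)
    return(out)
  }
  if (ncol(nuisance$regressors) != 0 &&
      nrow(nuisance$regressors) != ncol(v))
    stop("regressor rows must match the number of timepoints")
  X <- cbind(intercept = 1, nuisance$regressors)
  X <- drop_collinear(X)
  # residual via the thin QR of the design
  qr_x <- qr(X)
  Q <- qr.Q(qr_x)
  out$values <- v - (v %*% Q) %*% t(Q)
  out
}

# Drop collinear design columns (with a warning naming how many).
drop_collinear <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning(sprintf("dropping %d collinear regressor column(s)",
                    ncol(X) - qr_x$rank))
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }
  X
}

# Columns of the (possibly reduced) design X that correspond to the
# noise-classified columns of the original component matrix M.
match_noise_cols <- function(X, M, noise_idx) {
  # X = cbind(1, M) possibly with columns dropped; match by identity of values
  cols <- integer(0)
  for (j in noise_idx) {
    hit <- which(vapply(seq_len(ncol(X)), function(c)
      isTRUE(all.equal(X[, c], M[, j], check.attributes = FALSE)), logical(1)))
    if (length(hit)) cols <- c(cols, hit[1])
  }
  cols
}
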