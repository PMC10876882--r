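#' Voxel-by-time BOLD container
#'
#' `voxel_ts()` wraps a voxels x timepoints matrix together with its sampling
#' interval and optional spatial bookkeeping: integer voxel coordinates, a
#' tissue label per voxel (`"GM"`, `"WM"`, `"CSF"`, `"BG"`), a region-of-interest
#' (ROI) index and a functional-network index.  All analysis functions in the
#' package operate on this container.
#'
#' @param values numeric matrix, voxels in rows, timepoints in columns.
#' @param tr sampling interval in seconds (the repetition time).
#' @param coords optional integer matrix (voxels x 3) of grid coordinates.
#' @param tissue optional character vector of per-voxel tissue labels.
#' @param roi optional integer vector of per-voxel ROI labels (0 = none).
#' @param network optional integer vector of per-voxel network labels (0 = none).
#' @param grid_shape optional length-3 integer vector giving the volume grid.
#' @return an object of class `voxel_ts`.
#' @export
voxel_ts <- function(values, tr, coords = NULL, tissue = NULL, roi = NULL,
                     network = NULL, grid_shape = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (ncol(values) < 2L) stop("a voxel time series needs at least 2 timepoints")
  if (anyNA(values)) stop("values must not contain missing entries")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a single positive number of seconds")
  v <- nrow(values)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == v, ncol(coords) == 3L)
  }
  for (lab in list(tissue, roi, network))
    if (!is.null(lab) && length(lab) != v)
      stop("per-voxel labels must match the number of rows")
  structure(
    list(values = values, tr = tr, coords = coords, tissue = tissue,
         roi = roi, network = network,
         grid_shape = if (!is.null(grid_shape)) as.integer(grid_shape)),
    class = "voxel_ts")
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat(sprintf("<voxel_ts> %d voxels x %d timepoints, TR = %.3g s (fs = %.3g Hz)\n",
              nrow(x$values), ncol(x$values), x$tr, 1 / x$tr))
  if (!is.null(x$tissue)) {
    tab <- table(x$tissue)
    cat("  tissue:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.voxel_ts <- function(x) dim(x$values)

n_timepoints <- function(x) ncol(x$values)

nyquist <- function(x) 1 / (2 * x$tr)

#' Tissue mask helper
#'
#' @param series a [voxel_ts] with tissue labels.
#' @param tissue character vector of tissue classes to include.
#' @return logical per-voxel mask.
#' @export
tissue_mask <- function(series, tissue) {
  if (is.null(series$tissue)) stop("series carries no tissue labels")
  series$tissue %in% tissue
}

#' In-brain mask (everything that is not background)
#' @param series a [voxel_ts].
#' @return logical per-voxel mask.
#' @export
brain_mask <- function(series) {
  if (is.null(series$tissue)) rep(TRUE, nrow(series$values))
  else series$tissue != "BG"
}

# Place a per-voxel vector into a 3-D array given coords and grid shape.
vec_to_vol <- function(x, coords, grid_shape, fill = 0) {
  vol <- array(fill, dim = grid_shape)
  vol[coords] <- x
  vol
}

# Value of the 6-neighbour at offset `by` along axis `ax`; FALSE outside the
# volume boundary.
shift_logical <- function(vol, ax, by) {
  d <- dim(vol)
  out <- array(FALSE, d)
  dst <- lapply(d, seq_len)
  src <- lapply(d, seq_len)
  n <- d[ax]
  if (by == 1L) { dst[[ax]] <- 1:(n - 1L); src[[ax]] <- 2:n }
  else          { dst[[ax]] <- 2:n;        src[[ax]] <- 1:(n - 1L) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

# Binary erosion of a logical per-voxel mask, repeated `iterations` times, on
# the grid implied by coords/grid_shape.  The default structuring element is
# in-plane (x/y 4-neighbour), matching thick-slice acquisitions where
# through-slice erosion would empty thin tissue shells; pass axes = 1:3 for
# the full 6-neighbour element.
erode_mask <- function(mask, coords, grid_shape, iterations = 1L,
                       axes = c(1L, 2L)) {
  if (iterations < 1L) return(mask)
  vol <- vec_to_vol(mask, coords, grid_shape, fill = FALSE)
  for (it in seq_len(iterations)) {
    keep <- vol
    for (ax in axes) for (by in c(-1L, 1L)) keep <- keep & shift_logical(vol, ax, by)
    vol <- keep
  }
  as.logical(vol[coords])
}

# Rim mask: in-brain voxels with at least one out-of-brain 6-neighbour
# (including the volume boundary).
rim_mask <- function(in_brain, coords, grid_shape) {
  eroded <- erode_mask(in_brain, coords, grid_shape, 1L, axes = 1:3)
  in_brain & !eroded
}
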