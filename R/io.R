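#' Read a 4-D BOLD volume into a [voxel_ts]
#'
#' Voxels are taken in array order over the full grid; tissue/ROI labels can
#' be attached afterwards from label volumes read with [load_labels()].  The
#' sampling interval is taken from the NIfTI header (`pixdim[4]`) unless `tr`
#' is given explicitly.
#'
#' @param path path to a NIfTI file.
#' @param tr optional sampling interval in seconds, overriding the header.
#' @return a [voxel_ts].
#' @export
load_bold <- function(path, tr = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4-D volume, got %d dimensions", length(d)))
  if (is.null(tr)) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0)
      stop("header carries no usable sampling interval; pass tr explicitly")
  }
  grid <- d[1:3]
  coords <- as.matrix(expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                                  z = seq_len(grid[3])))
  values <- matrix(as.numeric(img), prod(grid), d[4])
  voxel_ts(values, tr = tr, coords = coords, grid_shape = grid)
}

#' Write a [voxel_ts] as a 4-D NIfTI volume
#'
#' Requires the series to carry a `grid_shape`; the TR is stored in the
#' header's fourth pixdim.
#'
#' @param series a [voxel_ts] with grid information.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_bold <- function(series, path) {
  if (is.null(series$grid_shape) || is.null(series$coords))
    stop("series carries no grid information; cannot write a volume")
  g <- series$grid_shape
  arr <- array(0, dim = c(g, ncol(series$values)))
  for (t in seq_len(ncol(series$values)))
    arr[, , , t][series$coords] <- series$values[, t]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, series$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a per-voxel label volume (tissue or parcellation)
#'
#' Tissue labels are stored as integer codes 0=BG, 1=GM, 2=WM, 3=CSF; ROI and
#' network volumes store their integer labels directly.
#'
#' @param labels character tissue vector or integer label vector.
#' @param coords,grid_shape grid bookkeeping as in [voxel_ts].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_labels <- function(labels, coords, grid_shape, path) {
  if (is.character(labels))
    labels <- match(labels, c("BG", "GM", "WM", "CSF")) - 1L
  vol <- vec_to_vol(as.numeric(labels), as.matrix(coords), grid_shape)
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' @rdname save_labels
#' @param tissue if `TRUE`, decode integer codes back to tissue names.
#' @export
load_labels <- function(path, tissue = FALSE) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3-D label volume")
  x <- as.integer(round(as.numeric(img)))
  if (tissue) c("BG", "GM", "WM", "CSF")[x + 1L] else x
}

#' Write a synthetic subject to disk in standard formats
#'
#' BOLD and label volumes as NIfTI, motion parameters and nuisance confounds
#' as fMRIPrep-style TSV, physiological traces as two-column TSV, ground
#' truth as JSON + TSV.
#'
#' @param subject a `synthetic_subject`.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, sprintf(...))
  b <- subject$bold
  paths <- list(
    bold = p("%s_bold.nii.gz", subject$id),
    tissue = p("%s_tissue.nii.gz", subject$id),
    roi = p("%s_parcellation.nii.gz", subject$id),
    network = p("%s_networks.nii.gz", subject$id),
    motion = p("%s_motion.tsv", subject$id),
    physio = p("%s_physio.tsv", subject$id),
    ground_truth = p("%s_ground_truth.json", subject$id),
    courses = p("%s_true_courses.tsv", subject$id))
  save_bold(b, paths$bold)
  save_labels(b$tissue, b$coords, b$grid_shape, paths$tissue)
  save_labels(b$roi, b$coords, b$grid_shape, paths$roi)
  save_labels(b$network, b$coords, b$grid_shape, paths$network)
  utils::write.table(as.data.frame(subject$motion), paths$motion,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(time = subject$physio$time, cardiac = subject$physio$cardiac,
               respiratory = subject$physio$respiratory),
    paths$physio, sep = "\t", row.names = FALSE, quote = FALSE)
  gt <- subject$ground_truth
  jsonlite::write_json(
    list(id = subject$id, group = subject$group,
         cardiac_freq = gt$cardiac_freq, resp_freq = gt$resp_freq,
         within_net_corr = gt$within_net_corr, baseline = gt$baseline,
         physio_seed = subject$physio_seed),
    paths$ground_truth, auto_unbox = TRUE, digits = NA)
  courses <- data.frame(cardiac = gt$courses$cardiac,
                        respiratory = gt$courses$respiratory,
                        global = gt$courses$global, drift = gt$courses$drift)
  utils::write.table(courses, paths$courses, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' Write a whole cohort plus a JSON manifest
#'
#' @param cohort list of `synthetic_subject`s from [generate_cohort()].
#' @param dir output directory.
#' @param config the generating [cohort_config()], recorded in the manifest.
#' @return path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(s) {
    paths <- write_subject(s, file.path(dir, s$id))
    c(list(id = s$id, group = s$group, physio_seed = s$physio_seed),
      lapply(paths, function(x) sub(paste0(dir, "/"), "", x, fixed = TRUE)))
  })
  manifest <- list(n_subjects = length(cohort),
                   seed = if (!is.null(config)) config$seed,
                   config = if (!is.null(config)) unclass(config),
                   subjects = entries)
  mpath <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mpath)
}

#' Write a nuisance set as an fMRIPrep-style confounds TSV
#'
#' Column names follow the fMRIPrep convention: `global_signal`,
#' `white_matter`, `csf`, `a_comp_cor_00`..., `t_comp_cor_00`...,
#' `aroma_motion_00`....
#'
#' @param nuisance a `nuisance_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_confounds <- function(nuisance, path) {
  reg <- nuisance$regressors
  if (ncol(reg) == 0L) reg <- matrix(numeric(0), nrow(reg), 0)
  utils::write.table(as.data.frame(reg), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
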