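#' Template-based-rotation functional-connectivity maps
#'
#' Stage 1 reverses the direction of prediction relative to dual regression:
#' each spatial template is predicted as a linear sum of the data volumes by
#' least squares over voxels (volumes are the predictors), yielding one
#' time-weight course per template.  Stage 2 regresses every voxel's time
#' series on that course and reports the t-statistic of the slope, giving an
#' unthresholded per-network t-map.  Maps are invariant to template scaling.
#' When the voxel count does not exceed the volume count the stage-1 normal
#' equations are rank deficient and a small ridge penalty is applied (the
#' penalty is recorded in the result's attributes).
#'
#' @param series a [voxel_ts].
#' @param templates voxels x k numeric matrix of spatial templates (one
#'   column per network), on the same voxel grid as `series`.
#' @param mask logical per-voxel mask over which stage 1 is solved (default:
#'   in-brain voxels).
#' @param ridge_rel ridge penalty for stage 1, relative to the mean diagonal
#'   of the volumes' Gram matrix, applied whenever the voxel count does not
#'   exceed the volume count (the normal equations are then rank deficient
#'   and unpenalized least squares interpolates the template through voxel
#'   noise, which destroys the map's dependence on the true correlation
#'   structure).  The default of 1 keeps stage 1 close to the
#'   template-weighted mean-course regime.
#' @return voxels x k matrix of t-maps (class `fc_maps`), with the stage-1
#'   courses in `attr(, "courses")` and the penalty in `attr(, "ridge")`.
#' @export
tbr_maps <- function(series, templates, mask = brain_mask(series),
                     ridge_rel = 1) {
  templates <- as.matrix(templates)
  if (nrow(templates) != nrow(series$values))
    stop("templates must live on the data's voxel grid")
  if (any(colSums(templates != 0) == 0)) stop("templates must be nonzero")
  X <- series$values[mask, , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))                 # centre each volume
  Tt <- sweep(templates[mask, , drop = FALSE], 2,
              colMeans(templates[mask, , drop = FALSE]))
  G <- crossprod(X)                             # T x T
  ridge <- 0
  ch <- if (nrow(X) > ncol(X))
    tryCatch(chol(G), error = function(e) NULL) else NULL
  if (is.null(ch)) {
    ridge <- ridge_rel * mean(diag(G))
    ch <- chol(G + diag(ridge, ncol(G)))
  }
  courses <- backsolve(ch, backsolve(ch, crossprod(X, Tt), transpose = TRUE))
  # stage 2: per-voxel t of the slope on each course
  n <- ncol(series$values)
  V <- series$values - rowMeans(series$values)
  tmap <- apply(courses, 2, function(w) {
    w <- w - mean(w)
    r <- as.vector(V %*% w) / (sqrt(rowSums(V^2)) * sqrt(sum(w^2)))
    r[!is.finite(r)] <- 0
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    r * sqrt((n - 2) / (1 - r^2))
  })
  colnames(tmap) <- colnames(templates)
  attr(tmap, "courses") <- courses
  attr(tmap, "ridge") <- ridge
  class(tmap) <- c("fc_maps", class(tmap))
  tmap
}

#' ROI-level Pearson correlation matrix
#'
#' ROI time courses are voxel means within each ROI; empty ROIs are excluded
#' with a message.
#'
#' @param series a [voxel_ts] with ROI labels (or supply `roi`).
#' @param roi optional integer per-voxel ROI labels (0 = background).
#' @return a `connectivity_matrix`: correlation matrix with ROI network
#'   assignment in `attr(, "network")`.
#' @export
roi_connectivity <- function(series, roi = series$roi) {
  if (is.null(roi)) stop("series carries no ROI labels")
  ids <- sort(unique(roi[roi > 0]))
  courses <- vapply(ids, function(r)
    colMeans(series$values[roi == r, , drop = FALSE]),
    numeric(ncol(series$values)))
  ok <- apply(courses, 2, stats::sd) > 0
  if (!all(ok)) message(sum(!ok), " constant/empty ROI(s) excluded")
  cm <- stats::cor(courses[, ok, drop = FALSE])
  dimnames(cm) <- list(ids[ok], ids[ok])
  if (!is.null(series$network)) {
    netmap <- vapply(ids[ok], function(r)
      series$network[which(roi == r)[1]], numeric(1))
    attr(cm, "network") <- as.integer(netmap)
  }
  class(cm) <- c("connectivity_matrix", class(cm))
  cm
}

# unique within-network and between-network pair values for one network
network_pairs <- function(cm, network, k) {
  idx_in <- which(network == k)
  idx_out <- which(network != k)
  within <- cm[idx_in, idx_in][upper.tri(diag(length(idx_in)))]
  between <- as.vector(cm[idx_in, idx_out])
  list(within = within, between = between)
}

#' Mean within-network correlation
#'
#' Mean over unique within-network ROI pairs (diagonal excluded), per
#' network.  Singleton networks are returned as `NA` with a warning.
#'
#' @param cm a `connectivity_matrix` with a network attribute (or pass
#'   `network`).
#' @param network integer ROI-to-network assignment.
#' @return named numeric vector, one value per network.
#' @export
network_mean_correlation <- function(cm, network = attr(cm, "network")) {
  if (is.null(network)) stop("no ROI-to-network assignment available")
  ks <- sort(unique(network))
  out <- vapply(ks, function(k) {
    idx <- which(network == k)
    if (length(idx) < 2) {
      warning(sprintf("network %d has a single ROI; mean undefined", k))
      return(NA_real_)
    }
    mean(cm[idx, idx][upper.tri(diag(length(idx)))])
  }, numeric(1))
  names(out) <- paste0("network_", ks)
  out
}

# Wilcoxon rank-sum z statistic (normal approximation, tie-corrected, no
# continuity correction) for x vs y.
ranksum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(0)   # all values tied: no evidence either way
  (U - n1 * n2 / 2) / sqrt(sigma2)
}

#' Functional-connectivity contrast (FCC)
#'
#' Per network, the rank-sum z statistic comparing within-network connectivity
#' values against between-network values (pairs linking that network's ROIs
#' to all others); higher z means stronger network segregation.  The FCC is
#' the mean z over networks.
#'
#' @inheritParams network_mean_correlation
#' @return list with `z` (per network) and `fcc` (their mean).
#' @export
fcc <- function(cm, network = attr(cm, "network")) {
  if (is.null(network)) stop("no ROI-to-network assignment available")
  ks <- sort(unique(network))
  z <- vapply(ks, function(k) {
    p <- network_pairs(cm, network, k)
    if (length(p$within) < 2 || length(p$between) < 2)
      stop(sprintf("network %d has too few pairs for a rank-sum test", k))
    ranksum_z(p$within, p$between)
  }, numeric(1))
  names(z) <- paste0("network_", ks)
  list(z = z, fcc = mean(z))
}

#' Cosine-similarity adjacency across subjects
#'
#' A_ij is the cosine similarity between subject i's and subject j's
#' vectorized connectivity maps; the diagonal is set to zero and excluded
#' from the degrees `k_i` and the connection mass `m = sum(A)/2`.
#'
#' @param maps subjects x features numeric matrix (one row per subject, e.g.
#'   a network's t-map restricted to a common GM mask).
#' @param groups character/factor of group labels (`"young"`/`"old"`),
#'   converted to signs +1/-1 for [modularity()].
#' @param center if `TRUE`, subtract the cohort-mean map before computing
#'   similarities.  Raw connectivity maps share a large common pattern (the
#'   network geometry itself), which dominates the cosine and masks
#'   between-subject structure; centering measures similarity of each
#'   subject's *deviation* from the cohort mean.
#' @return a `modularity_input`: list with `A`, `s`, `k`, `m`.
#' @export
cosine_similarity_adjacency <- function(maps, groups, center = FALSE) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 2) stop("need at least two subjects")
  if (center) maps <- sweep(maps, 2, colMeans(maps))
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm < .Machine$double.eps)) stop("zero-norm connectivity map")
  U <- maps / nrm
  A <- U %*% t(U)
  diag(A) <- 0
  s <- ifelse(groups == "young", 1, -1)
  structure(list(A = A, s = s, k = rowSums(A), m = sum(A) / 2),
            class = "modularity_input")
}

#' Age-partition modularity
#'
#' `Q = 1/(4m) * sum_ij (A_ij - k_i k_j / (2m)) s_i s_j`, the Newman-style
#' partition quality of the fixed young/old split on the subject-similarity
#' graph: the double sum runs over all ordered pairs including i = j (with
#' `A_ii = 0`).  Raw cosine values may be negative; `clip_negative = TRUE`
#' zeroes them first (the configuration null model assumes nonnegative
#' weights).
#'
#' @param input a `modularity_input` (from [cosine_similarity_adjacency()]),
#'   or a list with `A` and `s`.
#' @param clip_negative clip negative similarities to zero before computing.
#' @return scalar Q.
#' @export
modularity <- function(input, clip_negative = FALSE) {
  A <- input$A
  s <- input$s
  if (!all(s %in% c(-1, 1))) stop("group signs must be +1/-1")
  if (clip_negative) A <- pmax(A, 0)
  diag(A) <- 0
  k <- rowSums(A)
  m <- sum(A) / 2
  if (m <= 0) stop("non-positive connection mass; modularity undefined")
  B <- A - outer(k, k) / (2 * m)
  sum(B * outer(s, s)) / (4 * m)
}

#' Permutation null for the age-partition modularity
#'
#' Re-draws the group signs `n_perm` times (preserving group sizes) and
#' returns the observed Q, the permutation quantile, and a z-like
#' standardized score.
#'
#' @inheritParams modularity
#' @param n_perm number of permutations.
#' @return list with `q`, `null` (vector), `quantile`, `z`.
#' @export
modularity_permutation <- function(input, n_perm = 1000, clip_negative = FALSE) {
  q <- modularity(input, clip_negative)
  s <- input$s
  null <- vapply(seq_len(n_perm), function(i) {
    inp <- input
    inp$s <- sample(s)
    modularity(inp, clip_negative)
  }, numeric(1))
  list(q = q, null = null,
       quantile = mean(null < q),
       z = (q - mean(null)) / stats::sd(null))
}

#' Voxelwise two-sample group-difference t-map
#'
#' Unpaired pooled-variance t per voxel, young minus old.
#'
#' @param maps_young,maps_old subjects x voxels matrices of per-subject maps.
#' @return list with `t` (per voxel) and `median_t`.
#' @export
group_difference_tmap <- function(maps_young, maps_old) {
  maps_young <- as.matrix(maps_young); maps_old <- as.matrix(maps_old)
  n1 <- nrow(maps_young); n2 <- nrow(maps_old)
  if (n1 < 2 || n2 < 2) stop("need at least two subjects per group")
  m1 <- colMeans(maps_young); m2 <- colMeans(maps_old)
  v1 <- apply(maps_young, 2, stats::var)
  v2 <- apply(maps_old, 2, stats::var)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  tt[!is.finite(tt)] <- 0
  list(t = tt, median_t = stats::median(tt))
}

#' Network templates from a synthetic subject's ground truth
#'
#' Binary spatial maps of each network's GM voxels, usable as the template
#' set for [tbr_maps()] in synthetic mode.
#'
#' @param series a [voxel_ts] with network labels.
#' @return voxels x n_networks indicator matrix.
#' @export
network_templates <- function(series) {
  ks <- sort(unique(series$network[series$network > 0]))
  tpl <- vapply(ks, function(k) as.numeric(series$network == k),
                numeric(nrow(series$values)))
  colnames(tpl) <- paste0("network_", ks)
  tpl
}
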