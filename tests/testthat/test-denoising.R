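test_that("GSR recovers a shared global course and validates masks", {
  set.seed(11)
  n <- 400
  g <- denoisebench:::standardize(rnorm(n))
  vals <- matrix(rep(g, each = 1000), 1000, n) + matrix(rnorm(1000 * n), 1000)
  s <- voxel_ts(vals, tr = 0.5, tissue = rep("GM", 1000))
  reg <- gsr_regressor(s, brain = rep(TRUE, 1000), csf = rep(FALSE, 1000))
  expect_gt(cor(reg$regressors[, 1], g), 0.99)
  expect_equal(mean(reg$regressors[, 1]), 0)

  z <- voxel_ts(matrix(0, 10, 50), tr = 0.5, tissue = rep("GM", 10))
  expect_warning(gsr_regressor(z, brain = rep(TRUE, 10),
                               csf = rep(FALSE, 10)), "constant")
  expect_error(gsr_regressor(s, brain = rep(TRUE, 1000),
                             csf = rep(TRUE, 1000)), "empty mask")
})

test_that("WM-CSF regressors recover the planted tissue courses", {
  lay <- grid_layout()
  n <- 400
  set.seed(12)
  w <- denoisebench:::standardize(rnorm(n))
  cf <- denoisebench:::standardize(rnorm(n))
  vals <- matrix(rnorm(nrow(lay$coords) * n, sd = 0.05), nrow(lay$coords), n)
  vals[lay$tissue == "WM", ] <- vals[lay$tissue == "WM", ] +
    matrix(rep(w, each = sum(lay$tissue == "WM")), ncol = n)
  vals[lay$tissue == "CSF", ] <- vals[lay$tissue == "CSF", ] +
    matrix(rep(cf, each = sum(lay$tissue == "CSF")), ncol = n)
  s <- grid_series(vals)
  reg <- wmcsf_regressors(s)
  expect_gt(cor(reg$regressors[, "white_matter"], w), 0.99)
  expect_gt(cor(reg$regressors[, "csf"], cf), 0.99)
  # erosion 0 keeps the plain mask means
  reg0 <- wmcsf_regressors(s, erosion_voxels = 0)
  wm_mean <- colMeans(vals[lay$tissue == "WM", ])
  expect_equal(reg0$regressors[, "white_matter"], wm_mean - mean(wm_mean),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(wmcsf_regressors(s, erosion_voxels = 10), "empties")
})

test_that("aCompCor components match an independent SVD oracle", {
  lay <- grid_layout()
  mask <- lay$tissue %in% c("WM", "CSF")
  n <- 300
  set.seed(13)
  s1 <- denoisebench:::standardize(sin(2 * pi * 0.9 * (1:n) * 0.38))
  s2 <- denoisebench:::standardize(rnorm(n))
  s2 <- denoisebench:::standardize(residuals(lm(s2 ~ s1)))  # orthogonalize
  vals <- matrix(rnorm(nrow(lay$coords) * n, sd = 0.05), nrow(lay$coords), n)
  half <- which(mask)[seq_len(floor(sum(mask) / 2))]
  rest <- setdiff(which(mask), half)
  vals[half, ] <- vals[half, ] + 2 * matrix(rep(s1, each = length(half)), ncol = n)
  vals[rest, ] <- vals[rest, ] + matrix(rep(s2, each = length(rest)), ncol = n)
  s <- grid_series(vals)
  reg <- acompcor_regressors(s, n_components = 5, erosion_voxels = 0)
  expect_equal(ncol(reg$regressors), 5L)
  # two planted orthogonal sources are recovered by the leading components
  expect_gt(max(abs(cor(reg$regressors, s1))), 0.95)
  expect_gt(max(abs(cor(reg$regressors, s2))), 0.95)
  # Gram matrix: columns mutually orthogonal
  g <- crossprod(reg$regressors)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # explained variance non-increasing
  expect_true(all(diff(reg$metadata$explained) <= 1e-12))
  # independent oracle: eigendecomposition of the normalized data covariance
  x <- vals[mask, ]
  x <- x - rowMeans(x)
  x <- x / apply(x, 1, sd)
  ev <- eigen(crossprod(x), symmetric = TRUE)$vectors[, 1:5]
  cc <- abs(cor(ev, reg$regressors))
  expect_true(all(apply(cc, 1, max) > 0.99))
})

test_that("tCompCor isolates a high-variance localized source", {
  lay <- grid_layout()
  n <- 500
  set.seed(14)
  src <- denoisebench:::standardize(sin(2 * pi * 1.0 * (1:n) * 0.38))
  vals <- matrix(rnorm(nrow(lay$coords) * n, sd = 1), nrow(lay$coords), n)
  hot <- sample(which(lay$tissue != "BG"), 12)
  vals[hot, ] <- vals[hot, ] + 6 * matrix(rep(src, each = 12), ncol = n)
  s <- grid_series(vals)
  reg <- tcompcor_regressors(s)
  expect_gt(abs(cor(reg$regressors[, 1], src)), 0.95)
  # variance_target = 1 keeps the full rank of the noise-ROI matrix
  reg_full <- tcompcor_regressors(s, variance_target = 1)
  n_roi <- sum(apply(s$values[brain_mask(s), ], 1, sd) >
               quantile(apply(s$values[brain_mask(s), ], 1, sd), 0.98))
  expect_equal(ncol(reg_full$regressors), min(n_roi, n))
  # uniform noise still yields at least one component
  su <- grid_series(matrix(rnorm(nrow(lay$coords) * 100), ncol = 100))
  expect_gte(ncol(tcompcor_regressors(su)$regressors), 1L)
})

test_that("aggressive regression satisfies its algebraic contracts", {
  set.seed(15)
  n <- 120
  for (rep_i in 1:20) {
    reg <- matrix(rnorm(n * 3), n, 3)
    vals <- matrix(rnorm(8 * n), 8, n)
    vals[1, ] <- reg[, 1]                           # voxel equal to a regressor
    s <- voxel_ts(vals, tr = 1)
    ns <- nuisance_set("tCompCor", reg)
    res <- regress_nuisance(s, ns)
    # residuals orthogonal to the removed regressors (scaled by input norms)
    ip <- abs(crossprod(t(res$values), ns$regressors))
    norms <- outer(sqrt(rowSums(vals^2)),
                   sqrt(colSums(ns$regressors^2)))
    expect_lt(max(ip / norms), 1e-8)
    expect_lt(sqrt(sum(res$values[1, ]^2)) / sqrt(sum(vals[1, ]^2)), 1e-8)
    # variance never increases
    expect_true(all(apply(res$values, 1, var) <=
                    apply(vals, 1, var) + 1e-12))
    # column permutation leaves residuals unchanged
    res2 <- regress_nuisance(s, nuisance_set("tCompCor", reg[, c(3, 1, 2)]))
    expect_equal(res$values, res2$values, tolerance = 1e-10)
  }
})

test_that("voxels orthogonal to the design pass through unchanged", {
  set.seed(16)
  n <- 200
  reg <- matrix(rnorm(n * 2), n, 2)
  v <- rnorm(n)
  v <- residuals(lm(v ~ reg))          # orthogonal to intercept + regressors
  s <- voxel_ts(rbind(v, v), tr = 1)
  res <- regress_nuisance(s, nuisance_set("GSR", reg[, 1, drop = FALSE]))
  expect_equal(unname(res$values[1, ]), unname(v), tolerance = 1e-10)
})

test_that("non-aggressive removal equals aggressive under orthogonality", {
  set.seed(17)
  n <- 150
  for (rep_i in 1:20) {
    # orthonormal components, also orthogonal to the intercept
    M <- qr.Q(qr(cbind(1, matrix(rnorm(n * 5), n, 5))))[, -1]
    noise_idx <- c(2, 4)
    vals <- matrix(rnorm(6 * n), 6, n)
    s <- voxel_ts(vals, tr = 1)
    nonagg <- nuisance_set("AROMA", M[, noise_idx], mode = "nonaggressive",
                           metadata = list(all_regressors = M,
                                           noise_idx = noise_idx))
    agg <- nuisance_set("AROMA", M[, noise_idx])
    r1 <- regress_nuisance(s, nonagg)$values
    r2 <- regress_nuisance(s, agg)$values
    # aggressive also removes the mean; compare after demeaning both
    expect_lt(max(abs((r1 - rowMeans(r1)) - (r2 - rowMeans(r2)))), 1e-8)
  }
})

test_that("GSR residuals are uncorrelated with the global regressor", {
  s <- small_cohort()[[1]]
  b <- highpass(s$bold, 0.01)
  reg <- gsr_regressor(b)
  res <- regress_nuisance(b, reg)
  cc <- abs(cor(t(res$values[brain_mask(b), ]), reg$regressors[, 1]))
  expect_lt(max(cc, na.rm = TRUE), 1e-8)
})

test_that("collinear designs are reduced with a warning", {
  set.seed(18)
  n <- 100
  r <- rnorm(n)
  reg <- cbind(r, 2 * r)
  s <- voxel_ts(matrix(rnorm(3 * n), 3, n), tr = 1)
  expect_warning(regress_nuisance(s, nuisance_set("tCompCor", reg)),
                 "collinear")
})
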