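test_that("TBR maps recover a true network template and are scale invariant", {
  s <- small_cohort()[[1]]
  b <- highpass(s$bold, 0.01)
  tpl <- network_templates(b)
  tm <- tbr_maps(b, tpl)
  gm <- tissue_mask(b, "GM")
  rec <- diag(cor(tm[gm, ], tpl[gm, ]))
  expect_true(all(rec > 0.8))
  tm10 <- tbr_maps(b, 10 * tpl)
  expect_equal(unclass(tm10)[, ], unclass(tm)[, ], tolerance = 1e-8)
})

test_that("a template orthogonal to the data patterns yields a null t-map", {
  # voxel-rich regime (voxels > volumes) so stage 1 is honest least squares
  set.seed(31)
  V <- 400; n <- 80
  pats <- matrix(rnorm(V * 3), V, 3)
  courses <- matrix(rnorm(3 * n), 3, n)
  vals <- pats %*% courses + matrix(rnorm(V * n, sd = 1), V, n)
  s <- voxel_ts(vals, tr = 1)
  tpl <- rnorm(V)
  tpl <- residuals(lm(tpl ~ pats))      # orthogonal to every data pattern
  tm <- tbr_maps(s, matrix(tpl, ncol = 1), mask = rep(TRUE, V))
  expect_gt(mean(abs(tm) < 2), 0.95)
})

test_that("ROI connectivity matrices behave as correlation matrices", {
  set.seed(32)
  n <- 1950
  shared <- rnorm(n)
  roi <- rep(1:2, each = 3)
  vals <- matrix(rnorm(6 * n, sd = 0.3), 6, n)
  vals[1:3, ] <- vals[1:3, ] + matrix(rep(shared, each = 3), ncol = n)
  vals[4:6, ] <- vals[4:6, ] + matrix(rep(shared, each = 3), ncol = n)
  s <- voxel_ts(vals, tr = 0.38, roi = roi)
  cm <- roi_connectivity(s)
  expect_gt(cm[1, 2], 0.9)
  expect_true(isSymmetric(unclass(cm)))
  expect_equal(unname(diag(cm)), c(1, 1))

  # independent ROIs: off-diagonals obey the null sampling bound
  vals2 <- matrix(rnorm(20 * n), 20, n)
  s2 <- voxel_ts(vals2, tr = 0.38, roi = 1:20)
  cm2 <- roi_connectivity(s2)
  off <- cm2[upper.tri(cm2)]
  expect_gt(mean(abs(off) < 3 / sqrt(n)), 0.99)
})

test_that("network-mean correlation averages unique within-network pairs", {
  cm <- matrix(0.1, 6, 6)
  net <- rep(1:2, each = 3)
  for (k in 1:2) cm[net == k, net == k] <- 0.5
  diag(cm) <- 1
  out <- network_mean_correlation(cm, net)
  expect_equal(unname(out), c(0.5, 0.5))
  expect_equal(unname(network_mean_correlation(diag(6), net)), c(0, 0))
  # invariance to ROI permutation
  p <- c(4, 2, 6, 1, 3, 5)
  expect_equal(sort(unname(network_mean_correlation(cm[p, p], net[p]))),
               sort(unname(out)))
  expect_warning(network_mean_correlation(cm, c(1, 2, 2, 2, 2, 2)),
                 "single ROI")
})

# exact rank-sum enumeration oracle: P(U) by brute force over assignments
ranksum_z_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  N <- n1 + n2
  s2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  (U - mu) / sqrt(s2)
}

test_that("FCC matches the exact rank-sum statistic on worked sets", {
  z <- denoisebench:::ranksum_z(c(0.9, 0.8, 0.85), c(0.1, 0.2, 0.15))
  expect_equal(z, (9 - 4.5) / sqrt(5.25), tolerance = 1e-12)
  expect_equal(z, 1.9640, tolerance = 1e-4)
  expect_equal(denoisebench:::ranksum_z(c(1, 2, 3), c(1, 2, 3)), 0)
  # adding a positive constant to the within values never decreases z
  set.seed(33)
  for (i in 1:20) {
    w <- runif(5); b <- runif(7)
    expect_gte(denoisebench:::ranksum_z(w + 0.3, b),
               denoisebench:::ranksum_z(w, b) - 1e-12)
    expect_equal(denoisebench:::ranksum_z(w, b), ranksum_z_oracle(w, b))
  }
})

test_that("fcc aggregates per-network segregation on a block matrix", {
  set.seed(34)
  n_roi <- 21
  net <- rep(1:3, each = 7)
  cm <- matrix(0.1 + rnorm(n_roi^2, sd = 0.01), n_roi)
  cm <- (cm + t(cm)) / 2
  for (k in 1:3) cm[net == k, net == k] <- 0.6 + rnorm(49, sd = 0.01)
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  out <- fcc(cm, net)
  expect_length(out$z, 3)
  expect_true(all(out$z > 3))
  expect_equal(out$fcc, mean(out$z))
})

test_that("cosine adjacency handles identical, scaled, and degenerate maps", {
  maps <- matrix(rep(c(1, 2, 3, 4), 4), 4, 4, byrow = TRUE)
  mi <- cosine_similarity_adjacency(maps, c("young", "young", "old", "old"))
  expect_equal(mi$A[upper.tri(mi$A)], rep(1, 6))
  expect_equal(diag(mi$A), rep(0, 4))
  # scaling one subject's map leaves A unchanged
  maps2 <- maps; maps2[2, ] <- 5 * maps2[2, ]
  mi2 <- cosine_similarity_adjacency(maps2, c("young", "young", "old", "old"))
  expect_equal(mi2$A, mi$A)
  # orthogonal maps: zero mass, modularity undefined
  orth <- diag(4)
  mio <- cosine_similarity_adjacency(orth, c("young", "young", "old", "old"))
  expect_equal(mio$m, 0)
  expect_error(modularity(mio), "connection mass")
  expect_error(cosine_similarity_adjacency(rbind(0, orth[1:3, ]),
                                           rep("young", 4)), "zero-norm")
})

# independent oracle: literal double sum over ordered pairs
modularity_oracle <- function(A, s) {
  diag(A) <- 0
  k <- rowSums(A)
  m <- sum(A) / 2
  tot <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
    tot <- tot + (A[i, j] - k[i] * k[j] / (2 * m)) * s[i] * s[j]
  tot / (4 * m)
}

test_that("modularity matches direct summation and its identities", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  s <- c(1, 1, -1, -1)
  expect_equal(modularity(list(A = A, s = s)), 0.5)
  expect_equal(modularity_oracle(A, s), 0.5)
  # all-same signs: the null-model identity forces Q = 0
  expect_equal(modularity(list(A = A, s = rep(1, 4))), 0, tolerance = 1e-12)
  # global sign flip leaves Q unchanged
  expect_equal(modularity(list(A = A, s = -s)),
               modularity(list(A = A, s = s)))
  set.seed(35)
  for (i in 1:10) {
    B <- matrix(runif(36), 6)
    B <- (B + t(B)) / 2
    sg <- sample(c(-1, 1), 6, replace = TRUE)
    expect_equal(modularity(list(A = B, s = sg)), modularity_oracle(B, sg),
                 tolerance = 1e-12)
  }
})

test_that("group-difference t-maps respect their sign conventions", {
  set.seed(36)
  y <- matrix(rnorm(10 * 200), 10, 200)
  o <- matrix(rnorm(10 * 200), 10, 200)
  null_map <- group_difference_tmap(y, o)
  expect_gt(mean(abs(null_map$t) < 2), 0.90)
  shifted <- group_difference_tmap(y + 2, y)
  expect_true(all(shifted$t > 0))
  swap <- group_difference_tmap(o, y)
  expect_equal(swap$t, -group_difference_tmap(y, o)$t)
  expect_error(group_difference_tmap(y[1, , drop = FALSE], o), "two subjects")
})
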