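test_that("generate_cohort returns the configured subjects, deterministically", {
  cfg <- small_config()
  coh <- small_cohort()
  expect_length(coh, cfg$n_young + cfg$n_old)
  expect_equal(sum(vapply(coh, `[[`, "", "group") == "young"), cfg$n_young)
  for (s in coh[c(1, 4)]) {
    expect_s3_class(s$bold, "voxel_ts")
    expect_equal(ncol(s$bold$values), cfg$n_volumes)
    expect_equal(nrow(s$motion), cfg$n_volumes)
    # frequency bookkeeping is consistent between BOLD truth and physio trace
    expect_equal(s$physio$cardiac_freq, s$cardiac_freq)
    expect_gte(s$cardiac_freq, cfg$cardiac_freq_range[1])
    expect_lte(s$cardiac_freq, cfg$cardiac_freq_range[2])
  }
  # seeded determinism, bitwise
  coh2 <- generate_cohort(small_config())
  expect_identical(coh[[2]]$bold$values, coh2[[2]]$bold$values)
  expect_identical(coh[[5]]$motion, coh2[[5]]$motion)
})

test_that("every GM voxel has one ROI and every ROI one network", {
  s <- small_cohort()[[1]]
  gm <- s$bold$tissue == "GM"
  expect_true(all(s$bold$roi[gm] > 0))
  expect_true(all(s$bold$roi[!gm] == 0))
  roi_net <- tapply(s$bold$network[gm], s$bold$roi[gm],
                    function(x) length(unique(x)))
  expect_true(all(roi_net == 1))
})

test_that("invalid configurations fail naming the violated invariant", {
  expect_error(cohort_config(n_volumes = 1), "n_volumes")
  expect_error(cohort_config(
    variance_fractions = c(neural = 0.5, cardiac = 0.3, respiratory = 0.2,
                           global = 0.2, drift = 0.1)), "sum")
  expect_error(cohort_config(within_net_corr_young = 0.2,
                             within_net_corr_old = 0.4), "within_net_corr_old")
  expect_error(cohort_config(tr = 2), "Nyquist")
})

test_that("per-voxel component variances match the stored fractions", {
  cfg <- small_config(n_young = 1, n_old = 0, n_volumes = 1200)
  s <- generate_cohort(cfg)[[1]]
  gt <- s$ground_truth
  C <- cbind(gt$courses$roi, gt$courses$cardiac_basis,
             gt$courses$respiratory_basis, gt$courses$global,
             gt$courses$drift)
  comp_cols <- list(neural = seq_len(cfg$n_rois),
                    cardiac = cfg$n_rois + 1:4,
                    respiratory = cfg$n_rois + 5:8,
                    global = cfg$n_rois + 9, drift = cfg$n_rois + 10)
  biased_var <- function(x) mean((x - mean(x))^2)
  set.seed(1)
  for (v in sample(which(s$bold$tissue != "BG"), 12)) {
    for (nm in names(comp_cols)) {
      part <- C[, comp_cols[[nm]], drop = FALSE] %*%
        gt$mixing[v, comp_cols[[nm]]]
      got <- biased_var(part) / cfg$total_sd^2
      want <- gt$variance_fractions[v, nm]
      if (want > 0.01) expect_lt(abs(got - want) / want, 0.10)
    }
    # stored courses reproduce the voxel up to the white-noise residual
    recon <- as.vector(C %*% gt$mixing[v, ]) + gt$baseline
    resid <- s$bold$values[v, ] - recon
    expect_lt(abs(stats::sd(resid) - gt$noise_sd[v]) / gt$noise_sd[v], 0.15)
  }
})

test_that("GM-mean spectral peak in the cardiac range matches the true frequency", {
  for (s in small_cohort()[c(1, 2, 4)]) {
    spec <- mean_signal_spectrum(s$bold, tissue_mask(s$bold, "GM"), "GM")
    sel <- spec$frequency >= 0.6 & spec$frequency <= 1.5
    peak <- spec$frequency[sel][which.max(spec$power[sel])]
    expect_lt(abs(peak - s$cardiac_freq), spec$df + 1e-12)
  }
})

test_that("young subjects show higher within-network coupling than old", {
  coh <- memo("coupling_cohort",
              generate_cohort(small_config(n_young = 6, n_old = 6, seed = 77)))
  mean_within <- vapply(coh, function(s) {
    cm <- roi_connectivity(highpass(s$bold, 0.01))
    mean(network_mean_correlation(cm))
  }, numeric(1))
  groups <- vapply(coh, `[[`, "", "group")
  tt <- t.test(mean_within[groups == "young"], mean_within[groups == "old"],
               alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("zero cardiac variance leaves no cardiac-band peak above the noise floor", {
  vf0 <- c(neural = 0.20, cardiac = 0, respiratory = 0.06,
           global = 0.10, drift = 0.05)
  vf2 <- c(neural = 0.20, cardiac = 0.2, respiratory = 0.06,
           global = 0.10, drift = 0.05)
  s0 <- generate_cohort(small_config(n_young = 1, n_old = 0,
                                     variance_fractions = vf0))[[1]]
  s2 <- generate_cohort(small_config(n_young = 1, n_old = 0,
                                     variance_fractions = vf2))[[1]]
  band <- frequency_bands(s2$cardiac_freq, s2$resp_freq)$cardiac
  p0 <- band_power(mean_signal_spectrum(s0$bold, tissue_mask(s0$bold, "GM")), band)
  p2 <- band_power(mean_signal_spectrum(s2$bold, tissue_mask(s2$bold, "GM")), band)
  expect_gt(p2, 5 * p0)
})

test_that("physio recordings recover their frequencies and validate inputs", {
  rec <- generate_physio_recording(1.1, 0.25, duration = 600, rate = 50,
                                   seed = 3)
  pc <- physio_peak(rec, "cardiac", c(0.6, 1.5))
  pr <- physio_peak(rec, "respiratory", c(0.15, 0.4))
  expect_lt(abs(pc$frequency - 1.1), 1 / 600 + 1e-12)
  expect_lt(abs(pr$frequency - 0.25), 1 / 600 + 1e-12)
  expect_true(pc$confident && pr$confident)

  expect_error(generate_physio_recording(1.1, 0.25, duration = 0, rate = 50),
               "duration")
  expect_error(generate_physio_recording(1.1, 0.25, duration = 60, rate = 2),
               "rate")
  # same frequencies, different seeds: same peaks, different noise
  rec2 <- generate_physio_recording(1.1, 0.25, duration = 600, rate = 50,
                                    seed = 4)
  expect_equal(physio_peak(rec2, "cardiac", c(0.6, 1.5))$frequency,
               pc$frequency)
  expect_false(identical(rec$cardiac, rec2$cardiac))
})
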