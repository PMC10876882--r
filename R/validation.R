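# Calibration and validation routines: parameter-recovery checks against the
# generator's ground truth, and Monte-Carlo calibration of the group
# statistics.  These consume ground truth; the analysis pipeline itself never
# does.

#' Nyquist frequency of a sampling interval
#' @param tr sampling interval in seconds.
#' @return half the sampling rate, in Hz.
#' @export
nyquist_frequency <- function(tr) 1 / (2 * tr)

# Per-voxel band power via the FFT of every row (boxcar, mean removed).
voxel_band_power <- function(values, tr, band) {
  n <- ncol(values)
  x <- values - rowMeans(values)
  xf <- stats::mvfft(t(x))                  # n x voxels
  dens <- Mod(xf)^2 * tr / n
  half <- floor(n / 2)
  k <- seq_len(half)
  p <- dens[k + 1, , drop = FALSE]
  fold <- n - k
  dup <- fold >= 1 & fold != k
  p[dup, ] <- p[dup, ] + dens[fold[dup] + 1, , drop = FALSE]
  freq <- k / (n * tr)
  sel <- freq >= band[1] & freq <= band[2]
  colSums(p[sel, , drop = FALSE]) / (n * tr)
}

#' Cardiac-removal calibration against ground truth
#'
#' For each subject, regresses the true cardiac quadrature courses out of the
#' raw BOLD data and measures, per grey-matter voxel, how much cardiac-band
#' power was removed relative to the voxel's total variance.  If the
#' generator's bookkeeping is right, the grey-matter mean of that quantity
#' equals the mean injected cardiac variance fraction.
#'
#' @param cohort list of `synthetic_subject`s.
#' @return data frame with one row per subject: `removed_frac`,
#'   `injected_frac`, `relative_error`.
#' @export
cardiac_removal_calibration <- function(cohort) {
  rows <- lapply(cohort, function(s) {
    b <- s$bold
    gm <- tissue_mask(b, "GM")
    band <- frequency_bands(s$cardiac_freq, s$resp_freq)$cardiac
    den <- regress_nuisance(b, oracle_nuisance(s, "cardiac"))
    bp0 <- voxel_band_power(b$values[gm, , drop = FALSE], b$tr, band)
    bp1 <- voxel_band_power(den$values[gm, , drop = FALSE], b$tr, band)
    tot <- rowMeans((b$values[gm, ] - rowMeans(b$values[gm, ]))^2)
    removed <- mean((bp0 - bp1) / tot)
    injected <- mean(s$ground_truth$variance_fractions[gm, "cardiac"])
    data.frame(subject = s$id, removed_frac = removed,
               injected_frac = injected,
               relative_error = abs(removed - injected) / injected)
  })
  do.call(rbind, rows)
}

#' Validation scene with planted ICA components of known character
#'
#' Builds a BOLD series containing five planted components on disjoint voxel
#' sets over a concentric-tissue grid: a pure 1 Hz tone (high-frequency
#' content above threshold), a copy of one motion parameter, a brain-edge rim
#' course, a low-frequency (0.02-0.04 Hz) course confined to one network's
#' grey matter, and a CSF-confined high-frequency course.  Used to validate
#' the component classifier.
#'
#' @param n,tr timepoints and sampling interval.
#' @param seed RNG seed.
#' @return list with `series`, `motion`, `courses`, `masks`, and the
#'   expected classification per planted component.
#' @export
aroma_validation_scene <- function(n = 400, tr = 0.38, seed = 51) {
  set.seed(seed)
  lay <- cohort_layout(c(12L, 12L, 8L), 7L, 42L)
  V <- nrow(lay$coords)
  t_s <- (seq_len(n) - 1) * tr
  in_brain <- lay$tissue != "BG"
  rim <- rim_mask(in_brain, lay$coords, lay$grid_shape)
  gm <- lay$tissue == "GM" & !rim
  csf <- lay$tissue == "CSF"
  motion <- motion_trace(n)
  courses <- list(
    tone_1hz = standardize(sin(2 * pi * 1.0 * t_s)),
    motion_locked = standardize(motion[, 1]),
    edge = standardize(band_limited_noise(n, tr, 0.15, 0.9)),
    network = standardize(band_limited_noise(n, tr, 0.02, 0.04)),
    csf_pulse = standardize(band_limited_noise(n, tr, 0.5, 1.2)))
  masks <- list(
    tone_1hz = sample(which(in_brain & !rim), 60),
    motion_locked = sample(which(in_brain & !csf), 60),
    edge = which(rim),
    network = which(lay$network == 1 & gm),
    csf_pulse = which(csf & !rim))
  amp <- c(tone_1hz = 3, motion_locked = 5, edge = 3, network = 3,
           csf_pulse = 3)
  vals <- matrix(stats::rnorm(V * n, sd = 0.3), V, n)
  for (nm in names(courses))
    vals[masks[[nm]], ] <- vals[masks[[nm]], ] +
      outer(rep(amp[[nm]], length(masks[[nm]])), courses[[nm]])
  series <- voxel_ts(vals, tr = tr, coords = lay$coords, tissue = lay$tissue,
                     roi = lay$roi, network = lay$network,
                     grid_shape = lay$grid_shape)
  list(series = series, motion = motion, courses = courses, masks = masks,
       expected = c(tone_1hz = "noise", motion_locked = "noise",
                    edge = "noise", network = "signal", csf_pulse = "noise"))
}

#' Classify a validation scene and score the planted components
#'
#' @param scene output of [aroma_validation_scene()].
#' @param n_components components for the decomposition.
#' @return data frame per planted component: matched component index, match
#'   correlation, classification, expected label, and whether they agree.
#' @export
aroma_validation_score <- function(scene, n_components = 10) {
  report <- aroma_like_components(scene$series, scene$motion,
                                  n_components = n_components)
  rows <- lapply(names(scene$courses), function(nm) {
    cc <- abs(stats::cor(report$courses, scene$courses[[nm]]))
    i <- which.max(cc)
    data.frame(component = nm, matched = i, match_r = cc[i],
               classification = report$features$classification[i],
               expected = scene$expected[[nm]],
               correct = report$features$classification[i] ==
                 scene$expected[[nm]])
  })
  do.call(rbind, rows)
}

# Null and effect tables for the ANOVA calibration.
sim_power_table <- function(n_young, n_old, methods, subject_sd = 1,
                            noise_sd = 1, method_shift = 0, age_shift = 0) {
  subjects <- sprintf("s%02d", seq_len(n_young + n_old))
  groups <- rep(c("young", "old"), c(n_young, n_old))
  d <- expand.grid(subject = subjects, method = methods,
                   source = c("GM", "WM"), stringsAsFactors = FALSE)
  d$group <- groups[match(d$subject, subjects)]
  d$band <- "band"
  b <- stats::rnorm(length(subjects), 0, subject_sd)
  d$value <- b[match(d$subject, subjects)] +
    stats::rnorm(nrow(d), 0, noise_sd) +
    method_shift * (d$method == methods[1]) +
    age_shift * (d$group == "old")
  d
}

sim_metric_table <- function(n_young, n_old, methods, subject_sd = 1,
                             noise_sd = 1, method_shift = 0, age_shift = 0) {
  d <- sim_power_table(n_young, n_old, methods, subject_sd, noise_sd,
                       method_shift, age_shift)
  d[d$source == "GM", c("subject", "group", "method", "value")]
}

#' Monte-Carlo calibration of the mixed-model ANOVAs
#'
#' Simulates `n_rep` datasets at the study's size (two groups of 18, five
#' denoising methods, two tissues) and returns per-factor type-I error rates
#' under the null (subject random effect plus noise only), plus detection
#' rates for an injected method effect (one method shifted by one noise SD,
#' detected at p < 0.01) and an injected age effect (1.5 subject-SD shift,
#' detected at p < 0.05).
#'
#' @param n_rep simulation replicates.
#' @param n_young,n_old group sizes.
#' @param alpha type-I level examined.
#' @param seed RNG seed.
#' @return list with `type1_power_anova`, `type1_mixed_anova` (named per
#'   factor), `method_effect_detection`, `age_effect_detection`.
#' @export
anova_calibration <- function(n_rep = 200, n_young = 18, n_old = 18,
                              alpha = 0.05, seed = 1) {
  set.seed(seed)
  methods <- c("GSR", "WM-CSF", "aCompCor", "tCompCor", "AROMA")
  p_pow <- p_mix <- NULL
  det_method <- det_age <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    d0 <- sim_power_table(n_young, n_old, methods)
    a0 <- power_anova(d0, "band")
    p_pow <- rbind(p_pow, stats::setNames(a0$p, a0$factor))
    m0 <- sim_metric_table(n_young, n_old, methods)
    b0 <- mixed_anova_metric(m0)
    p_mix <- rbind(p_mix, stats::setNames(b0$p, b0$factor))
    dm <- sim_metric_table(n_young, n_old, methods, method_shift = 1)
    am <- mixed_anova_metric(dm)
    det_method[r] <- am$p[am$factor == "method"] < 0.01
    da <- sim_metric_table(n_young, n_old, methods, age_shift = 1.5)
    aa <- mixed_anova_metric(da)
    det_age[r] <- aa$p[aa$factor == "age"] < 0.05
  }
  list(type1_power_anova = colMeans(p_pow < alpha),
       type1_mixed_anova = colMeans(p_mix < alpha),
       method_effect_detection = mean(det_method),
       age_effect_detection = mean(det_age))
}

#' Cohort-level denoising comparison against ground truth
#'
#' Streams through a cohort once and collects, per subject: grey-matter
#' cardiac-band fractional power change under GSR and WM-CSF, and
#' template-based-rotation maps under no correction and under oracle
#' denoising (true cardiac + respiratory + global courses regressed).
#' Returns per-network modularity (cohort-centered, clipped) and permutation
#' summaries for both conditions.
#'
#' @param cohort list of `synthetic_subject`s.
#' @param highpass_cutoff preprocessing cutoff in Hz.
#' @param n_perm permutations for the modularity null.
#' @param seed seed for the permutation draws.
#' @return list with `power` (per-subject data frame), `modularity` (per
#'   network and condition), `permutation` (z and quantile per condition).
#' @export
denoising_comparison <- function(cohort, highpass_cutoff = 0.01,
                                 n_perm = 1000, seed = 1) {
  groups <- vapply(cohort, `[[`, "", "group")
  tpl <- network_templates(cohort[[1]]$bold)
  gm <- tissue_mask(cohort[[1]]$bold, "GM")
  n_net <- ncol(tpl)
  maps_none <- maps_oracle <- vector("list", length(cohort))
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    b <- highpass(s$bold, highpass_cutoff)
    band <- frequency_bands(s$cardiac_freq, s$resp_freq)$cardiac
    spec0 <- mean_signal_spectrum(b, gm, "GM")
    p0 <- band_power(spec0, band)
    frac <- vapply(c(GSR = "GSR", `WM-CSF` = "WM-CSF"), function(m) {
      den <- denoise_subject(s, m, series = b)$series
      fractional_power_change(p0, band_power(mean_signal_spectrum(den, gm,
                                                                  "GM"),
                                             band))
    }, numeric(1))
    rows[[i]] <- data.frame(subject = s$id, group = s$group,
                            gsr_cardiac = frac[["GSR"]],
                            wmcsf_cardiac = frac[["WM-CSF"]])
    maps_none[[i]] <- tbr_maps(b, tpl)
    den_o <- regress_nuisance(b, oracle_nuisance(s))
    maps_oracle[[i]] <- tbr_maps(den_o, tpl)
  }
  mod_summary <- function(maps) {
    per_net <- lapply(seq_len(n_net), function(k) {
      M <- t(vapply(maps, function(m) m[gm, k], numeric(sum(gm))))
      mi <- cosine_similarity_adjacency(M, groups, center = TRUE)
      set.seed(seed)
      modularity_permutation(mi, n_perm, clip_negative = TRUE)
    })
    list(q = vapply(per_net, `[[`, numeric(1), "q"),
         z = vapply(per_net, `[[`, numeric(1), "z"),
         quantile = vapply(per_net, `[[`, numeric(1), "quantile"))
  }
  list(power = do.call(rbind, rows),
       none = mod_summary(maps_none),
       oracle = mod_summary(maps_oracle))
}
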