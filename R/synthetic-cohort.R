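#' Configuration for a synthetic fast-TR cohort
#'
#' Describes the study conditions emulated by [generate_cohort()]: two age
#' groups scanned with a fast simultaneous-multi-slice-like acquisition
#' (default TR 0.38 s, 1950 volumes), a small concentric-tissue voxel grid,
#' seven functional networks subdivided into ROIs, subject-specific cardiac
#' (~1 Hz) and respiratory (~0.27 Hz) oscillations present both in the BOLD
#' data and in simultaneously "recorded" physiological traces, a global
#' low-frequency nuisance component, slow scanner drift, band-limited
#' (0.01-0.1 Hz) network-structured neural signal with reduced within-network
#' coupling in the old group, and white measurement noise.
#'
#' `variance_fractions` gives the fraction of single-voxel variance carried by
#' each named component in a typical grey-matter voxel; the remainder is white
#' noise.  Cardiac weight is boosted in CSF and in a small set of vessel-like
#' GM voxels, respiratory weight is mildly boosted in CSF, and neural weight
#' is zero outside GM (reallocated to noise), so per-voxel fractions differ by
#' tissue; the realized per-voxel fractions are stored in the ground truth.
#'
#' @param n_young,n_old subjects per group.
#' @param tr repetition time in seconds.
#' @param n_volumes number of BOLD volumes.
#' @param grid_shape length-3 integer voxel grid.
#' @param n_networks,n_rois functional networks and total ROI count.
#' @param cardiac_freq_mean,cardiac_freq_sd cardiac frequency distribution (Hz),
#'   truncated to `cardiac_freq_range`.
#' @param resp_freq_mean,resp_freq_sd respiratory frequency distribution (Hz),
#'   truncated to `resp_freq_range`.
#' @param cardiac_freq_range,resp_freq_range truncation bounds (Hz).
#' @param within_net_corr_young,within_net_corr_old target correlation between
#'   ROI neural courses within a network, per group.
#' @param variance_fractions named fractions of voxel variance for
#'   `neural`, `cardiac`, `respiratory`, `global`, `drift` (GM baseline).
#' @param physio_sampling_rate sampling rate of the physiological traces (Hz).
#' @param seed integer RNG seed; same config + seed gives an identical cohort.
#' @param csf_cardiac_boost,vessel_cardiac_boost multiplicative cardiac-variance
#'   boost in CSF / vessel-like GM voxels.
#' @param csf_resp_boost respiratory boost in CSF.
#' @param vessel_fraction fraction of GM voxels treated as vessel-like.
#' @param old_noise_scale multiplier on white-noise sd in the old group.
#' @param motion_artifact if `TRUE`, inject a motion-locked rim artifact into
#'   the BOLD data (off by default; motion parameters are always generated).
#' @param baseline,total_sd BOLD baseline intensity and total fluctuation sd
#'   (arbitrary units; their ratio sets the tSNR scale).
#' @param cardiac_harmonic relative amplitude of the first cardiac harmonic.
#' @param cardiac_mod_depth,resp_mod_depth slow amplitude-modulation depth.
#' @param cardiac_phase_spread,resp_phase_spread width (radians) of the
#'   uniform per-voxel phase dispersion of the oscillatory components,
#'   emulating spatially varying pulse-wave/respiratory arrival times.
#' @param age_effect_roi_fraction fraction of each network's ROIs whose
#'   within-network coupling drops to `within_net_corr_old` in old subjects
#'   (the remaining ROIs keep the young coupling in both groups).  Aging
#'   effects on connectivity are regionally specific; a spatially uniform
#'   coupling change would leave the *pattern* of each subject's
#'   connectivity map unchanged and hence be invisible to scale-invariant
#'   map-similarity measures.
#' @return a `cohort_config` list, validated.
#' @export
cohort_config <- function(n_young = 18L, n_old = 18L, tr = 0.38,
                          n_volumes = 1950L, grid_shape = c(16L, 16L, 10L),
                          n_networks = 7L, n_rois = 200L,
                          cardiac_freq_mean = 1.0, cardiac_freq_sd = 0.1,
                          resp_freq_mean = 0.27, resp_freq_sd = 0.04,
                          cardiac_freq_range = c(0.6, 1.5),
                          resp_freq_range = c(0.15, 0.4),
                          within_net_corr_young = 0.5,
                          within_net_corr_old = 0.3,
                          variance_fractions = c(neural = 0.20, cardiac = 0.10,
                                                 respiratory = 0.06,
                                                 global = 0.10, drift = 0.05),
                          physio_sampling_rate = 50,
                          seed = 1L,
                          csf_cardiac_boost = 3, vessel_cardiac_boost = 3,
                          csf_resp_boost = 1.5, vessel_fraction = 0.05,
                          old_noise_scale = 1,
                          motion_artifact = FALSE,
                          baseline = 100, total_sd = 2,
                          cardiac_harmonic = 0.3,
                          cardiac_mod_depth = 0.1, resp_mod_depth = 0.25,
                          cardiac_phase_spread = pi, resp_phase_spread = pi,
                          age_effect_roi_fraction = 0.4) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_volumes < 2L) stop_config("invalid config: n_volumes must be >= 2")
  if (cfg$tr <= 0) stop_config("invalid config: tr must be > 0")
  vf <- cfg$variance_fractions
  need <- c("neural", "cardiac", "respiratory", "global", "drift")
  if (!all(need %in% names(vf)))
    stop_config("invalid config: variance_fractions must name %s",
                paste(need, collapse = ", "))
  if (any(vf < 0) || any(vf > 1))
    stop_config("invalid config: each variance fraction must lie in [0, 1]")
  if (sum(vf) > 1)
    stop_config("invalid config: variance fractions sum to %.3f > 1", sum(vf))
  if (cfg$within_net_corr_old > cfg$within_net_corr_young)
    stop_config("invalid config: within_net_corr_old must be <= within_net_corr_young")
  for (p in c("within_net_corr_young", "within_net_corr_old"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop_config("invalid config: %s must lie in [0, 1]", p)
  nyq <- 1 / (2 * cfg$tr)
  if (vf[["cardiac"]] > 0 && cfg$cardiac_freq_mean >= nyq)
    stop_config(paste0("invalid config: cardiac_freq_mean (%.3g Hz) must lie ",
                       "below the BOLD Nyquist %.3g Hz"),
                cfg$cardiac_freq_mean, nyq)
  if (cfg$physio_sampling_rate <= 2 * cfg$cardiac_freq_range[2])
    stop_config("invalid config: physio_sampling_rate must exceed twice the cardiac range")
  if (cfg$n_rois < cfg$n_networks)
    stop_config("invalid config: n_rois must be >= n_networks")
  invisible(cfg)
}

# Concentric spatial layout on an ellipsoidal "brain": CSF at the core
# (ventricle-like) and at the outer edge (subarachnoid-like), a WM shell, and
# a GM ribbon in between; everything at normalized radius > 1 is background.
# GM voxels are split into n_rois ROIs of near-equal size, ROIs grouped into
# n_networks contiguous blocks.
cohort_layout <- function(grid_shape, n_networks, n_rois,
                          age_fraction = 0.4) {
  g <- as.integer(grid_shape)
  coords <- as.matrix(expand.grid(x = seq_len(g[1]), y = seq_len(g[2]),
                                  z = seq_len(g[3])))
  ctr <- (g + 1) / 2
  rad <- (g - 1) / 2
  r <- sqrt(((coords[, 1] - ctr[1]) / rad[1])^2 +
            ((coords[, 2] - ctr[2]) / rad[2])^2 +
            ((coords[, 3] - ctr[3]) / rad[3])^2)
  tissue <- rep("BG", nrow(coords))
  tissue[r <= 1]    <- "CSF"   # outer subarachnoid layer
  tissue[r <= 0.90] <- "GM"
  tissue[r <= 0.65] <- "WM"
  tissue[r <= 0.35] <- "CSF"   # ventricle core
  gm <- which(tissue == "GM")
  if (length(gm) < n_rois)
    stop_config("grid too small: %d GM voxels for %d ROIs", length(gm), n_rois)
  # order GM voxels by angular position so ROIs are spatially contiguous-ish
  ang <- atan2(coords[gm, 2] - ctr[2], coords[gm, 1] - ctr[1]) +
    0.2 * (coords[gm, 3] - ctr[3])
  ord <- gm[order(ang)]
  roi <- integer(nrow(coords))
  roi[ord] <- as.integer(cut(seq_along(ord), breaks = n_rois, labels = FALSE))
  roi_network <- as.integer(cut(seq_len(n_rois), breaks = n_networks,
                                labels = FALSE))
  network <- integer(nrow(coords))
  network[roi > 0] <- roi_network[roi[roi > 0]]
  # deterministic regionally-specific aging target: the leading ROIs of each
  # network lose coupling in the old group
  age_sensitive <- logical(n_rois)
  for (k in seq_len(n_networks)) {
    idx <- which(roi_network == k)
    age_sensitive[idx[seq_len(ceiling(age_fraction * length(idx)))]] <- TRUE
  }
  list(coords = coords, tissue = tissue, roi = roi, network = network,
       roi_network = roi_network, age_sensitive = age_sensitive,
       grid_shape = g, radius = r)
}

# One amplitude-modulated oscillator (fundamental + one harmonic) at unit sd.
oscillator_course <- function(time, freq, phase, harmonic, mod_depth) {
  n <- length(time)
  dt <- time[2] - time[1]
  mod <- 1 + mod_depth * band_limited_noise(n, dt, 1 / (n * dt), 0.05)
  x <- mod * (sin(2 * pi * freq * time + phase) +
              harmonic * sin(4 * pi * freq * time + 2 * phase))
  standardize(x)
}

# Quadrature basis of an amplitude-modulated oscillator: columns
# a(t)*sin(wt), a(t)*cos(wt), a(t)*sin(2wt), a(t)*cos(2wt).  A voxel whose
# oscillation is phase-shifted by phi mixes these columns with coefficients
# (cos phi, sin phi, h*cos 2phi, h*sin 2phi), emulating the spatially varying
# arrival time of pulsatile and respiratory effects.
oscillator_basis <- function(time, freq, phase0, mod_depth) {
  n <- length(time)
  dt <- time[2] - time[1]
  mod <- 1 + mod_depth * band_limited_noise(n, dt, 1 / (n * dt), 0.05)
  w <- 2 * pi * freq * time + phase0
  B <- cbind(mod * sin(w), mod * cos(w), mod * sin(2 * w), mod * cos(2 * w))
  B <- sweep(B, 2, colMeans(B))
  B
}

# Per-voxel quadrature mixing coefficients for phases phi, harmonic ratio h,
# scaled so every voxel's oscillation has exactly unit empirical variance.
oscillator_coefs <- function(phi, h, basis) {
  coef <- cbind(cos(phi), sin(phi), h * cos(2 * phi), h * sin(2 * phi))
  S <- stats::cov(basis) * (nrow(basis) - 1) / nrow(basis)
  norm <- sqrt(rowSums((coef %*% S) * coef))
  coef / norm
}

# Slow scanner drift: linear trend plus the two slowest cosines, random mix.
drift_course <- function(n) {
  t01 <- seq(0, 1, length.out = n)
  b <- stats::rnorm(3)
  standardize(b[1] * t01 + b[2] * cospi(t01) + b[3] * cospi(2 * t01))
}

simulate_subject <- function(cfg, layout, group, id, f_card, f_resp) {
  n <- cfg$n_volumes
  time <- (seq_len(n) - 1) * cfg$tr
  V <- nrow(layout$coords)
  # per-ROI within-network coupling: old subjects lose coupling only in the
  # age-sensitive ROI subset
  rho_roi <- rep(cfg$within_net_corr_young, cfg$n_rois)
  if (group == "old")
    rho_roi[layout$age_sensitive] <- cfg$within_net_corr_old
  rho <- mean(rho_roi)

  ## --- component time courses (all unit sd) ------------------------------
  net_courses <- vapply(seq_len(cfg$n_networks), function(k)
    band_limited_noise(n, cfg$tr, 0.01, 0.1), numeric(n))      # n x K
  roi_courses <- vapply(seq_len(cfg$n_rois), function(r) {
    innov <- band_limited_noise(n, cfg$tr, 0.01, 0.1)
    standardize(sqrt(rho_roi[r]) * net_courses[, layout$roi_network[r]] +
                sqrt(1 - rho_roi[r]) * innov)
  }, numeric(n))                                               # n x n_rois
  card_basis <- oscillator_basis(time, f_card, stats::runif(1, 0, 2 * pi),
                                 cfg$cardiac_mod_depth)
  resp_basis <- oscillator_basis(time, f_resp, stats::runif(1, 0, 2 * pi),
                                 cfg$resp_mod_depth)
  global <- band_limited_noise(n, cfg$tr, 1 / (n * cfg$tr), 0.1)
  drift <- drift_course(n)

  ## --- per-voxel variance fractions --------------------------------------
  vf <- cfg$variance_fractions
  tissue <- layout$tissue
  in_brain <- tissue != "BG"
  frac <- matrix(0, V, 6,
                 dimnames = list(NULL, c("neural", "cardiac", "respiratory",
                                         "global", "drift", "noise")))
  frac[in_brain, "cardiac"]     <- vf[["cardiac"]]
  frac[in_brain, "respiratory"] <- vf[["respiratory"]]
  frac[in_brain, "global"]      <- vf[["global"]]
  frac[in_brain, "drift"]       <- vf[["drift"]]
  frac[tissue == "GM", "neural"] <- vf[["neural"]]
  frac[tissue == "CSF", "cardiac"] <- vf[["cardiac"]] * cfg$csf_cardiac_boost
  frac[tissue == "CSF", "respiratory"] <- vf[["respiratory"]] * cfg$csf_resp_boost
  gm_idx <- which(tissue == "GM")
  n_vessel <- round(cfg$vessel_fraction * length(gm_idx))
  vessel <- if (n_vessel > 0) sample(gm_idx, n_vessel) else integer(0)
  frac[vessel, "cardiac"] <- vf[["cardiac"]] * cfg$vessel_cardiac_boost
  ssum <- rowSums(frac[, 1:5, drop = FALSE])
  over <- ssum > 0.95
  if (any(over))    # keep headroom for white noise where boosts pile up
    frac[over, 1:5] <- frac[over, 1:5] * (0.95 / ssum[over])
  frac[in_brain, "noise"] <- 1 - rowSums(frac[in_brain, 1:5, drop = FALSE])
  frac[!in_brain, "noise"] <- 1

  ## --- mix into BOLD ------------------------------------------------------
  noise_scale <- if (group == "old") cfg$old_noise_scale else 1
  # course matrix: one neural course per ROI, quadrature cardiac and
  # respiratory bases (4 columns each), then global and drift
  C <- t(cbind(roi_courses, card_basis, resp_basis, global, drift))
  W <- matrix(0, V, nrow(C))
  has_roi <- layout$roi > 0
  W[cbind(which(has_roi), layout$roi[has_roi])] <-
    sqrt(frac[has_roi, "neural"]) * cfg$total_sd
  # spatially dispersed oscillation phase: pulse-wave/respiratory arrival
  # differs across voxels, so each voxel mixes the quadrature columns
  phi_c <- stats::runif(V, -cfg$cardiac_phase_spread / 2,
                        cfg$cardiac_phase_spread / 2)
  phi_r <- stats::runif(V, -cfg$resp_phase_spread / 2,
                        cfg$resp_phase_spread / 2)
  cc <- cfg$n_rois
  W[, cc + 1:4] <- oscillator_coefs(phi_c, cfg$cardiac_harmonic, card_basis) *
    sqrt(frac[, "cardiac"]) * cfg$total_sd
  W[, cc + 5:8] <- oscillator_coefs(phi_r, 0.2, resp_basis) *
    sqrt(frac[, "respiratory"]) * cfg$total_sd
  W[, cc + 9] <- sqrt(frac[, "global"]) * cfg$total_sd
  W[, cc + 10] <- sample(c(-1, 1), V, replace = TRUE) *
    sqrt(frac[, "drift"]) * cfg$total_sd
  noise_sd <- sqrt(frac[, "noise"]) * cfg$total_sd * noise_scale
  values <- W %*% C +
    matrix(stats::rnorm(V * n), V, n) * noise_sd + cfg$baseline

  ## --- motion and optional motion-locked artifact -------------------------
  motion <- motion_trace(n)
  if (isTRUE(cfg$motion_artifact)) {
    rim <- rim_mask(in_brain, layout$coords, layout$grid_shape)
    mcourse <- standardize(motion[, 1])
    values[rim, ] <- values[rim, ] +
      outer(rep(0.5 * cfg$total_sd, sum(rim)), mcourse)
  }

  physio_seed <- sample.int(.Machine$integer.max, 1)
  physio <- generate_physio_recording(f_card, f_resp,
                                      duration = n * cfg$tr,
                                      rate = cfg$physio_sampling_rate,
                                      seed = physio_seed)

  bold <- voxel_ts(values, tr = cfg$tr, coords = layout$coords,
                   tissue = tissue, roi = layout$roi, network = layout$network,
                   grid_shape = layout$grid_shape)
  gt <- list(
    courses = list(network = net_courses, roi = roi_courses,
                   cardiac = standardize(card_basis[, 1] +
                                         cfg$cardiac_harmonic * card_basis[, 3]),
                   cardiac_basis = card_basis,
                   respiratory = standardize(resp_basis[, 1] +
                                             0.2 * resp_basis[, 3]),
                   respiratory_basis = resp_basis,
                   global = global, drift = drift),
    mixing = W,
    course_names = c(paste0("roi_", seq_len(cfg$n_rois)),
                     paste0("cardiac_q", 1:4), paste0("respiratory_q", 1:4),
                     "global", "drift"),
    noise_sd = noise_sd, baseline = cfg$baseline,
    cardiac_freq = f_card, resp_freq = f_resp,
    variance_fractions = frac, vessel_voxels = vessel,
    within_net_corr = rho)
  structure(list(id = id, group = group, bold = bold, physio = physio,
                 motion = motion, ground_truth = gt,
                 cardiac_freq = f_card, resp_freq = f_resp,
                 physio_seed = physio_seed),
            class = "synthetic_subject")
}

# Head-motion parameters: slow random walk plus occasional spikes.
# Columns: trans_x/y/z (mm), rot_x/y/z (rad).
motion_trace <- function(n) {
  step_sd <- c(rep(0.01, 3), rep(2e-4, 3))
  m <- vapply(step_sd, function(s) cumsum(stats::rnorm(n, 0, s)), numeric(n))
  spikes <- which(stats::runif(n) < 0.005)
  for (t in spikes) {
    j <- sample.int(6, 1)
    amp <- if (j <= 3) 0.2 else 0.004
    m[t:n, j] <- m[t:n, j] + sample(c(-1, 1), 1) * amp
  }
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Generate a synthetic two-group fast-TR cohort
#'
#' Draws per-subject cardiac and respiratory frequencies once (from truncated
#' normals) and uses them consistently in both the BOLD data and the
#' physiological recording, builds each subject's BOLD series from unit-sd
#' component courses mixed with per-voxel weights (stored in the ground
#' truth), and attaches motion parameters and a physiological trace.
#'
#' @param config a [cohort_config()].
#' @return a list of `synthetic_subject` objects (young first, then old);
#'   deterministic given `config$seed`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  layout <- cohort_layout(config$grid_shape, config$n_networks, config$n_rois,
                          config$age_effect_roi_fraction)
  groups <- c(rep("young", config$n_young), rep("old", config$n_old))
  lapply(seq_along(groups), function(i) {
    f_card <- rtruncnorm1(1, config$cardiac_freq_mean, config$cardiac_freq_sd,
                          config$cardiac_freq_range[1], config$cardiac_freq_range[2])
    f_resp <- rtruncnorm1(1, config$resp_freq_mean, config$resp_freq_sd,
                          config$resp_freq_range[1], config$resp_freq_range[2])
    simulate_subject(config, layout, groups[i],
                     id = sprintf("sub-%02d", i), f_card = f_card,
                     f_resp = f_resp)
  })
}

#' Generate a high-rate physiological recording
#'
#' Cardiac and respiratory traces sampled at `rate` Hz: amplitude-modulated
#' sinusoids (fundamental plus one harmonic) with additive measurement noise.
#' The spectral peak of each trace falls within one frequency bin
#' (`1/duration` Hz) of the requested frequency.
#'
#' @param cardiac_freq,resp_freq oscillation frequencies in Hz.
#' @param duration recording length in seconds.
#' @param rate sampling rate in Hz; must exceed `2 * cardiac_freq`.
#' @param seed integer seed for the noise realization.
#' @return a `physio_recording`: list with `time`, `cardiac`, `respiratory`,
#'   `rate`, `cardiac_freq`, `resp_freq`.
#' @export
generate_physio_recording <- function(cardiac_freq, resp_freq, duration, rate,
                                      seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  if (rate <= 2 * cardiac_freq)
    stop(sprintf("sampling rate %.3g Hz too low for a %.3g Hz cardiac trace",
                 rate, cardiac_freq))
  set.seed(seed)
  n <- floor(duration * rate)
  if (n < 8) stop("duration too short for the requested rate")
  time <- (seq_len(n) - 1) / rate
  cardiac <- oscillator_course(time, cardiac_freq, stats::runif(1, 0, 2 * pi),
                               0.3, 0.1) + stats::rnorm(n, 0, 0.1)
  respir <- oscillator_course(time, resp_freq, stats::runif(1, 0, 2 * pi),
                              0.2, 0.25) + stats::rnorm(n, 0, 0.1)
  structure(list(time = time, cardiac = cardiac, respiratory = respir,
                 rate = rate, cardiac_freq = cardiac_freq,
                 resp_freq = resp_freq),
            class = "physio_recording")
}

#' Ground-truth (oracle) nuisance set for a synthetic subject
#'
#' Builds a nuisance set from the true generating courses — the full
#' quadrature bases for the oscillatory components, so regression removes
#' each voxel's phase-shifted oscillation exactly.  Used for calibration and
#' validation, never by the data-driven methods.
#'
#' @param subject a `synthetic_subject`.
#' @param components which true components to remove.
#' @return a `nuisance_set` (method tag `"none"` is not used; tagged as
#'   aggressive `"tCompCor"`-style custom set via metadata `oracle = TRUE`).
#' @export
oracle_nuisance <- function(subject,
                            components = c("cardiac", "respiratory",
                                           "global")) {
  gt <- subject$ground_truth$courses
  cols <- list()
  if ("cardiac" %in% components) cols$cardiac <- gt$cardiac_basis
  if ("respiratory" %in% components) cols$respiratory <- gt$respiratory_basis
  if ("global" %in% components) cols$global <- gt$global
  if ("drift" %in% components) cols$drift <- gt$drift
  reg <- do.call(cbind, cols)
  ns <- nuisance_set("tCompCor", reg)
  ns$metadata$oracle <- TRUE
  ns$metadata$components <- components
  ns
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s (%s): cardiac %.3f Hz, respiratory %.3f Hz\n",
              x$id, x$group, x$cardiac_freq, x$resp_freq))
  print(x$bold)
  invisible(x)
}
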