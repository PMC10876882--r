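#' Downsample a BOLD series by decimation
#'
#' Keeps every `factor`-th volume starting at `phase` (default 0) with no
#' anti-alias filtering: aliasing of above-Nyquist physiological signals into
#' the low-frequency band is the phenomenon under study.  The sampling
#' interval becomes `factor * tr` (e.g. 0.38 s x 5 = 1.9 s, a conventional
#' acquisition rate).
#'
#' @param series a [voxel_ts].
#' @param factor integer decimation factor, `1 <= factor < timepoints`.
#' @param phase first retained volume, 0-based.
#' @return decimated [voxel_ts].
#' @export
downsample <- function(series, factor, phase = 0L) {
  factor <- as.integer(factor)
  n <- n_timepoints(series)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor >= n) stop("factor must be smaller than the number of timepoints")
  if (factor == 1L && phase == 0L) return(series)
  idx <- seq(1L + phase, n, by = factor)
  out <- series
  out$values <- series$values[, idx, drop = FALSE]
  out$tr <- series$tr * factor
  out
}

#' Apply one denoising method to one subject
#'
#' Dispatches to the regressor constructors and [regress_nuisance()].
#'
#' @param subject a `synthetic_subject` (or list with `bold` and `motion`).
#' @param method one of `"none"`, `"GSR"`, `"WM-CSF"`, `"aCompCor"`,
#'   `"tCompCor"`, `"AROMA"`.
#' @param series optional [voxel_ts] overriding `subject$bold` (e.g. a
#'   preprocessed or downsampled version).
#' @param ... passed to the method's regressor constructor.
#' @return list with `series` (denoised [voxel_ts]) and `nuisance`.
#' @export
denoise_subject <- function(subject, method, series = subject$bold, ...) {
  nui <- switch(method,
    "none" = no_correction(series),
    "GSR" = gsr_regressor(series, ...),
    "WM-CSF" = wmcsf_regressors(series, ...),
    "aCompCor" = acompcor_regressors(series, ...),
    "tCompCor" = tcompcor_regressors(series, ...),
    "AROMA" = {
      motion <- subject$motion
      if (series$tr != subject$bold$tr) {
        fac <- round(series$tr / subject$bold$tr)
        motion <- motion[seq(1, nrow(motion), by = fac), , drop = FALSE]
        motion <- motion[seq_len(ncol(series$values)), , drop = FALSE]
      }
      aroma_nuisance(aroma_like_components(series, motion, ...))
    },
    stop("unknown method: ", method))
  list(series = regress_nuisance(series, nui), nuisance = nui)
}

#' Experiment configuration
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort.
#' @param methods denoising conditions to run.
#' @param downsample_factor decimation factor for the slow-sampling arm
#'   (default 5; 1 disables the arm).
#' @param highpass_cutoff common preprocessing high-pass cutoff in Hz.
#' @param sources band-power sources.
#' @param out_dir optional output directory for TSV tables and the manifest.
#' @param seed seed for the experiment (defaults to the cohort seed).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              methods = c("none", "GSR", "WM-CSF",
                                          "aCompCor", "tCompCor", "AROMA"),
                              downsample_factor = 5L,
                              highpass_cutoff = 0.01,
                              sources = c("GM", "WM"),
                              out_dir = NULL,
                              seed = cohort$seed) {
  allowed <- c("none", "GSR", "WM-CSF", "aCompCor", "tCompCor", "AROMA")
  if (!all(methods %in% allowed))
    stop_config("invalid config: unknown method(s) %s",
                paste(setdiff(methods, allowed), collapse = ", "))
  if (downsample_factor < 1) stop_config("invalid config: downsample_factor must be >= 1")
  structure(list(cohort = cohort, methods = methods,
                 downsample_factor = as.integer(downsample_factor),
                 highpass_cutoff = highpass_cutoff, sources = sources,
                 out_dir = out_dir, seed = seed),
            class = "experiment_config")
}

# Connectivity metrics for one rate arm: per subject x method network-mean
# correlation, FCC, and per-network modularity over subjects.
connectivity_metrics <- function(cohort, denoised, templates, gm_mask) {
  metric_rows <- list()
  tmaps <- list()   # method -> subject x (voxels x networks)
  for (method in names(denoised)) {
    maps_by_subject <- vector("list", length(cohort))
    for (si in seq_along(cohort)) {
      den <- denoised[[method]][[si]]
      cm <- roi_connectivity(den)
      nmc <- network_mean_correlation(cm)
      fz <- fcc(cm)
      metric_rows[[length(metric_rows) + 1L]] <- data.frame(
        subject = cohort[[si]]$id, group = cohort[[si]]$group,
        method = method,
        metric = c("network_mean_correlation", "fcc"),
        value = c(mean(nmc, na.rm = TRUE), fz$fcc))
      maps_by_subject[[si]] <- tbr_maps(den, templates)
    }
    tmaps[[method]] <- maps_by_subject
  }
  groups <- vapply(cohort, `[[`, "", "group")
  n_networks <- ncol(templates)
  mod_rows <- list()
  for (method in names(tmaps)) {
    qs <- vapply(seq_len(n_networks), function(k) {
      M <- t(vapply(tmaps[[method]], function(m) m[gm_mask, k],
                    numeric(sum(gm_mask))))
      # cohort-centered similarity with clipped negatives: see the methods
      # vignette for why the raw cosine is insensitive to group structure
      tryCatch(
        modularity(cosine_similarity_adjacency(M, groups, center = TRUE),
                   clip_negative = TRUE),
        error = function(e) NA_real_)   # degenerate similarity graph
    }, numeric(1))
    mod_rows[[length(mod_rows) + 1L]] <- data.frame(
      method = method, network = seq_len(n_networks), q = qs)
  }
  list(metrics = do.call(rbind, metric_rows),
       modularity = do.call(rbind, mod_rows),
       tmaps = tmaps)
}

#' Run the full benchmarking experiment
#'
#' Generates (or accepts) a synthetic cohort, applies the common
#' preprocessing (discrete-cosine high-pass), runs every requested denoising
#' condition, and computes band-power tables, connectivity metric tables
#' (network-mean correlation, FCC, age-partition modularity per network),
#' group-difference t-map summaries, and ANOVA/follow-up tables, at the
#' native rate and (for connectivity) at the decimated rate.  Identical
#' config + seed give identical tables; ground truth is never consulted.
#'
#' @param config an [experiment_config()].
#' @param cohort optional pre-generated cohort (else generated from
#'   `config$cohort`).
#' @return a `report_bundle` list: `band_power`, `metrics`, `modularity`,
#'   `anova`, `followup`, `difference_maps`, `downsampled` (same tables at
#'   the slow rate), `manifest`, `failures`.
#' @export
run_experiment <- function(config, cohort = NULL) {
  set.seed(config$seed)
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  failures <- list()
  note_failure <- function(stage, e)
    failures[[length(failures) + 1L]] <<- list(stage = stage,
                                               message = conditionMessage(e))

  pre <- lapply(cohort, function(s) highpass(s$bold, config$highpass_cutoff))
  base_sub <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]; s$bold <- pre[[i]]; s
  })

  run_arm <- function(subjects, rate_label, spectra = TRUE) {
    denoised <- list()
    for (method in config$methods) {
      denoised[[method]] <- lapply(seq_along(subjects), function(i)
        tryCatch(denoise_subject(subjects[[i]], method)$series,
                 error = function(e) {
                   note_failure(sprintf("%s/%s/%s", rate_label, method,
                                        subjects[[i]]$id), e)
                   NULL
                 }))
    }
    bp <- NULL
    if (spectra)
      bp <- tryCatch(band_power_table(subjects, denoised,
                                      sources = config$sources),
                     error = function(e) { note_failure("band_power", e); NULL })
    templates <- network_templates(subjects[[1]]$bold)
    gm <- tissue_mask(subjects[[1]]$bold, "GM")
    ok_methods <- Filter(function(m) !any(vapply(denoised[[m]], is.null,
                                                 logical(1))),
                         names(denoised))
    conn <- tryCatch(
      connectivity_metrics(subjects, denoised[ok_methods], templates, gm),
      error = function(e) { note_failure("connectivity", e); NULL })
    diff_maps <- NULL
    if (!is.null(conn)) {
      groups <- vapply(subjects, `[[`, "", "group")
      diff_maps <- lapply(conn$tmaps, function(maps) {
        res <- lapply(seq_len(ncol(templates)), function(k) {
          M <- t(vapply(maps, function(m) m[gm, k], numeric(sum(gm))))
          group_difference_tmap(M[groups == "young", , drop = FALSE],
                                M[groups == "old", , drop = FALSE])
        })
        data.frame(network = seq_len(ncol(templates)),
                   median_t = vapply(res, `[[`, numeric(1), "median_t"))
      })
    }
    list(band_power = bp,
         metrics = if (!is.null(conn)) conn$metrics,
         modularity = if (!is.null(conn)) conn$modularity,
         difference_maps = diff_maps)
  }

  native <- run_arm(base_sub, "native", spectra = TRUE)

  stats_tabs <- list()
  if (!is.null(native$band_power) && length(setdiff(config$methods, "none"))) {
    pc <- power_change_table(native$band_power, sources = config$sources)
    for (bn in unique(pc$band)) {
      stats_tabs[[paste0("power_", bn)]] <- tryCatch(
        power_anova(pc, bn), error = function(e) {
          note_failure(paste0("anova/", bn), e); NULL })
    }
  }
  followup <- list()
  if (!is.null(native$metrics)) {
    for (met in unique(native$metrics$metric)) {
      d <- native$metrics[native$metrics$metric == met, ]
      stats_tabs[[paste0("metric_", met)]] <- tryCatch(
        mixed_anova_metric(d), error = function(e) {
          note_failure(paste0("anova/", met), e); NULL })
      followup[[met]] <- tryCatch(
        followup_tests(d, "method"), error = function(e) {
          note_failure(paste0("followup/", met), e); NULL })
    }
  }

  downs <- NULL
  if (config$downsample_factor > 1L) {
    slow_sub <- lapply(base_sub, function(s) {
      s$bold <- downsample(s$bold, config$downsample_factor); s
    })
    downs <- run_arm(slow_sub, "downsampled", spectra = FALSE)
  }

  manifest <- list(
    seed = config$seed, methods = config$methods,
    downsample_factor = config$downsample_factor,
    highpass_cutoff = config$highpass_cutoff,
    n_subjects = length(cohort),
    tr = cohort[[1]]$bold$tr,
    n_volumes = ncol(cohort[[1]]$bold$values),
    package_version = as.character(utils::packageVersion("denoisebench")),
    failures = failures)

  bundle <- list(band_power = native$band_power, metrics = native$metrics,
                 modularity = native$modularity,
                 difference_maps = native$difference_maps,
                 anova = stats_tabs, followup = followup,
                 downsampled = downs, manifest = manifest,
                 failures = failures)
  class(bundle) <- "report_bundle"
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

# TSV + JSON export of a report bundle.
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, name) if (!is.null(d))
    utils::write.table(d, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(bundle$band_power, "band_power.tsv")
  wt(bundle$metrics, "connectivity_metrics.tsv")
  wt(bundle$modularity, "modularity.tsv")
  for (nm in names(bundle$anova))
    wt(bundle$anova[[nm]], sprintf("anova_%s.tsv", nm))
  for (nm in names(bundle$followup))
    wt(bundle$followup[[nm]], sprintf("followup_%s.tsv", nm))
  if (!is.null(bundle$downsampled)) {
    wt(bundle$downsampled$metrics, "connectivity_metrics_downsampled.tsv")
    wt(bundle$downsampled$modularity, "modularity_downsampled.tsv")
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
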