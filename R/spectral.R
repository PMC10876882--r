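#' One-sided periodogram of a single time course
#'
#' Mean-removed, optionally Hann-tapered periodogram on the grid
#' `k/(n*tr)`, `k = 1..floor(n/2)`.  Power is normalized by the taper energy
#' so that `sum(power) * df` equals the taper-weighted variance of the series
#' exactly (the ordinary biased variance when `taper = "none"`); this keeps
#' the Parseval identity testable while retaining the leakage suppression of
#' the taper.
#'
#' @param x numeric time course.
#' @param tr sampling interval in seconds.
#' @param taper `"hann"` (default) or `"none"`.
#' @return list with `frequency` (Hz), `power` (density per Hz), `df` (bin
#'   width).
#' @export
periodogram <- function(x, tr, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  n <- length(x)
  x <- x - mean(x)
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
       else rep(1, n)
  xw <- x * w
  xw <- xw - mean(xw)        # tapering re-introduces a DC offset; remove it
  xf <- stats::fft(xw)
  # two-sided density normalized by taper energy; fold onto one side
  dens <- Mod(xf)^2 * tr / sum(w^2)
  half <- floor(n / 2)
  k <- seq_len(half)
  p <- dens[k + 1]
  fold <- n - k
  dup <- fold >= 1 & fold != k            # conjugate bins (skip Nyquist self-pair)
  p[dup] <- p[dup] + dens[fold[dup] + 1]
  list(frequency = k / (n * tr), power = p, df = 1 / (n * tr))
}

#' Mask-mean signal spectrum
#'
#' Averages the time series over the mask voxels first, then computes the
#' periodogram of that mean signal.
#'
#' @param series a [voxel_ts].
#' @param mask logical per-voxel mask.
#' @param label source label stored in the record (e.g. `"GM"`).
#' @param taper passed to [periodogram()].
#' @return a `power_spectrum` record: frequency, power, df, label.
#' @export
mean_signal_spectrum <- function(series, mask, label = "mask",
                                 taper = c("hann", "none")) {
  taper <- match.arg(taper)
  if (!any(mask)) stop("empty mask")
  m <- colMeans(series$values[mask, , drop = FALSE])
  spec <- periodogram(m, series$tr, taper = taper)
  structure(c(spec, list(label = label, tr = series$tr)),
            class = "power_spectrum")
}

#' Peak frequency of a physiological trace
#'
#' Frequency of maximum periodogram power within the search band; resolution
#' is one bin (`1/duration` Hz).  If no bin in the band reaches three times
#' the in-band median power the estimate is flagged as low-confidence.
#'
#' @param recording a `physio_recording` (or any list with `time` and a trace).
#' @param channel `"cardiac"` or `"respiratory"`.
#' @param search_band length-2 numeric Hz range.
#' @return list with `frequency` (Hz), `confident` (logical), `resolution`.
#' @export
physio_peak <- function(recording, channel = c("cardiac", "respiratory"),
                        search_band = NULL) {
  channel <- match.arg(channel)
  duration <- max(recording$time) - min(recording$time)
  if (duration < 60)
    stop("recording shorter than 60 s; peak estimate unreliable")
  if (is.null(search_band))
    search_band <- if (channel == "cardiac") c(0.6, 1.5) else c(0.15, 0.4)
  x <- recording[[channel]]
  dt <- recording$time[2] - recording$time[1]
  spec <- periodogram(x, dt)
  sel <- spec$frequency >= search_band[1] & spec$frequency <= search_band[2]
  if (!any(sel)) stop("search band outside the spectral range")
  p <- spec$power[sel]
  f <- spec$frequency[sel]
  peak <- which.max(p)
  # confidence compares a *smoothed* spectrum's peak against its median:
  # the raw maximum of many exponential-like periodogram bins exceeds any
  # fixed multiple of the median even for white noise
  w <- max(5L, 2L * (length(p) %/% 40L) + 1L)
  ps <- stats::filter(p, rep(1 / w, w), sides = 2)
  ps <- ps[!is.na(ps)]
  list(frequency = f[peak],
       confident = max(ps) >= 3 * stats::median(ps),
       resolution = spec$df)
}

#' Subject-specific frequency bands
#'
#' Cardiac band: 0.1 Hz wide, centred at the subject's heartbeat frequency;
#' respiratory band: 0.2 Hz wide around the respiration frequency;
#' low-frequency band: 0.01-0.1 Hz.
#'
#' @param cardiac_freq,resp_freq subject frequencies in Hz.
#' @param cardiac_width,resp_width band widths in Hz.
#' @param low_band low-frequency band edges in Hz.
#' @return named list of length-2 band edges.
#' @export
frequency_bands <- function(cardiac_freq, resp_freq, cardiac_width = 0.1,
                            resp_width = 0.2, low_band = c(0.01, 0.1)) {
  list(cardiac = cardiac_freq + c(-1, 1) * cardiac_width / 2,
       respiratory = resp_freq + c(-1, 1) * resp_width / 2,
       low = low_band)
}

#' Integrated band power of a spectrum
#'
#' Sum of power density times bin width over bins whose centres fall inside
#' the band.  Bands extending beyond the Nyquist frequency are clipped with a
#' warning; a band lying entirely above Nyquist is an error.
#'
#' @param spectrum a `power_spectrum` (or list with `frequency`, `power`, `df`).
#' @param band length-2 numeric band edges in Hz.
#' @return scalar power.
#' @export
band_power <- function(spectrum, band) {
  nyq <- max(spectrum$frequency)
  if (band[1] >= nyq + spectrum$df / 2)
    stop(sprintf("band [%.3g, %.3g] Hz lies above the Nyquist frequency %.3g Hz",
                 band[1], band[2], nyq))
  if (band[2] > nyq + spectrum$df / 2) {
    warning(sprintf("band clipped at the Nyquist frequency (%.3g Hz)", nyq))
    band[2] <- nyq
  }
  sel <- spectrum$frequency >= band[1] & spectrum$frequency <= band[2]
  sum(spectrum$power[sel]) * spectrum$df
}

#' Fractional power change
#'
#' `(p_uncorrected - p_corrected) / p_uncorrected`: positive values mean
#' power removed by denoising, negative values mean power added.
#'
#' @param p_unc,p_cor band power before and after denoising.
#' @return dimensionless fractional change; `NA` with a warning if the
#'   uncorrected power is zero.
#' @export
fractional_power_change <- function(p_unc, p_cor) {
  if (any(p_unc < 0) || any(p_cor < 0)) stop("powers must be non-negative")
  out <- (p_unc - p_cor) / p_unc
  if (any(p_unc == 0)) {
    warning("zero uncorrected power: fractional change undefined")
    out[p_unc == 0] <- NA_real_
  }
  out
}

#' Alias of a frequency under a given sampling rate
#'
#' The apparent frequency of an `f`-Hz oscillation sampled at `sampling_rate`
#' Hz: the minimum over integers k of `|f - k * sampling_rate|`, always in
#' `[0, sampling_rate/2]`.
#'
#' @param f true frequency in Hz (vectorized).
#' @param sampling_rate sampling rate in Hz.
#' @return aliased frequency in Hz.
#' @export
alias_frequency <- function(f, sampling_rate) {
  if (any(f < 0)) stop("f must be non-negative")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  r <- f %% sampling_rate
  pmin(r, sampling_rate - r)
}

#' Band-power table across a cohort
#'
#' One long-format row per subject x method x band x source, with the
#' uncorrected power, corrected power, and fractional change.  Sources are
#' tissue-mean signals (`GM`, `WM`) and/or network-mean signals
#' (`network_1`...).  `denoised` maps method name -> list of denoised
#' [voxel_ts] per subject (the `"none"` method may be included and yields
#' zero fractional change up to mean removal).
#'
#' @param cohort list of `synthetic_subject`s (or lists with `bold`, `id`,
#'   `group`, `cardiac_freq`, `resp_freq`).
#' @param denoised named list: method -> list of [voxel_ts] aligned with
#'   `cohort`.
#' @param sources character: any of `"GM"`, `"WM"`, `"networks"`.
#' @param taper passed to [mean_signal_spectrum()].
#' @return data frame with columns subject, group, method, source, band,
#'   p_uncorrected, p_corrected, fractional_change.
#' @export
band_power_table <- function(cohort, denoised,
                             sources = c("GM", "WM", "networks"),
                             taper = "hann") {
  rows <- list()
  for (si in seq_along(cohort)) {
    sub <- cohort[[si]]
    base <- sub$bold
    bands <- frequency_bands(sub$cardiac_freq, sub$resp_freq)
    masks <- list()
    if ("GM" %in% sources) masks$GM <- tissue_mask(base, "GM")
    if ("WM" %in% sources) masks$WM <- tissue_mask(base, "WM")
    if ("networks" %in% sources && !is.null(base$network))
      for (k in sort(unique(base$network[base$network > 0])))
        masks[[sprintf("network_%d", k)]] <- base$network == k
    empty <- !vapply(masks, any, logical(1))
    if (any(empty)) {
      message("sources absent for ", sub$id, ": ",
              paste(names(masks)[empty], collapse = ", "))
      masks <- masks[!empty]
    }
    for (src in names(masks)) {
      spec_unc <- mean_signal_spectrum(base, masks[[src]], src, taper = taper)
      for (method in names(denoised)) {
        den <- denoised[[method]][[si]]
        if (is.null(den)) {
          message("missing ", method, " output for ", sub$id, "; skipped")
          next
        }
        spec_cor <- mean_signal_spectrum(den, masks[[src]], src, taper = taper)
        for (bn in names(bands)) {
          nyq <- max(spec_unc$frequency)
          if (bands[[bn]][1] >= nyq) next   # band unobservable at this rate
          pu <- band_power(spec_unc, bands[[bn]])
          pc <- band_power(spec_cor, bands[[bn]])
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sub$id, group = sub$group, method = method,
            source = src, band = bn, p_uncorrected = pu, p_corrected = pc,
            fractional_change = fractional_power_change(pu, pc))
        }
      }
    }
  }
  do.call(rbind, rows)
}
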