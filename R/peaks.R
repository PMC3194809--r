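#' Detect peaks on an average spectrum
#'
#' Two detectors: `local_maxima` keeps grid points that are local maxima of
#' the (smoothed, baseline-corrected) average spectrum with signal-to-noise
#' ratio at least `snr_threshold`; `cwt` builds Mexican-hat wavelet ridge
#' lines across 12 dyadically spaced scales and keeps ridges that are long
#' enough, reach the fine scales and exceed the ridge SNR threshold. The
#' noise scale defaults to 1.4826 x MAD of the finest undecimated-wavelet
#' detail band (for `cwt`, of the finest-scale coefficients). Peak intervals
#' are half-open index ranges bounded by the flanking local minima; plateau
#' ties resolve to the lowest index.
#'
#' @param avg Average [mass_spectrum()], smoothed and baseline-subtracted
#'   for `local_maxima`.
#' @param method `"local_maxima"` or `"cwt"`.
#' @param snr_threshold Positive SNR threshold.
#' @param sigma Optional noise scale override; when the estimated noise is
#'   exactly 0 (noise-free input) every local maximum passes.
#' @param scales CWT scales (default `2^seq(0, 5.5, 0.5)`).
#' @param ridge_gap,ridge_min_length CWT ridge-linking parameters.
#' @return List with `peak_mz`, `peak_index`, `intervals` (two-column matrix
#'   of half-open index ranges `[left, right)`), and `snr`.
#' @export
detect_peaks <- function(avg, method = c("local_maxima", "cwt"),
                         snr_threshold = 3, sigma = NULL,
                         scales = 2^seq(0, 5.5, by = 0.5),
                         ridge_gap = 2L, ridge_min_length = 6L) {
  method <- match.arg(method)
  if (snr_threshold <= 0) stop("'snr_threshold' must be positive")
  y <- avg$intensity
  n <- length(y)
  if (method == "local_maxima") {
    cand <- local_maxima_idx(y)
    if (is.null(sigma)) sigma <- noise_mad(y)
    # noise-free signals: every genuine maximum passes, but floating-point
    # dust from reconstruction does not
    snr_all <- if (sigma > 0) y[cand] / sigma else
      ifelse(y[cand] > max(abs(y)) * 1e-9, Inf, 0)
    keep <- snr_all >= snr_threshold
    idx <- cand[keep]
    snr_idx <- snr_all[keep]
  } else {
    coefs <- mexhat_cwt(y, scales)
    cand <- cwt_ridge_peaks(coefs, scales, gap_tol = ridge_gap,
                            min_length = ridge_min_length,
                            snr_threshold = snr_threshold, sigma = sigma)
    # snap ridge positions to local maxima of the spectrum so interval
    # construction (flanking minima) is well defined
    lm <- local_maxima_idx(y)
    if (!length(lm) || !nrow(cand)) {
      idx <- integer(0L); snr_idx <- numeric(0L)
    } else {
      snapped <- vapply(cand$idx, function(i) {
        d <- abs(lm - i)
        if (min(d) <= 4L) lm[which.min(d)] else NA_integer_
      }, integer(1L))
      ok <- !is.na(snapped)
      agg <- tapply(cand$snr[ok], snapped[ok], max)
      idx <- as.integer(names(agg))
      o <- order(idx)
      idx <- idx[o]
      snr_idx <- as.numeric(agg)[o]
    }
  }
  if (!length(idx)) {
    return(list(peak_mz = numeric(0L), peak_index = integer(0L),
                intervals = matrix(integer(0L), 0L, 2L,
                                   dimnames = list(NULL, c("left", "right"))),
                snr = numeric(0L)))
  }
  # half-open intervals bounded by flanking local minima (or spectrum ends)
  mins <- which(c(FALSE, y[2:(n - 1L)] < y[1:(n - 2L)] &
                    y[2:(n - 1L)] <= y[3:n], FALSE))
  bounds <- sort(unique(c(1L, mins, n + 1L)))
  left <- vapply(idx, function(a) max(bounds[bounds < a]), integer(1L))
  right <- vapply(idx, function(a) min(bounds[bounds > a]), integer(1L))
  list(peak_mz = avg$mz[idx], peak_index = idx,
       intervals = cbind(left = left, right = right), snr = snr_idx)
}

#' Quantify detected peaks in individual spectra
#'
#' The intensity of peak `p` in spectrum `s` is the maximum intensity of `s`
#' inside the detection interval of `p` (the intervals defined on the
#' average spectrum).
#'
#' @param spectra List of normalized [mass_spectrum()] on the detection
#'   grid.
#' @param intervals Two-column matrix of half-open index ranges.
#' @param peak_mz Peak positions (Da), one per interval.
#' @param preset,snr_threshold,peak_snr Provenance carried into the profile.
#' @return A [peak_profile] object (samples x peaks intensity matrix).
#' @export
quantify <- function(spectra, intervals, peak_mz, preset = "manual",
                     snr_threshold = NA_real_, peak_snr = NULL) {
  n <- length(spectra[[1L]]$mz)
  if (nrow(intervals) != length(peak_mz)) {
    stop("'intervals' and 'peak_mz' disagree in length")
  }
  if (nrow(intervals) &&
      (any(intervals[, 1L] < 1L) || any(intervals[, 2L] > n + 1L) ||
       any(intervals[, 1L] >= intervals[, 2L]))) {
    stop("peak interval outside the spectrum grid")
  }
  mat <- matrix(0, length(spectra), length(peak_mz))
  for (s in seq_along(spectra)) {
    y <- spectra[[s]]$intensity
    for (p in seq_len(ncol(mat))) {
      mat[s, p] <- max(y[intervals[p, 1L]:(intervals[p, 2L] - 1L)])
    }
  }
  new_peak_profile(
    peak_mz = peak_mz, intervals = intervals, intensity = mat,
    sample_id = vapply(spectra, `[[`, character(1L), "sample_id"),
    replicate_id = sapply(spectra, `[[`, "replicate_id"),
    group = vapply(spectra, `[[`, character(1L), "group"),
    preset = preset, snr_threshold = snr_threshold, peak_snr = peak_snr)
}

# Low-level peak_profile constructor with invariant checks.
new_peak_profile <- function(peak_mz, intervals, intensity, sample_id,
                             replicate_id, group, preset = "manual",
                             snr_threshold = NA_real_, peak_snr = NULL) {
  if (length(peak_mz) > 1L && any(diff(peak_mz) <= 0)) {
    stop("'peak_mz' must be strictly increasing")
  }
  if (ncol(intensity) != length(peak_mz) ||
      nrow(intensity) != length(sample_id)) {
    stop("intensity matrix does not match peaks/samples")
  }
  if (length(peak_mz) && any(intensity < 0)) {
    stop("peak intensities must be non-negative")
  }
  colnames(intensity) <- sprintf("%.6f", peak_mz)
  rownames(intensity) <- make.unique(
    paste0(sample_id, "/r", as.character(replicate_id)), sep = "_")
  structure(list(peak_mz = as.numeric(peak_mz), intervals = intervals,
                 intensity = intensity, sample_id = as.character(sample_id),
                 replicate_id = replicate_id, group = as.character(group),
                 preset = preset, snr_threshold = snr_threshold,
                 peak_snr = peak_snr),
            class = "peak_profile")
}

#' @export
print.peak_profile <- function(x, ...) {
  cat(sprintf(
    "<peak_profile> %s (SNR >= %s): %d peaks x %d spectra, m/z %.6g-%.6g Da\n",
    x$preset, format(x$snr_threshold), length(x$peak_mz),
    nrow(x$intensity),
    if (length(x$peak_mz)) min(x$peak_mz) else NA,
    if (length(x$peak_mz)) max(x$peak_mz) else NA))
  invisible(x)
}

#' @export
summary.peak_profile <- function(object, ...) {
  cat(sprintf("Peak profile from preset '%s', SNR threshold %s\n",
              object$preset, format(object$snr_threshold)))
  cat(sprintf("  %d peaks, %d spectra (%d samples)\n",
              length(object$peak_mz), nrow(object$intensity),
              length(unique(object$sample_id))))
  if (length(object$peak_mz)) {
    cat("  peak m/z range: ",
        sprintf("%.1f-%.1f Da", min(object$peak_mz), max(object$peak_mz)),
        "\n", sep = "")
    cat("  median peak intensity: ",
        format(stats::median(object$intensity), digits = 4), "\n", sep = "")
  }
  invisible(object)
}

# Keep only peaks whose stored per-peak SNR meets `thr` (used by SNR sweeps;
# detection noise does not depend on the threshold, so this equals a re-run).
filter_snr <- function(profile, thr) {
  if (is.null(profile$peak_snr)) stop("profile carries no per-peak SNR")
  keep <- profile$peak_snr >= thr
  profile_select_peaks(profile, keep, snr_threshold = thr)
}

profile_select_peaks <- function(profile, keep, snr_threshold = NULL) {
  new_peak_profile(
    peak_mz = profile$peak_mz[keep],
    intervals = profile$intervals[keep, , drop = FALSE],
    intensity = profile$intensity[, keep, drop = FALSE],
    sample_id = profile$sample_id, replicate_id = profile$replicate_id,
    group = profile$group, preset = profile$preset,
    snr_threshold = if (is.null(snr_threshold)) profile$snr_threshold else
      snr_threshold,
    peak_snr = profile$peak_snr[keep])
}

profile_select_rows <- function(profile, rows) {
  new_peak_profile(
    peak_mz = profile$peak_mz, intervals = profile$intervals,
    intensity = profile$intensity[rows, , drop = FALSE],
    sample_id = profile$sample_id[rows],
    replicate_id = profile$replicate_id[rows],
    group = profile$group[rows], preset = profile$preset,
    snr_threshold = profile$snr_threshold, peak_snr = profile$peak_snr)
}

preset_default_snr <- c(specalign_like = 1.5, mswpro_like = 3,
                        cromwell_like = 5)

#' Run a pre-processing preset
#'
#' Executes one of three average-spectrum-dependent pre-processing
#' procedures end to end and returns the per-spectrum peak profile. All
#' three detect peaks once on the average spectrum and then quantify those
#' peaks in every individual spectrum.
#'
#' \describe{
#' \item{`specalign_like`}{Savitzky-Golay smoothing; restrained
#'   moving-average baseline subtraction; rescaling to a zero minimum; TIC
#'   normalization; average spectrum; FFT alignment of each spectrum to the
#'   average; local-maxima peak picking on the realigned average. Default
#'   SNR 1.5 (a height ratio against the smoothing-residual noise scale).}
#' \item{`mswpro_like`}{Continuous-wavelet ridge-line peak detection on the
#'   average of the raw spectra; per-spectrum linear-interpolation baseline
#'   subtraction, median-AUC normalization, and local-maximum quantification
#'   inside the detection intervals. Default SNR 3.}
#' \item{`cromwell_like`}{Average spectrum; undecimated-wavelet denoising;
#'   monotone-minimum baseline subtraction; local-maxima detection; the same
#'   denoising/baseline treatment plus TIC normalization per spectrum;
#'   quantification by the interval maximum; final extraction of peaks with
#'   SNR at least the threshold. Default SNR 5.}
#' }
#'
#' @param spectra List of at least two [mass_spectrum()] on a common grid.
#' @param preset Preset name.
#' @param snr_threshold SNR threshold; preset default when `NULL`.
#' @param ... Preset tuning parameters (`window`, `poly_order`,
#'   `window_frac`, `max_shift`, `n_segments`, `levels`, `k`).
#' @return A [peak_profile] with one row per input spectrum and the per-peak
#'   SNR values recorded.
#' @export
run_preset <- function(spectra,
                       preset = c("specalign_like", "mswpro_like",
                                  "cromwell_like"),
                       snr_threshold = NULL, ...) {
  preset <- match.arg(preset)
  if (length(spectra) < 2L) stop("need at least 2 spectra")
  if (!same_grid(spectra)) stop("spectra must share one m/z grid")
  if (is.null(snr_threshold)) snr_threshold <- preset_default_snr[[preset]]
  if (snr_threshold <= 0) stop("'snr_threshold' must be positive")
  switch(preset,
         specalign_like = preset_specalign(spectra, snr_threshold, ...),
         mswpro_like = preset_mswpro(spectra, snr_threshold, ...),
         cromwell_like = preset_cromwell(spectra, snr_threshold, ...))
}

preset_specalign <- function(spectra, snr_threshold, window = 11L,
                             poly_order = 2L, window_frac = 0.05,
                             max_shift = 10L) {
  sm <- lapply(spectra, smooth_spectrum, method = "savitzky_golay",
               window = window, poly_order = poly_order)
  # per-spectrum noise from the smoothing residual ("height ratio" scale)
  res_sd <- mapply(function(raw, s) {
    stats::mad(raw$intensity - s$intensity, center = 0)
  }, spectra, sm)
  corr <- lapply(sm, function(s) {
    rescale_min_zero(subtract_baseline(
      s, estimate_baseline(s, "restrained_moving_average",
                           window_frac = window_frac), clip = FALSE))
  })
  norm <- normalize_spectra(corr, "tic")
  f <- attr(norm, "factors")
  avg <- average_spectrum(norm)
  aligned <- align_fft(norm, avg, max_shift = max_shift)
  avg2 <- average_spectrum(aligned)
  # "height ratio" noise scale: the typical single-spectrum residual noise
  # (not reduced by averaging), which keeps the default threshold of 1.5
  # conservative on the much smoother average spectrum
  sigma <- sqrt(mean((f * res_sd)^2))
  det <- detect_peaks(avg2, "local_maxima", snr_threshold, sigma = sigma)
  quantify(aligned, det$intervals, det$peak_mz, preset = "specalign_like",
           snr_threshold = snr_threshold, peak_snr = det$snr)
}

preset_mswpro <- function(spectra, snr_threshold, n_segments = 20L,
                          window = 11L, poly_order = 2L) {
  avg <- average_spectrum(spectra)
  # detection and interval construction use a lightly smoothed,
  # baseline-subtracted average: the Mexican-hat transform responds to the
  # curvature of a raw exponential baseline at coarse scales, so removing
  # the baseline first keeps ridge lines peak-specific
  avg_s <- smooth_spectrum(avg, "savitzky_golay", window = window,
                           poly_order = poly_order)
  avg_corr <- subtract_baseline(
    avg_s, estimate_baseline(avg_s, "linear_interpolation",
                             n_segments = n_segments))
  # ridge SNR noise scale from the unsmoothed baseline-subtracted average:
  # smoothing suppresses the finest-scale coefficients and would understate
  # the noise
  avg_raw_corr <- subtract_baseline(
    avg, estimate_baseline(avg, "linear_interpolation",
                           n_segments = n_segments))
  sigma_c <- stats::mad(mexhat_cwt(avg_raw_corr$intensity, 1)[, 1L],
                        center = 0)
  det <- detect_peaks(avg_corr, "cwt", snr_threshold, sigma = sigma_c)
  corr <- lapply(spectra, function(s) {
    subtract_baseline(s, estimate_baseline(s, "linear_interpolation",
                                           n_segments = n_segments))
  })
  norm <- normalize_spectra(corr, "median_auc")
  quantify(norm, det$intervals, det$peak_mz, preset = "mswpro_like",
           snr_threshold = snr_threshold, peak_snr = det$snr)
}

preset_cromwell <- function(spectra, snr_threshold, levels = 6L, k = 3) {
  avg <- average_spectrum(spectra)
  sigma <- noise_mad(avg$intensity)
  avg_dn <- smooth_spectrum(avg, "udwt", levels = levels, k = k)
  avg_corr <- subtract_baseline(
    avg_dn, estimate_baseline(avg_dn, "monotone_minimum"))
  det <- detect_peaks(avg_corr, "local_maxima", snr_threshold = 1e-9,
                      sigma = sigma)
  corr <- lapply(spectra, function(s) {
    dn <- smooth_spectrum(s, "udwt", levels = levels, k = k)
    subtract_baseline(dn, estimate_baseline(dn, "monotone_minimum"))
  })
  norm <- normalize_spectra(corr, "tic")
  prof <- quantify(norm, det$intervals, det$peak_mz,
                   preset = "cromwell_like", snr_threshold = snr_threshold,
                   peak_snr = det$snr)
  filter_snr(prof, snr_threshold)
}
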