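#' Smooth a spectrum
#'
#' Savitzky-Golay polynomial smoothing (the filter is exact on polynomials up
#' to the fitting order) or undecimated-wavelet denoising.
#'
#' @param spectrum A [mass_spectrum()].
#' @param method `"savitzky_golay"` or `"udwt"`.
#' @param window Odd filter window length (Savitzky-Golay).
#' @param poly_order Polynomial order, must be < `window`.
#' @param levels,k Wavelet depth and hard threshold (see [udwt_denoise()]).
#' @return Smoothed `mass_spectrum` on the same grid.
#' @export
smooth_spectrum <- function(spectrum, method = c("savitzky_golay", "udwt"),
                            window = 11L, poly_order = 2L,
                            levels = 6L, k = 3) {
  method <- match.arg(method)
  y <- spectrum$intensity
  out <- switch(method,
    savitzky_golay = {
      if (window %% 2L == 0L) stop("'window' must be odd")
      if (window > length(y)) stop("'window' longer than the spectrum")
      if (poly_order >= window) stop("'poly_order' must be below 'window'")
      as.numeric(signal::sgolayfilt(y, p = poly_order, n = window))
    },
    udwt = udwt_denoise(y, levels = levels, k = k))
  if (anyNA(out)) stop("smoothing produced NA values")
  set_intensity(spectrum, out)
}

#' Estimate a spectrum baseline
#'
#' Three estimators of the slowly varying background:
#' `restrained_moving_average` - a moving average of a windowed running
#' median (which resists the peaks), restrained so the baseline never
#' exceeds the signal; the restraint clips the baseline to the signal under
#' its local minima, and the median keeps the baseline centred in the noise
#' rather than biased below it;
#' `monotone_minimum` - the cumulative running minimum (non-increasing,
#' equal to the signal on decreasing stretches, and at a peak apex equal to
#' the pre-peak minimum);
#' `linear_interpolation` - linear interpolation through the minima of
#' `n_segments` equal-width segments.
#'
#' @param spectrum A [mass_spectrum()] (smoothing first is recommended).
#' @param method Baseline estimator.
#' @param window_frac Running-median window as a fraction of the number of
#'   points (restrained moving average; default 5%, which must exceed the
#'   widest peak support so the median does not track the peaks).
#' @param n_segments Number of anchor segments (linear interpolation).
#' @return Numeric baseline, same length as the spectrum.
#' @export
estimate_baseline <- function(spectrum,
                              method = c("restrained_moving_average",
                                         "monotone_minimum",
                                         "linear_interpolation"),
                              window_frac = 0.05, n_segments = 20L) {
  method <- match.arg(method)
  y <- spectrum$intensity
  n <- length(y)
  if (n == 0L) stop("empty spectrum")
  switch(method,
    monotone_minimum = cummin(y),
    restrained_moving_average = {
      half <- max(1L, round(window_frac * n / 2))
      w <- 2L * half + 1L
      rmed <- stats::runmed(y, k = min(w, n - (1 - n %% 2)),
                            endrule = "median")
      sm <- as.numeric(stats::filter(rmed, rep(1 / w, w), sides = 2L))
      # edges: fall back to the running median itself
      sm[is.na(sm)] <- rmed[is.na(sm)]
      pmin(sm, y)
    },
    linear_interpolation = {
      breaks <- floor(seq(1L, n + 1L, length.out = n_segments + 1L))
      anchor_idx <- vapply(seq_len(n_segments), function(i) {
        seg <- breaks[i]:(breaks[i + 1L] - 1L)
        seg[which.min(y[seg])]
      }, integer(1L))
      stats::approx(spectrum$mz[anchor_idx], y[anchor_idx],
                    xout = spectrum$mz, rule = 2L)$y
    })
}

#' Subtract a baseline, clipping at zero
#'
#' @param spectrum A [mass_spectrum()].
#' @param baseline Numeric baseline of the same length.
#' @param clip Clip negative residuals to 0 (default TRUE).
#' @return Baseline-corrected `mass_spectrum`.
#' @export
subtract_baseline <- function(spectrum, baseline, clip = TRUE) {
  y <- spectrum$intensity - baseline
  if (clip) y <- pmax(y, 0)
  set_intensity(spectrum, y)
}

# Rescale intensities to be non-negative by shifting the minimum to 0.
rescale_min_zero <- function(spectrum) {
  set_intensity(spectrum, spectrum$intensity - min(spectrum$intensity))
}

#' Normalize a set of spectra
#'
#' `tic` scales every spectrum to the mean pre-normalization total ion
#' current (intensity sum); `median_auc` scales every spectrum to the median
#' pre-normalization trapezoidal area under the curve. Either way each
#' spectrum is multiplied by a single positive factor.
#'
#' @param spectra List of [mass_spectrum()], baseline-subtracted and
#'   non-negative.
#' @param method `"tic"` or `"median_auc"`.
#' @return List of normalized spectra, with the factors in attribute
#'   `"factors"`.
#' @export
normalize_spectra <- function(spectra, method = c("tic", "median_auc")) {
  method <- match.arg(method)
  if (!length(spectra)) stop("no spectra to normalize")
  size <- vapply(spectra, function(s) {
    switch(method,
           tic = sum(s$intensity),
           median_auc = trapz(s$mz, s$intensity))
  }, numeric(1L))
  bad <- which(size <= 0)
  if (length(bad)) {
    stop(sprintf("spectrum %s has zero total intensity; cannot normalize",
                 spectrum_label(spectra[[bad[1L]]])))
  }
  target <- switch(method, tic = mean(size), median_auc = stats::median(size))
  factors <- target / size
  out <- Map(function(s, f) set_intensity(s, s$intensity * f),
             spectra, factors)
  attr(out, "factors") <- factors
  out
}

#' Align spectra to a reference by integer grid shifts
#'
#' Each spectrum is shifted by the integer offset (at most `max_shift` grid
#' points in magnitude) that maximises its cross-correlation with the
#' reference, computed through the FFT. Vacated edge points are padded with
#' the edge value. Ties are broken toward the smallest |offset|.
#'
#' @param spectra List of [mass_spectrum()] on a common grid.
#' @param reference Reference `mass_spectrum` (typically the average).
#' @param max_shift Maximum |offset| in grid points.
#' @return List of aligned spectra, with the offsets in attribute
#'   `"offsets"`.
#' @export
align_fft <- function(spectra, reference, max_shift = 10L) {
  n <- length(reference$intensity)
  if (max_shift >= n) stop("'max_shift' must be below the spectrum length")
  fr <- stats::fft(reference$intensity)
  lags <- seq.int(-max_shift, max_shift)
  offsets <- integer(length(spectra))
  out <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    x <- spectra[[i]]$intensity
    # circular cross-correlation cc[s] = sum_j ref[j] * x[j - s]
    cc <- Re(stats::fft(fr * Conj(stats::fft(x)), inverse = TRUE)) / n
    vals <- cc[(lags %% n) + 1L]
    best <- which(vals == max(vals))
    s <- lags[best[which.min(abs(lags[best]))]]
    offsets[i] <- s
    shifted <- if (s > 0) {
      c(rep(x[1L], s), x[seq_len(n - s)])
    } else if (s < 0) {
      c(x[(-s + 1L):n], rep(x[n], -s))
    } else x
    out[[i]] <- set_intensity(spectra[[i]], shifted)
  }
  attr(out, "offsets") <- offsets
  out
}
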