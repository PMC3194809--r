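test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
  sp <- mk_spectrum(function(m) (m / 1000)^2)
  out <- smooth_spectrum(sp, "savitzky_golay", window = 11L,
                         poly_order = 2L)
  interior <- 6:(length(sp$mz) - 5L)
  expect_equal(out$intensity[interior], sp$intensity[interior],
               tolerance = 1e-9)
})

test_that("Savitzky-Golay equals an independent least-squares fit", {
  set.seed(1)
  y <- c(rep(0, 10), rep(1, 10)) + 0  # step function, 20 points
  sp <- mass_spectrum(seq_len(20) + 1000, y)
  out <- smooth_spectrum(sp, "savitzky_golay", window = 5L, poly_order = 2L)
  # oracle: per-window quadratic least squares evaluated at the centre
  oracle <- y
  for (i in 3:18) {
    w <- (i - 2):(i + 2)
    fit <- lm(y[w] ~ poly(seq_along(w), 2))
    oracle[i] <- fitted(fit)[3]
  }
  expect_equal(out$intensity[3:18], oracle[3:18], tolerance = 1e-8)
  expect_gt(sum(abs(out$intensity - y)), 0)  # the step is reshaped
})

test_that("wavelet decomposition reconstructs perfectly at threshold 0", {
  set.seed(2)
  y <- cumsum(rnorm(256)) + gauss(1:256, 128, 20, 6)
  expect_equal(udwt_denoise(y, levels = 6L, k = 0), y, tolerance = 1e-10)
  dec <- udwt(y, 5L)
  expect_equal(dec$smooth + Reduce(`+`, dec$details), y, tolerance = 1e-10)
  expect_error(udwt(y, 9L), "levels")
})

test_that("wavelet denoising attenuates noise but keeps the peak", {
  set.seed(3)
  clean <- gauss(1:512, 256, 30, 8)
  noisy <- clean + rnorm(512, 0, 1)
  dn <- udwt_denoise(noisy, levels = 6L, k = 3)
  flat <- c(1:180, 330:512)  # far from the peak
  expect_lt(sd(dn[flat]), 0.35 * sd(noisy[flat] - clean[flat]))
  expect_gt(max(dn), 25)
  expect_lt(abs(which.max(dn) - 256), 4)
})

test_that("baseline estimators satisfy their defining behaviour", {
  mz <- seq(1000, 1029)
  dec <- mk_spectrum(function(m) 100 * exp(-(m - 1000) / 50), mz = mz)
  bl <- estimate_baseline(dec, "monotone_minimum")
  expect_equal(bl, dec$intensity)  # decreasing spectrum: baseline = signal
  flat <- mk_spectrum(function(m) rep(7, length(m)), mz = mz)
  for (m in c("restrained_moving_average", "monotone_minimum",
              "linear_interpolation")) {
    expect_equal(estimate_baseline(flat, m), rep(7, 30), tolerance = 1e-9)
  }
  # exp decay + one Gaussian: baseline at the apex is the pre-peak minimum,
  # verified against a hand-run cumulative-minimum recursion
  y <- 50 * exp(-(mz - 1000) / 100) + gauss(mz, 1020, 30, 2)
  spk <- mass_spectrum(mz, y)
  bl <- estimate_baseline(spk, "monotone_minimum")
  oracle <- y
  for (i in 2:30) oracle[i] <- min(oracle[i - 1L], y[i])
  expect_equal(bl, oracle)
  apex <- which.max(gauss(mz, 1020, 30, 2))
  expect_equal(bl[apex], min(y[1:(apex - 1L)]))
  # restrained moving average never exceeds the signal
  expect_true(all(estimate_baseline(spk, "restrained_moving_average",
                                    window_frac = 0.2) <= y + 1e-12))
})

test_that("normalization hits the prescribed targets exactly", {
  mz <- seq(0, 10)
  mk <- function(c) mass_spectrum(mz, rep(c, 11), sample_id = paste0("s", c))
  # tic: sums 11*c; two spectra with TIC 10 and 30 -> both 20
  s1 <- mass_spectrum(mz, rep(10 / 11, 11))
  s2 <- mass_spectrum(mz, rep(30 / 11, 11))
  out <- normalize_spectra(list(s1, s2), "tic")
  expect_equal(sum(out[[1L]]$intensity), 20, tolerance = 1e-12)
  expect_equal(sum(out[[2L]]$intensity), 20, tolerance = 1e-12)
  expect_equal(attr(out, "factors"), c(2, 2 / 3), tolerance = 1e-12)
  # single spectrum: unchanged
  one <- normalize_spectra(list(s1), "median_auc")
  expect_equal(one[[1L]]$intensity, s1$intensity)
  # median_auc: flat spectra with trapezoid areas 5, 7, 100 -> all 7
  out <- normalize_spectra(list(mk(0.5), mk(0.7), mk(10)), "median_auc")
  areas <- vapply(out, function(s) peakconcord:::trapz(s$mz, s$intensity),
                  numeric(1L))
  expect_equal(areas, rep(7, 3), tolerance = 1e-12)
  expect_equal(attr(out, "factors"), c(1.4, 1, 0.07), tolerance = 1e-12)
  # zero spectrum is an error naming the spectrum
  zero <- mass_spectrum(mz, rep(0, 11), sample_id = "BAD", replicate_id = 2)
  expect_error(normalize_spectra(list(s1, zero), "tic"), "BAD")
  # invariant: TIC equal to relative tolerance 1e-9 on random spectra
  set.seed(4)
  sps <- lapply(1:6, function(i) mass_spectrum(mz, runif(11, 0.1, 5)))
  out <- normalize_spectra(sps, "tic")
  tics <- vapply(out, function(s) sum(s$intensity), numeric(1L))
  expect_lt(diff(range(tics)) / mean(tics), 1e-9)
})

test_that("average spectrum is the pointwise mean", {
  sp <- mk_spectrum(function(m) sin(m / 40) + 2)
  expect_equal(average_spectrum(list(sp))$intensity, sp$intensity)
  neg <- set_int <- mass_spectrum(sp$mz, -sp$intensity + 6)
  expect_equal(average_spectrum(list(sp, neg))$intensity,
               rep(3, length(sp$mz)))
  set.seed(5)
  sps <- lapply(1:10, function(i) mass_spectrum(sp$mz, runif(200)))
  oracle <- numeric(200)
  for (i in seq_len(200)) {
    for (s in sps) oracle[i] <- oracle[i] + s$intensity[i]
  }
  expect_equal(average_spectrum(sps)$intensity, oracle / 10,
               tolerance = 1e-12)
  bad <- mass_spectrum(sp$mz + 0.5, sp$intensity)
  expect_error(average_spectrum(list(sp, bad)), "grid")
})

test_that("FFT alignment recovers constructed shifts", {
  ref <- mk_spectrum(function(m) gauss(m, 1100, 10, 8))
  out <- align_fft(list(ref), ref, max_shift = 10L)
  expect_identical(attr(out, "offsets"), 0L)
  # spectrum = reference shifted right by 3 grid points -> offset -3
  y <- ref$intensity
  shifted <- mass_spectrum(ref$mz, c(rep(y[1], 3), y[1:(length(y) - 3)]))
  out <- align_fft(list(shifted), ref, max_shift = 5L)
  expect_equal(attr(out, "offsets"), -3L)
  interior <- 10:190
  expect_equal(out[[1L]]$intensity[interior], y[interior])
  expect_error(align_fft(list(ref), ref, max_shift = 1000L), "max_shift")
})

test_that("alignment matches a brute-force argmax under noise", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    mz <- seq_len(200) + 999
    clean <- gauss(mz, 1100, 10, 6)
    y <- c(rep(clean[1], 5), clean[1:195]) + rnorm(200, 0, 0.5)
    ref <- mass_spectrum(mz, clean)
    sp <- mass_spectrum(mz, y)
    out <- align_fft(list(sp), ref, max_shift = 8L)
    # brute force: try every offset, score by dot product with reference
    scores <- vapply(-8:8, function(o) {
      shifted <- if (o > 0) c(rep(y[1], o), y[1:(200 - o)]) else
        if (o < 0) c(y[(-o + 1):200], rep(y[200], -o)) else y
      sum(clean * shifted)
    }, numeric(1L))
    expect_equal(scores[attr(out, "offsets") + 9L], max(scores),
                 tolerance = 1e-8)
    if (attr(out, "offsets") == -5L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("local-maxima detection equals the exhaustive scan oracle", {
  mz <- seq(1000, 1999)
  # single noise-free Gaussian: exactly one peak at the apex
  one <- mass_spectrum(mz, gauss(mz, 1500, 10, 15))
  det <- detect_peaks(one, "local_maxima", snr_threshold = 3)
  expect_equal(det$peak_mz, 1500)
  # flat spectrum: no peaks
  flat <- mass_spectrum(mz, rep(1, 1000))
  expect_length(detect_peaks(flat, "local_maxima", 1)$peak_mz, 0L)
  # two Gaussians + noise at several thresholds vs the oracle
  set.seed(6)
  y <- gauss(mz, 1300, 10, 10) + gauss(mz, 1700, 3, 10) + rnorm(1000)
  sp <- mass_spectrum(mz, y)
  sigma <- peakconcord:::noise_mad(y)
  counts <- vapply(c(2.5, 5, 8), function(thr) {
    det <- detect_peaks(sp, "local_maxima", thr)
    oracle <- detect_brute_force(y, sigma, thr)
    expect_identical(det$peak_index, oracle)
    length(det$peak_index)
  }, numeric(1L))
  expect_true(all(diff(counts) <= 0))
  expect_error(detect_peaks(sp, "local_maxima", 0), "snr_threshold")
})

test_that("detected peaks sit strictly inside non-overlapping intervals", {
  for (s in 1:5) {
    set.seed(s)
    mz <- seq(1000, 1799)
    y <- gauss(mz, 1150, 20, 8) + gauss(mz, 1400, 12, 10) +
      gauss(mz, 1650, 8, 12) + rnorm(800, 0, 0.4)
    det <- detect_peaks(mass_spectrum(mz, y), "local_maxima", 3)
    expect_gt(length(det$peak_index), 0L)
    expect_true(all(det$peak_index > det$intervals[, "left"]))
    expect_true(all(det$peak_index < det$intervals[, "right"]))
    if (nrow(det$intervals) > 1L) {
      expect_true(all(det$intervals[-1L, "left"] >=
                        det$intervals[-nrow(det$intervals), "right"]))
    }
  }
})

test_that("cwt detection finds well-separated peaks and honours SNR", {
  set.seed(7)
  mz <- seq(1000, 2999)
  y <- gauss(mz, 1400, 30, 8) + gauss(mz, 2200, 15, 12) + rnorm(2000, 0, 1)
  det <- detect_peaks(mass_spectrum(mz, y), "cwt", snr_threshold = 3)
  expect_gte(length(det$peak_mz), 2L)
  expect_true(any(abs(det$peak_mz - 1400) <= 6))
  expect_true(any(abs(det$peak_mz - 2200) <= 8))
  det_hi <- detect_peaks(mass_spectrum(mz, y), "cwt", snr_threshold = 12)
  expect_lte(length(det_hi$peak_mz), length(det$peak_mz))
})

test_that("quantification equals the double-loop maximum oracle", {
  mz <- seq(1000, 1099)
  avg <- mass_spectrum(mz, gauss(mz, 1030, 10, 5) + gauss(mz, 1070, 6, 5))
  det <- detect_peaks(avg, "local_maxima", 1)
  prof <- quantify(list(avg), det$intervals, det$peak_mz)
  expect_equal(as.numeric(prof$intensity[1L, ]),
               avg$intensity[det$peak_index])
  zero <- mass_spectrum(mz, rep(0, 100))
  prof <- quantify(list(zero), det$intervals, det$peak_mz)
  expect_true(all(prof$intensity == 0))
  set.seed(8)
  sps <- lapply(1:5, function(i) mass_spectrum(mz, runif(100)))
  ints <- cbind(left = c(1L, 30L, 60L, 90L), right = c(30L, 60L, 90L, 101L))
  prof <- quantify(sps, ints, c(1010, 1045, 1075, 1095))
  for (s in 1:5) {
    for (p in 1:4) {
      expect_equal(prof$intensity[s, p],
                   max(sps[[s]]$intensity[ints[p, 1]:(ints[p, 2] - 1L)]))
    }
  }
  expect_error(quantify(sps, cbind(1L, 200L), 1050), "interval")
})

test_that("presets agree on a clean single-peak dataset", {
  cfg <- sim_config(n_cancer = 3L, n_normal = 3L, n_replicates = 2L,
                    mz_range = c(1000, 2000), grid_step = 1, n_peaks = 1L,
                    de_fraction = 0, peak_height_range = c(30, 30),
                    baseline_amplitude = 0, noise_sd = 0,
                    scale_sd = 0.02, mz_jitter_sd = 0, height_cv = 0.05,
                    seed = 13L)
  ds <- simulate_dataset(cfg)
  true_mz <- ds$truth$truth$mz[1L]
  for (p in c("specalign_like", "mswpro_like", "cromwell_like")) {
    prof <- preprocess_dataset(ds, p)
    expect_equal(length(prof$peak_mz), 1L, label = p)
    expect_lt(abs(prof$peak_mz - true_mz) / true_mz, 0.003)
  }
  expect_error(run_preset(ds$spectra, "nonsense"), "specalign_like")
})

test_that("a permissive Cromwell run covers the default SpecAlign peaks", {
  covered <- 0L
  for (s in 1:20) {
    ds <- simulate_dataset(small_sim_config(seed = 100 + s))
    spec <- preprocess_dataset(ds, "specalign_like", 1.5)
    crom <- preprocess_dataset(ds, "cromwell_like", 2)
    if (length(spec$peak_mz) && length(crom$peak_mz)) {
      k <- match_peaks(spec$peak_mz, crom$peak_mz, 0.003)$k
      if (k == length(spec$peak_mz)) covered <- covered + 1L
    }
  }
  expect_gte(covered, 18L)
})

test_that("peak counts are non-increasing in the SNR threshold", {
  ds <- simulate_dataset(small_sim_config(seed = 21L, noise_sd = 1))
  for (p in c("specalign_like", "mswpro_like", "cromwell_like")) {
    counts <- vapply(c(1.5, 3, 6, 12), function(s) {
      length(suppressWarnings(preprocess_dataset(ds, p, s))$peak_mz)
    }, numeric(1L))
    expect_true(all(diff(counts) <= 0), label = p)
  }
})

test_that("baseline subtraction and rescaling keep intensities non-negative", {
  ds <- simulate_dataset(small_sim_config(seed = 31L, noise_sd = 1))
  for (sp in ds$spectra[1:4]) {
    sm <- smooth_spectrum(sp, "savitzky_golay")
    corr <- subtract_baseline(
      sm, estimate_baseline(sm, "restrained_moving_average"), clip = FALSE)
    corr <- peakconcord:::rescale_min_zero(corr)
    expect_gte(min(corr$intensity), 0)
    dn <- smooth_spectrum(sp, "udwt")
    corr2 <- subtract_baseline(dn, estimate_baseline(dn, "monotone_minimum"))
    expect_gte(min(corr2$intensity), 0)
  }
})
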