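# Shared fixtures and independent oracles used across the suite.

# A small spectrum from a function of m/z.
mk_spectrum <- function(f, mz = seq(1000, 1199, by = 1), sample_id = "S1",
                        replicate_id = 1L, group = "normal") {
  mass_spectrum(mz, f(mz), sample_id = sample_id,
                replicate_id = replicate_id, group = group)
}

gauss <- function(mz, center, height, width) {
  height * exp(-(mz - center)^2 / (2 * width^2))
}

# A tiny low-noise simulation used by several preprocessing tests.
small_sim_config <- function(seed, noise_sd = 0.2, mz_jitter_sd = 0,
                             n_peaks = 8L, de_fraction = 0.25,
                             height_cv = 0.3) {
  sim_config(n_cancer = 3L, n_normal = 3L, n_replicates = 2L,
             mz_range = c(1000, 3000), grid_step = 1, n_peaks = n_peaks,
             de_fraction = de_fraction, fold_changes = c(2, 0.5),
             peak_height_range = c(5, 40), noise_sd = noise_sd,
             scale_sd = 0.05, mz_jitter_sd = mz_jitter_sd,
             height_cv = height_cv, seed = seed)
}

# Brute-force BH: try every observed p-value (and 0) as the cutoff and keep
# the largest one satisfying the step-up inequality.
bh_brute_force <- function(p, q) {
  m <- length(p)
  best <- NA_real_
  for (cand in sort(unique(p))) {
    i <- sum(p <= cand)
    if (cand <= i * q / m) best <- cand
  }
  list(significant = if (!is.na(best)) p <= best else rep(FALSE, m),
       cutoff = if (is.na(best)) 0 else best)
}

# Brute-force greedy matcher: enumerate all candidate pairs, sort by
# relative distance, accept greedily (independent of the package's
# interval-search implementation).
match_brute_force <- function(a, b, shift) {
  cand <- NULL
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      if (abs(a[i] - b[j]) <= shift * a[i] + 1e-12) {
        cand <- rbind(cand, c(i, j, abs(a[i] - b[j]) / a[i]))
      }
    }
  }
  if (is.null(cand)) return(0L)
  cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  ua <- logical(length(a)); ub <- logical(length(b)); k <- 0L
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!ua[i] && !ub[j]) { ua[i] <- TRUE; ub[j] <- TRUE; k <- k + 1L }
  }
  k
}

# Exhaustive local-maximum + SNR scan used as the peak-detection oracle.
detect_brute_force <- function(y, sigma, thr) {
  n <- length(y)
  idx <- integer(0L)
  for (i in 2:(n - 1L)) {
    if (y[i] > y[i - 1L] && y[i] >= y[i + 1L] &&
        (if (sigma > 0) y[i] / sigma >= thr else y[i] > 0)) {
      idx <- c(idx, i)
    }
  }
  idx
}

make_tempdir <- function() {
  d <- tempfile("peakconcord")
  dir.create(d)
  d
}
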