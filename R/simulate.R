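#' Configuration for the synthetic spectrum generator
#'
#' Describes a two-group (cancer/normal) SELDI-like cohort with duplicate
#' technical spectra per sample. Each spectrum is built on a common m/z grid
#' as `scale * (sum of Gaussian peaks + exponential baseline) + noise`, with
#' a per-spectrum constant m/z jitter applied to the peak positions before
#' gridding. Peaks have m/z-proportional width `a + b * mz` (Gaussian sd, Da)
#' and per-sample biological height variation (log-normal, shared by the
#' replicates of a sample). A designated subset of peaks is differentially
#' expressed: their expected height in the cancer group is the normal-group
#' height times the fold change.
#'
#' The defaults emulate a plasma cohort of 26 cancer and 14 normal samples
#' with duplicate spectra in the 1-10 kDa range.
#'
#' @param n_cancer,n_normal Samples per group.
#' @param n_replicates Technical replicate spectra per sample (default 2).
#' @param mz_range Numeric length-2, low < high (Da).
#' @param grid_step Grid spacing (Da).
#' @param n_peaks Number of true peaks.
#' @param de_fraction Fraction of peaks that are differentially expressed.
#' @param fold_changes Multiplicative cancer/normal height ratios for the DE
#'   peaks, recycled in order of increasing peak height.
#' @param peak_height_range Range of expected peak heights (intensity units)
#'   in the normal group.
#' @param peak_width_a,peak_width_b Width model: Gaussian sd = a + b * mz (Da).
#' @param baseline_amplitude,baseline_decay Exponential baseline
#'   `A * exp(-mz / tau)`.
#' @param noise_sd Additive Gaussian noise sd per grid point.
#' @param scale_sd Sd of the per-spectrum log-normal intensity scale factor.
#' @param mz_jitter_sd Sd (Da) of the per-spectrum constant m/z shift.
#' @param height_cv Biological coefficient of variation of per-sample peak
#'   heights (log-normal, mean-preserving); replicates of a sample share the
#'   same realisation.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cancer = 26L, n_normal = 14L, n_replicates = 2L,
                       mz_range = c(1000, 10000), grid_step = 1,
                       n_peaks = 30L, de_fraction = 1 / 6, fold_changes = 2,
                       peak_height_range = c(2, 60),
                       peak_width_a = 1.5, peak_width_b = 0.002,
                       baseline_amplitude = 60, baseline_decay = 2500,
                       noise_sd = 1.5, scale_sd = 0.15, mz_jitter_sd = 1.5,
                       height_cv = 0.35, seed = 1L) {
  stopifnot_scalar_prob(de_fraction, "de_fraction")
  if (!is_count(n_cancer) || !is_count(n_normal) || !is_count(n_replicates) ||
      !is_count(n_peaks)) {
    stop("'n_cancer', 'n_normal', 'n_replicates' and 'n_peaks' must be counts")
  }
  if (length(mz_range) != 2L || mz_range[1L] >= mz_range[2L]) {
    stop("'mz_range' must be (low, high) with low < high")
  }
  if (grid_step <= 0 || peak_width_a <= 0 || peak_width_b < 0 ||
      any(peak_height_range <= 0) || noise_sd < 0 || scale_sd < 0 ||
      mz_jitter_sd < 0 || height_cv < 0 || baseline_amplitude < 0 ||
      baseline_decay <= 0) {
    stop("widths, heights and dispersion parameters must be positive")
  }
  if (any(fold_changes <= 0)) stop("'fold_changes' must be positive ratios")
  cfg <- list(n_cancer = as.integer(n_cancer), n_normal = as.integer(n_normal),
              n_replicates = as.integer(n_replicates), mz_range = mz_range,
              grid_step = grid_step, n_peaks = as.integer(n_peaks),
              de_fraction = de_fraction, fold_changes = fold_changes,
              peak_height_range = peak_height_range,
              peak_width_a = peak_width_a, peak_width_b = peak_width_b,
              baseline_amplitude = baseline_amplitude,
              baseline_decay = baseline_decay, noise_sd = noise_sd,
              scale_sd = scale_sd, mz_jitter_sd = mz_jitter_sd,
              height_cv = height_cv, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Maximum Gaussian sd over the configured m/z range.
max_peak_width <- function(cfg) {
  cfg$peak_width_a + cfg$peak_width_b * cfg$mz_range[2L]
}

#' Simulate a two-group spectrum set with known ground truth
#'
#' Draws true peak positions (uniform with a minimum separation of twice the
#' maximum peak width, so peaks are resolvable), designates DE peaks spread
#' evenly across the height order (so differential signal spans the dynamic
#' range, low-abundance markers included), and renders `n_replicates` spectra
#' per sample on the common grid.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset` with elements `spectra` (list of
#'   [mass_spectrum()]), `truth` (class `ground_truth`: data frame of peak
#'   m/z, DE flag, fold change, plus the per-group expected heights),
#'   `sample_heights` (true per-sample peak heights before noise/scale;
#'   replicates share them), and `manifest` (sample_id, replicate, group per
#'   spectrum).
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  w_max <- max_peak_width(cfg)
  low <- cfg$mz_range[1L]; high <- cfg$mz_range[2L]
  margin <- 3 * w_max; gap <- 2 * w_max
  usable <- (high - low) - 2 * margin - (cfg$n_peaks - 1) * gap
  if (usable <= 0) {
    stop(sprintf(
      "config rejected: %d peaks of width <= %.3g Da cannot be resolved in [%g, %g]",
      cfg$n_peaks, w_max, low, high))
  }
  with_seed(cfg$seed, {
    mz <- seq(low, high, by = cfg$grid_step)
    # uniform positions conditional on pairwise separation >= gap
    centers <- low + margin + sort(stats::runif(cfg$n_peaks, 0, usable)) +
      (seq_len(cfg$n_peaks) - 1L) * gap
    widths <- cfg$peak_width_a + cfg$peak_width_b * centers
    heights <- stats::runif(cfg$n_peaks, cfg$peak_height_range[1L],
                            cfg$peak_height_range[2L])
    n_de <- round(cfg$de_fraction * cfg$n_peaks)
    is_de <- rep(FALSE, cfg$n_peaks)
    fc <- rep(1, cfg$n_peaks)
    if (n_de > 0) {
      ord <- order(heights)  # DE designations span the height range
      de_idx <- ord[round(seq(1, cfg$n_peaks, length.out = n_de))]
      is_de[de_idx] <- TRUE
      fc[de_idx] <- rep_len(cfg$fold_changes, n_de)
    }
    group_means <- cbind(normal = heights, cancer = heights * fc)

    samples <- data.frame(
      sample_id = c(sprintf("C%03d", seq_len(cfg$n_cancer)),
                    sprintf("N%03d", seq_len(cfg$n_normal))),
      group = rep(c("cancer", "normal"), c(cfg$n_cancer, cfg$n_normal)),
      stringsAsFactors = FALSE)
    n_samples <- nrow(samples)

    # per-sample true heights: mean-preserving log-normal around group means
    sig_b <- sqrt(log1p(cfg$height_cv^2))
    bio <- matrix(exp(stats::rnorm(n_samples * cfg$n_peaks, 0, sig_b) -
                        sig_b^2 / 2), n_samples, cfg$n_peaks)
    expected <- t(group_means[, ifelse(samples$group == "cancer", 2L, 1L),
                              drop = FALSE])
    sample_heights <- expected * bio
    dimnames(sample_heights) <- list(samples$sample_id,
                                     sprintf("%.6f", centers))

    baseline <- cfg$baseline_amplitude * exp(-mz / cfg$baseline_decay)
    spectra <- vector("list", n_samples * cfg$n_replicates)
    manifest <- vector("list", length(spectra))
    idx <- 0L
    for (s in seq_len(n_samples)) {
      for (r in seq_len(cfg$n_replicates)) {
        idx <- idx + 1L
        jitter <- stats::rnorm(1L, 0, cfg$mz_jitter_sd)
        scale <- exp(stats::rnorm(1L, 0, cfg$scale_sd))
        sig <- baseline
        for (p in seq_len(cfg$n_peaks)) {
          c_p <- centers[p] + jitter
          w_p <- widths[p]
          win <- which(mz >= c_p - 6 * w_p & mz <= c_p + 6 * w_p)
          if (length(win)) {
            sig[win] <- sig[win] +
              sample_heights[s, p] * exp(-(mz[win] - c_p)^2 / (2 * w_p^2))
          }
        }
        y <- scale * sig
        if (cfg$noise_sd > 0) {
          y <- y + stats::rnorm(length(mz), 0, cfg$noise_sd)
        }
        spectra[[idx]] <- mass_spectrum(mz, y,
                                        sample_id = samples$sample_id[s],
                                        replicate_id = r,
                                        group = samples$group[s])
        manifest[[idx]] <- data.frame(
          file = sprintf("%s_r%d.csv", samples$sample_id[s], r),
          sample_id = samples$sample_id[s], replicate = r,
          group = samples$group[s], stringsAsFactors = FALSE)
      }
    }
    truth <- structure(
      list(truth = data.frame(mz = centers, is_de = is_de, fold_change = fc),
           group_means = group_means, config = cfg),
      class = "ground_truth")
    structure(list(spectra = spectra, truth = truth,
                   sample_heights = sample_heights,
                   manifest = do.call(rbind, manifest)),
              class = "sim_dataset")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d peaks, %d DE (fold changes %s)\n",
              nrow(x$truth), sum(x$truth$is_de),
              paste(format(unique(x$truth$fold_change[x$truth$is_de]),
                           digits = 3), collapse = ", ")))
  invisible(x)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d spectra (%d samples x %d replicates), %d grid points\n",
              length(x$spectra), nrow(x$sample_heights),
              x$truth$config$n_replicates, length(x$spectra[[1L]]$mz)))
  print(x$truth)
  invisible(x)
}

#' Simulate a p-value mixture for multiple-testing procedures
#'
#' Null p-values are uniform on (0, 1); alternatives come from a one-sided
#' normal shift test: `p = 1 - pnorm(z)` with `z ~ N(effect, 1)`. When a
#' stratum assignment is supplied, alternatives are concentrated in the first
#' stratum level (spilling over in level order once it is full), which is the
#' regime where per-stratum FDR control gains power.
#'
#' @param n_tests Number of tests.
#' @param pi0 Fraction of true nulls, in `[0, 1]`.
#' @param effect Noncentrality (mean shift) of the alternatives.
#' @param strata_assignment Optional vector of stratum labels, length
#'   `n_tests`.
#' @param seed Integer seed.
#' @return List with `p_values`, `is_alternative` and `strata`.
#' @export
simulate_pvalue_mixture <- function(n_tests, pi0, effect,
                                    strata_assignment = NULL, seed = 1L) {
  stopifnot_scalar_prob(pi0, "pi0")
  if (!is_count(n_tests)) stop("'n_tests' must be a count")
  n_alt <- round((1 - pi0) * n_tests)
  with_seed(seed, {
    alt <- rep(FALSE, n_tests)
    if (n_alt > 0) {
      if (is.null(strata_assignment)) {
        alt[sample.int(n_tests, n_alt)] <- TRUE
      } else {
        if (length(strata_assignment) != n_tests) {
          stop("'strata_assignment' must have one label per test")
        }
        lev <- unique(strata_assignment)
        remaining <- n_alt
        for (l in lev) {
          pos <- which(strata_assignment == l & !alt)
          take <- min(length(pos), remaining)
          if (take > 0) alt[sample(pos, take)] <- TRUE
          remaining <- remaining - take
          if (remaining <= 0) break
        }
      }
    }
    z <- stats::rnorm(n_tests)
    z[alt] <- z[alt] + effect
    p <- stats::runif(n_tests)
    p[alt] <- stats::pnorm(z[alt], lower.tail = FALSE)
    list(p_values = p, is_alternative = alt, strata = strata_assignment)
  })
}

#' Score a detected peak list against ground truth
#'
#' Matches detected to true peaks one-to-one within a relative window of
#' `shift` times the true m/z. Sensitivity is the fraction of true peaks
#' matched; the empirical FDR is the fraction of detected peaks left
#' unmatched. Empty lists give 0 by convention.
#'
#' @param detected_mz Numeric vector of detected peak positions (Da).
#' @param truth A `ground_truth` object or numeric vector of true m/z.
#' @param shift Relative matching window (e.g. 0.003 for +/-0.3%).
#' @return List with `sensitivity`, `fdr`, `n_matched`, `n_true`,
#'   `n_detected`.
#' @export
evaluate_detection <- function(detected_mz, truth, shift = 0.003) {
  if (shift <= 0) stop("'shift' must be positive")
  true_mz <- if (inherits(truth, "ground_truth")) truth$truth$mz else
    as.numeric(truth)
  n_true <- length(true_mz); n_det <- length(detected_mz)
  if (n_true == 0L || n_det == 0L) {
    return(list(sensitivity = 0, fdr = 0, n_matched = 0L,
                n_true = n_true, n_detected = n_det))
  }
  k <- match_peaks(sort(true_mz), sort(detected_mz), shift)$k
  list(sensitivity = k / n_true,
       fdr = (n_det - k) / n_det,
       n_matched = k, n_true = n_true, n_detected = n_det)
}

#' Simulate a quantified peak-intensity matrix directly
#'
#' Skips the spectrum level and draws log-normal per-sample peak intensities
#' for a two-group design: `log2 x = base + log2_fc * [DE & cancer] +
#' N(0, sigma_log2)`. This is the generator behind the stratified-FDR
#' "reversal" and "strong-signal" scenarios, where only the testing and
#' selection stages are under study.
#'
#' @param n_cancer,n_normal Samples per group.
#' @param n_peaks Number of peaks (tests).
#' @param n_de Number of DE peaks (the first `n_de` peaks).
#' @param log2_fc True log2 fold change of the DE peaks.
#' @param sigma_log2 Log2-scale biological sd.
#' @param base_log2_range Range of baseline log2 intensities.
#' @param seed Integer seed.
#' @return List with `intensity` (samples x peaks), `group`, `mz`
#'   (synthetic 1-10 kDa positions), `is_de`, `fold_change`.
#' @export
simulate_peak_matrix <- function(n_cancer = 26L, n_normal = 14L,
                                 n_peaks = 287L, n_de = 48L, log2_fc = 1.6,
                                 sigma_log2 = 1.6,
                                 base_log2_range = c(3, 8), seed = 1L) {
  if (n_de > n_peaks) stop("'n_de' cannot exceed 'n_peaks'")
  with_seed(seed, {
    base <- stats::runif(n_peaks, base_log2_range[1L], base_log2_range[2L])
    is_de <- seq_len(n_peaks) <= n_de
    shift <- ifelse(is_de, log2_fc, 0)
    n <- n_cancer + n_normal
    group <- rep(c("cancer", "normal"), c(n_cancer, n_normal))
    logx <- matrix(stats::rnorm(n * n_peaks, 0, sigma_log2), n, n_peaks)
    logx <- sweep(logx, 2L, base, `+`)
    logx[group == "cancer", ] <-
      sweep(logx[group == "cancer", , drop = FALSE], 2L, shift, `+`)
    mz <- sort(stats::runif(n_peaks, 1000, 10000))
    list(intensity = 2^logx, group = group, mz = mz, is_de = is_de,
         fold_change = ifelse(is_de, 2^log2_fc, 1))
  })
}
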