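# Experiment harness: the three study designs exercised on synthetic data -
# SNR sweeps, sample-size subsampling, and stratified-vs-simple FDR control.

#' Standard experiment conditions for the synthetic cohorts
#'
#' The simulation configurations used by the packaged experiments. Both
#' scenarios share 30 true peaks spanning a wide dynamic range (heights
#' 2-60 over additive noise of sd 1.5, so the weakest peaks sit near the
#' single-spectrum noise floor and are only secure on the average spectrum)
#' and 8 DE peaks spread across the height order. Fold changes alternate
#' between up- and down-regulation (3x down to ~1.8x) so the differential
#' signal does not shift the total ion current of one group, and
#' low-abundance peaks carry the larger relative changes.
#'
#' `breast_like` is a small weak-signal cohort (26 cancer / 14 normal,
#' biological height CV 0.8): per-peak power is marginal, the regime where
#' the number of tests limits DE detection. `prostate_like` is a larger
#' strong-signal cohort (42 cancer / 21 normal, height CV 0.35) where power
#' saturates at the full sample size, the regime for the sample-size
#' subsampling experiment.
#'
#' @param seed Integer seed.
#' @param scenario `"breast_like"` or `"prostate_like"`.
#' @return A [sim_config()].
#' @export
standard_experiment_config <- function(seed = 1L,
                                       scenario = c("breast_like",
                                                    "prostate_like")) {
  scenario <- match.arg(scenario)
  fcs <- c(3, 1 / 3, 2.5, 0.4, 2.2, 0.45, 2, 0.55)
  if (scenario == "breast_like") {
    sim_config(n_cancer = 26L, n_normal = 14L, n_replicates = 2L,
               mz_range = c(1000, 10000), grid_step = 1, n_peaks = 30L,
               de_fraction = 8 / 30, fold_changes = fcs,
               peak_height_range = c(2, 60), noise_sd = 1.5,
               scale_sd = 0.15, mz_jitter_sd = 1.5, height_cv = 0.8,
               seed = seed)
  } else {
    sim_config(n_cancer = 42L, n_normal = 21L, n_replicates = 2L,
               mz_range = c(1000, 10000), grid_step = 1, n_peaks = 30L,
               de_fraction = 8 / 30, fold_changes = fcs,
               peak_height_range = c(2, 60), noise_sd = 1.5,
               scale_sd = 0.15, mz_jitter_sd = 1.5, height_cv = 0.35,
               seed = seed)
  }
}

#' Pre-process a dataset into a consensus peak profile
#'
#' Runs a preset over all spectra (detection on the grand average), averages
#' the duplicate-replicate rows into one consensus row per sample, and
#' optionally restricts the m/z range.
#'
#' @param spectra A `sim_dataset` or list of [mass_spectrum()].
#' @param preset,snr_threshold,... Passed to [run_preset()].
#' @param mz_range Optional closed m/z restriction `(low, high)`.
#' @return Consensus [peak_profile].
#' @export
preprocess_dataset <- function(spectra, preset, snr_threshold = NULL,
                               mz_range = NULL, ...) {
  if (inherits(spectra, "sim_dataset")) spectra <- spectra$spectra
  prof <- run_preset(spectra, preset, snr_threshold, ...)
  prof <- consensus_by_replicate(prof)
  if (!is.null(mz_range)) {
    prof <- restrict_mz_range(prof, mz_range[1L], mz_range[2L])
  }
  prof
}

#' SNR sweep: reproducibility of peak and DE peak detection
#'
#' For every preset and SNR value in its grid, builds the consensus profile
#' and its DE peak list, then scores peak-level and DE-level consistency
#' against every other preset held at its default (reference) SNR. Peak-level
#' nulls draw from the raw m/z grid; DE-level nulls draw direction-carrying
#' peaks from the two profiles.
#'
#' @param spectra A `sim_dataset` or list of spectra on one grid.
#' @param snr_grids Named list of SNR vectors per preset.
#' @param reference_snr Named vector of reference SNRs (preset defaults).
#' @param shift Matching window (default 0.003).
#' @param q_level FDR level for DE selection (default 0.10).
#' @param n_perm Permutation draws per consistency score.
#' @param seed Integer seed.
#' @return Data frame with one row per (preset, SNR, reference) triple:
#'   peak counts, DE counts, PO/nPO/p at peak and DE level.
#' @export
run_snr_sweep <- function(spectra,
                          snr_grids = list(
                            specalign_like = c(1.5, 4, 10),
                            mswpro_like = c(3, 6, 12),
                            cromwell_like = c(2, 5, 15, 40)),
                          reference_snr = preset_default_snr,
                          shift = 0.003, q_level = 0.10, n_perm = 200L,
                          seed = 1L) {
  if (inherits(spectra, "sim_dataset")) spectra <- spectra$spectra
  presets <- names(snr_grids)
  universe <- spectra[[1L]]$mz

  base <- lapply(presets, function(p) {
    run_preset(spectra, p, min(c(snr_grids[[p]], reference_snr[[p]])))
  })
  names(base) <- presets
  profile_at <- function(p, s) consensus_by_replicate(filter_snr(base[[p]], s))
  de_at <- function(prof) select_de(test_peaks(prof), q_level)

  refs <- lapply(presets, function(p) {
    prof <- profile_at(p, reference_snr[[p]])
    list(profile = prof, de = de_at(prof))
  })
  names(refs) <- presets

  rows <- list()
  for (p in presets) {
    for (s in sort(snr_grids[[p]], decreasing = TRUE)) {
      prof <- profile_at(p, s)
      de <- de_at(prof)
      de_mz <- de$mz[de$significant]
      de_dir <- de$direction[de$significant]
      for (q in presets) {
        # with a single preset the sweep degenerates to self-comparison
        if (q == p && length(presets) > 1L) next
        ref <- refs[[q]]
        rep_pk <- if (length(prof$peak_mz) && length(ref$profile$peak_mz)) {
          consistency_report(prof$peak_mz, ref$profile$peak_mz,
                             universe, universe, shift = shift,
                             n_perm = n_perm, seed = seed)
        } else NULL
        ref_de_mz <- ref$de$mz[ref$de$significant]
        ref_de_dir <- ref$de$direction[ref$de$significant]
        rep_de <- if (length(de_mz) && length(ref_de_mz)) {
          consistency_report(de_mz, ref_de_mz,
                             de$mz, ref$de$mz, shift = shift,
                             n_perm = n_perm, seed = seed,
                             dir_1 = de_dir, dir_2 = ref_de_dir,
                             dir_universe_1 = de$direction,
                             dir_universe_2 = ref$de$direction)
        } else NULL
        rows[[length(rows) + 1L]] <- data.frame(
          preset = p, snr = s, n_peaks = length(prof$peak_mz),
          n_de = length(de_mz), reference = q,
          ref_snr = reference_snr[[q]],
          ref_n_peaks = length(ref$profile$peak_mz),
          ref_n_de = length(ref_de_mz),
          po = if (is.null(rep_pk)) NA_real_ else rep_pk$po,
          n_po = if (is.null(rep_pk)) NA_real_ else rep_pk$n_po,
          p = if (is.null(rep_pk)) NA_real_ else rep_pk$p_value,
          po_de = if (is.null(rep_de)) NA_real_ else rep_de$po,
          n_po_de = if (is.null(rep_de)) NA_real_ else rep_de$n_po,
          p_de = if (is.null(rep_de)) NA_real_ else rep_de$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Sample-size subsampling: statistical power of DE peak detection
#'
#' At every sample size, draws `n_reps` random subsets with the cancer /
#' normal proportions of the full cohort held fixed, re-runs DE selection on
#' each profile, and averages the DE counts and the pairwise direction-aware
#' DE consistency scores.
#'
#' @param profiles Named list of consensus [peak_profile]s over the same
#'   samples (one per preset).
#' @param sizes Total sample sizes to draw.
#' @param n_reps Subsets per size (default 100).
#' @param q_level FDR level.
#' @param shift Matching window.
#' @param n_perm Permutation draws for nPO (kept modest; it enters only as
#'   a per-rep normalisation).
#' @param seed Integer seed.
#' @return List with `de_counts` (size x preset mean DE counts) and
#'   `consistency` (size x preset-pair mean PO/nPO over the reps where both
#'   DE lists were non-empty).
#' @export
run_subsample_power <- function(profiles, sizes = c(10, 16, 24, 32, 40),
                                n_reps = 100L, q_level = 0.10,
                                shift = 0.003, n_perm = 100L, seed = 1L) {
  stopifnot(length(profiles) >= 1L, !is.null(names(profiles)))
  first <- profiles[[1L]]
  ids <- first$sample_id
  grp <- first$group
  cancer <- ids[grp == "cancer"]; normal <- ids[grp == "normal"]
  frac_c <- length(cancer) / length(ids)
  presets <- names(profiles)
  pairs <- if (length(presets) > 1L) utils::combn(presets, 2L) else NULL

  with_seed(seed, {
    de_rows <- list(); co_rows <- list()
    for (size in sizes) {
      n_c <- round(size * frac_c); n_n <- size - n_c
      if (n_c < 2L || n_n < 2L || n_c > length(cancer) ||
          n_n > length(normal)) {
        warning(sprintf("size %d skipped: groups too small for the t-test",
                        size))
        next
      }
      nde <- matrix(0, n_reps, length(presets),
                    dimnames = list(NULL, presets))
      po <- array(NA_real_, c(n_reps, if (is.null(pairs)) 0L else
        ncol(pairs)))
      npo <- po
      for (r in seq_len(n_reps)) {
        keep_ids <- c(sample(cancer, n_c), sample(normal, n_n))
        des <- lapply(profiles, function(pr) {
          sub <- profile_select_rows(pr, pr$sample_id %in% keep_ids)
          select_de(test_peaks(sub), q_level)
        })
        nde[r, ] <- vapply(des, function(d) sum(d$significant), numeric(1L))
        if (!is.null(pairs)) {
          for (j in seq_len(ncol(pairs))) {
            d1 <- des[[pairs[1L, j]]]; d2 <- des[[pairs[2L, j]]]
            s1 <- d1$significant; s2 <- d2$significant
            if (any(s1) && any(s2)) {
              rep_de <- consistency_report(
                d1$mz[s1], d2$mz[s2], d1$mz, d2$mz, shift = shift,
                n_perm = n_perm, seed = seed + r,
                dir_1 = d1$direction[s1], dir_2 = d2$direction[s2],
                dir_universe_1 = d1$direction,
                dir_universe_2 = d2$direction)
              po[r, j] <- rep_de$po
              npo[r, j] <- rep_de$n_po
            }
          }
        }
      }
      de_rows[[length(de_rows) + 1L]] <- data.frame(
        size = size, preset = presets, mean_n_de = colMeans(nde),
        row.names = NULL, stringsAsFactors = FALSE)
      if (!is.null(pairs)) {
        co_rows[[length(co_rows) + 1L]] <- data.frame(
          size = size,
          pair = apply(pairs, 2L, paste, collapse = " vs "),
          mean_po_de = colMeans(po, na.rm = TRUE),
          mean_n_po_de = colMeans(npo, na.rm = TRUE),
          n_valid = colSums(!is.na(po)),
          row.names = NULL, stringsAsFactors = FALSE)
      }
    }
    list(de_counts = do.call(rbind, de_rows),
         consistency = do.call(rbind, co_rows))
  })
}

#' Compare simple and stratified FDR control on one DE table
#'
#' Scores the same tests under simple BH and under fold-change-stratified BH
#' at the same level; when the true DE peak positions are known, also
#' reports the empirical FDR and power of each mode (selected peaks matched
#' one-to-one to true DE m/z within the shift window).
#'
#' @param table A `de_table`, or a [peak_profile] (tested internally).
#' @param q_level FDR level (default 0.10).
#' @param config [stratified_config()] for the k-means step.
#' @param truth_de_mz Optional true DE peak m/z values.
#' @param shift Matching window for truth evaluation.
#' @return List with the two selected tables, DE counts, the chosen number
#'   of strata, and (with truth) empirical FDR / power per mode.
#' @export
run_stratified_comparison <- function(table, q_level = 0.10,
                                      config = stratified_config(
                                        q_level = q_level),
                                      truth_de_mz = NULL, shift = 0.003) {
  if (inherits(table, "peak_profile")) table <- test_peaks(table)
  simple <- select_de(table, q_level)
  strat_cl <- stratify_by_fc(table, config)
  strat <- stratified_select(table, strat_cl$assignment, q_level)
  out <- list(simple = simple, stratified = strat,
              n_de_simple = sum(simple$significant),
              n_de_stratified = sum(strat$significant),
              k_strata = strat_cl$k,
              stratum_sizes = as.integer(table(strat_cl$assignment)))
  if (!is.null(truth_de_mz)) {
    score <- function(sel) {
      mzs <- sort(sel$mz[sel$significant])
      n_sel <- length(mzs)
      k <- if (n_sel) match_peaks(sort(truth_de_mz), mzs, shift)$k else 0L
      list(fdr = if (n_sel) (n_sel - k) / n_sel else 0,
           power = k / length(truth_de_mz))
    }
    si <- score(simple); st <- score(strat)
    out$fdr_simple <- si$fdr; out$power_simple <- si$power
    out$fdr_stratified <- st$fdr; out$power_stratified <- st$power
  }
  out
}

#' Stratified-FDR calibration study on simulated p-value mixtures
#'
#' Repeatedly simulates a p-value mixture whose alternatives are
#' concentrated in one (known) stratum, applies simple BH and per-stratum
#' BH at the same level, and reports the Monte-Carlo FDR and power of both.
#'
#' @param n_reps Replicates (default 1000).
#' @param n_tests Tests per replicate.
#' @param pi0 Null fraction.
#' @param effect Alternative noncentrality.
#' @param strata_sizes Sizes of the strata; alternatives fill the first.
#' @param q_level FDR level.
#' @param seed Integer seed.
#' @return List with `fdr_simple`, `fdr_stratified`, `power_simple`,
#'   `power_stratified`, their Monte-Carlo standard errors, and `n_reps`.
#' @export
run_fdr_calibration <- function(n_reps = 1000L, n_tests = 500L, pi0 = 0.9,
                                effect = 3, strata_sizes = c(100L, 400L),
                                q_level = 0.10, seed = 1L) {
  if (sum(strata_sizes) != n_tests) {
    stop("'strata_sizes' must sum to 'n_tests'")
  }
  strata <- rep(seq_along(strata_sizes), strata_sizes)
  fdp <- matrix(0, n_reps, 2L); pow <- matrix(0, n_reps, 2L)
  for (r in seq_len(n_reps)) {
    sim <- simulate_pvalue_mixture(n_tests, pi0, effect,
                                   strata_assignment = strata,
                                   seed = seed + r)
    simple <- bh_select(sim$p_values, q_level)$significant
    strat <- logical(n_tests)
    for (s in unique(strata)) {
      rows <- strata == s
      strat[rows] <- bh_select(sim$p_values[rows], q_level)$significant
    }
    n_alt <- sum(sim$is_alternative)
    for (m in 1:2) {
      sel <- if (m == 1L) simple else strat
      fdp[r, m] <- if (any(sel)) sum(sel & !sim$is_alternative) / sum(sel)
        else 0
      pow[r, m] <- if (n_alt) sum(sel & sim$is_alternative) / n_alt else 0
    }
  }
  list(fdr_simple = mean(fdp[, 1L]), fdr_stratified = mean(fdp[, 2L]),
       power_simple = mean(pow[, 1L]), power_stratified = mean(pow[, 2L]),
       se_fdr_simple = stats::sd(fdp[, 1L]) / sqrt(n_reps),
       se_fdr_stratified = stats::sd(fdp[, 2L]) / sqrt(n_reps),
       n_reps = n_reps)
}

#' Reversal study: stratified FDR rescues power in a large profile
#'
#' Repeatedly generates a "large profile, few strong DE peaks, small
#' cohort" scenario (log-normal peak intensities, tests on the raw scale),
#' runs simple and stratified selection at the same level, and counts how
#' often the reversal pattern appears: simple BH selects nothing while the
#' stratified procedure selects at least one peak.
#'
#' @param n_scenarios Number of scenarios (default 200).
#' @param q_level FDR level.
#' @param seed Integer seed; scenario i uses seed + i.
#' @param n_cancer,n_normal,n_peaks,n_de,log2_fc,sigma_log2 Scenario shape,
#'   passed to [simulate_peak_matrix()].
#' @param config_fn Function(seed) giving the [stratified_config()] per
#'   scenario.
#' @return List with `pattern_rate`, mean DE counts under both modes, and
#'   the per-scenario count data frame.
#' @export
run_reversal_study <- function(n_scenarios = 200L, q_level = 0.10,
                               seed = 1L, n_cancer = 26L, n_normal = 14L,
                               n_peaks = 287L, n_de = 48L, log2_fc = 1.6,
                               sigma_log2 = 1.6,
                               config_fn = function(s) {
                                 stratified_config(q_level = q_level,
                                                   seed = s)
                               }) {
  res <- t(vapply(seq_len(n_scenarios), function(i) {
    s <- seed + i
    mat <- simulate_peak_matrix(n_cancer, n_normal, n_peaks, n_de,
                                log2_fc, sigma_log2, seed = s)
    table <- test_peaks(mat$intensity, labels = mat$group, mz = mat$mz)
    simple <- select_de(table, q_level)
    strat <- select_de(table, q_level, stratified = TRUE,
                       config = config_fn(s))
    c(n_simple = sum(simple$significant),
      n_stratified = sum(strat$significant))
  }, numeric(2L)))
  df <- as.data.frame(res)
  list(pattern_rate = mean(df$n_simple == 0 & df$n_stratified > 0),
       mean_n_simple = mean(df$n_simple),
       mean_n_stratified = mean(df$n_stratified),
       scenarios = df)
}
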