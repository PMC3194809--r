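# peakconcord

Reproducibility of peak and biomarker detection across SELDI-TOF MS
pre-processing algorithms.

Peak profiles extracted from the same set of mass spectra differ — often
dramatically — depending on which pre-processing algorithm produced them,
and lists of differentially expressed (DE) peaks inherit that
disagreement. `peakconcord` is a toolkit for studying this problem
quantitatively, aimed at computational proteomics researchers who want to
compare pre-processing choices, and at statisticians interested in
stratified multiple-testing procedures on peak data. It provides:

* **Three average-spectrum-dependent pre-processing presets** (peaks are
  detected once on the average of all spectra, then quantified per
  spectrum): a Savitzky–Golay / restrained-moving-average-baseline / TIC
  pipeline with FFT alignment (`specalign_like`, default SNR 1.5); a
  continuous-wavelet ridge-line detector with linear-interpolation
  baseline and median-AUC normalisation (`mswpro_like`, default SNR 3);
  and an undecimated-wavelet denoising / monotone-minimum-baseline
  pipeline (`cromwell_like`, default SNR 5).
* **Shift-window peak matching**: greedy one-to-one matching of peak
  lists within a relative m/z window (±0.3% by default), optionally
  direction-aware for DE lists.
* **DE selection**: per-peak Student t-tests, simple Benjamini–Hochberg
  step-up, and the fold-change-stratified variant — k-means on
  |log2 FC| with silhouette-selected k, then BH within each stratum.
* **PO/nPO consistency scores.** Lists of lengths l1 ≤ l2 sharing k
  peaks get PO = k / l1 (coverage of the shorter list), the permutation
  expectation E(PO) from random list pairs drawn from the two m/z
  universes, the normalised score nPO = (PO − E(PO)) / (1 − E(PO)), and
  an empirical permutation p-value.
* **A synthetic spectrum simulator** with exact ground truth (Gaussian
  peaks with m/z-proportional width, exponential baseline, per-spectrum
  scale and m/z jitter, duplicate technical replicates, designated DE
  peaks) plus matrix- and p-value-level generators, so every stage is
  testable without any external dataset.
* **Experiment harnesses**: SNR sweeps, sample-size subsampling with
  group proportions held fixed, FDR-calibration and power-reversal
  studies (`run_snr_sweep`, `run_subsample_power`,
  `run_fdr_calibration`, `run_reversal_study`).

## Worked example

Simulate the standard weak-signal cohort (26 cancer / 14 normal plasma
samples, duplicate spectra, 30 true peaks of which 8 are DE), build the
three consensus profiles, select DE peaks at a 10% FDR, and score the
DE-level agreement between the smallest and the largest profile:

```r
library(peakconcord)

ds <- simulate_dataset(standard_experiment_config(seed = 1))
profiles <- lapply(
  c(specalign = "specalign_like", mswpro = "mswpro_like",
    cromwell = "cromwell_like"),
  function(p) preprocess_dataset(ds, p))
sapply(profiles, function(p) length(p$peak_mz))
#> specalign    mswpro  cromwell
#>        33        37        72

de <- lapply(profiles, function(p) select_de(test_peaks(p), q_level = 0.10))
sapply(de, function(d) sum(d$significant))
#> specalign    mswpro  cromwell
#>         6         7        10

a <- de$specalign; b <- de$cromwell
consistency_report(
  a$mz[a$significant], b$mz[b$significant], a$mz, b$mz,
  shift = 0.003, n_perm = 1000, seed = 1,
  dir_1 = a$direction[a$significant], dir_2 = b$direction[b$significant],
  dir_universe_1 = a$direction, dir_universe_2 = b$direction)
#> <consistency_report> [direction-aware] l1 = 6, l2 = 10, k = 5
#>   PO = 0.833, E(PO) = 0.121, nPO = 0.810, p = 0 (1000 draws, shift +/-0.3%)
```

Reading the output: the three presets report 33, 37 and 72 peaks from the
same 80 spectra — the wavelet-denoising preset is by far the most
permissive. Of the 6 DE peaks found in the smallest profile, 5 are also
declared DE (with the same regulation direction, within ±0.3% m/z) in the
largest profile's 10-peak list, giving PO = 0.833; random 6- and 10-peak
lists drawn from the two profiles would overlap with expectation 0.121,
so the normalised score is 0.810 and no permutation draw reached the
observed overlap (p below the 1/1000 resolution).

The methods vignette (`vignettes/peakconcord-methods.Rmd`) documents the
presets, the score definitions, the stratified-FDR procedure, the
simulator's assumptions, and the study conditions behind every packaged
experiment.

A thin command-line front end is installed at `inst/cli/peakconcord`
(subcommands `simulate`, `preprocess`, `de`, `consistency`).

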