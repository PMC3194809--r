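# Plain-text serialisation. All numeric fields are written with "%.17g" so
# doubles survive a write/read cycle bit-identically.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a simulated dataset as per-spectrum CSV files plus a manifest
#'
#' Each spectrum becomes a two-column CSV (`mz`, `intensity`); the manifest
#' TSV lists `file`, `sample_id`, `replicate`, `group`. The ground truth is
#' written as `truth.csv` (`mz`, `is_de`, `fold_change`).
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()], or a list of
#'   [mass_spectrum()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_spectra <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spectra <- if (inherits(dataset, "sim_dataset")) dataset$spectra else
    dataset
  rows <- lapply(spectra, function(sp) {
    file <- sprintf("%s_r%s.csv", sp$sample_id, as.character(sp$replicate_id))
    utils::write.csv(
      data.frame(mz = fmt_num(sp$mz), intensity = fmt_num(sp$intensity)),
      file.path(dir, file), row.names = FALSE, quote = FALSE)
    data.frame(file = file, sample_id = sp$sample_id,
               replicate = sp$replicate_id, group = sp$group,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (inherits(dataset, "sim_dataset")) {
    tr <- dataset$truth$truth
    utils::write.csv(
      data.frame(mz = fmt_num(tr$mz), is_de = tr$is_de,
                 fold_change = fmt_num(tr$fold_change)),
      file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read spectra written by [write_spectra()]
#'
#' @param dir Directory containing the manifest and spectrum CSV files.
#' @param manifest Manifest file name.
#' @return List of [mass_spectrum()] objects.
#' @export
read_spectra <- function(dir, manifest = "manifest.tsv") {
  man <- utils::read.table(file.path(dir, manifest), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    d <- utils::read.csv(file.path(dir, man$file[i]))
    mass_spectrum(as.numeric(d$mz), as.numeric(d$intensity),
                  sample_id = man$sample_id[i],
                  replicate_id = man$replicate[i], group = man$group[i])
  })
}

#' Write a peak profile as CSV plus a JSON side-car
#'
#' The CSV holds one row per spectrum (first columns `sample_id`,
#' `replicate`, `group`; remaining columns the peak m/z values); the JSON
#' side-car carries the provenance (preset, SNR threshold, per-peak SNR) and
#' the detection intervals.
#'
#' @param profile A [peak_profile].
#' @param csv_path,json_path Output paths; `json_path` defaults to the CSV
#'   path with a `.json` extension.
#' @return `csv_path`, invisibly.
#' @export
write_peak_profile <- function(profile, csv_path,
                               json_path = sub("\\.csv$", ".json",
                                               csv_path)) {
  mat <- profile$intensity
  df <- data.frame(sample_id = profile$sample_id,
                   replicate = as.character(profile$replicate_id),
                   group = profile$group, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) {
    df[[fmt_num(profile$peak_mz[j])]] <- fmt_num(mat[, j])
  }
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  side <- list(preset = profile$preset,
               snr_threshold = profile$snr_threshold,
               peak_mz = fmt_num(profile$peak_mz),
               intervals_left = profile$intervals[, 1L],
               intervals_right = profile$intervals[, 2L],
               peak_snr = if (is.null(profile$peak_snr)) NULL else
                 fmt_num(profile$peak_snr))
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(csv_path)
}

#' Read a peak profile written by [write_peak_profile()]
#'
#' @param csv_path,json_path Paths used by [write_peak_profile()].
#' @return A [peak_profile].
#' @export
read_peak_profile <- function(csv_path,
                              json_path = sub("\\.csv$", ".json",
                                              csv_path)) {
  df <- utils::read.csv(csv_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  peak_mz <- as.numeric(side$peak_mz)
  mat <- as.matrix(df[, -(1:3), drop = FALSE])
  mode(mat) <- "numeric"
  new_peak_profile(
    peak_mz = peak_mz,
    intervals = cbind(left = as.integer(side$intervals_left),
                      right = as.integer(side$intervals_right)),
    intensity = mat, sample_id = df$sample_id,
    replicate_id = df$replicate, group = df$group,
    preset = side$preset, snr_threshold = as.numeric(side$snr_threshold),
    peak_snr = if (is.null(side$peak_snr)) NULL else
      as.numeric(side$peak_snr))
}

#' Write / read a DE table as CSV
#'
#' @param table A `de_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(table, path) {
  df <- data.frame(mz = fmt_num(table$mz), t_stat = fmt_num(table$t_stat),
                   p_value = fmt_num(table$p_value), fc = fmt_num(table$fc),
                   direction = table$direction, stratum = table$stratum,
                   significant = table$significant,
                   q_level = fmt_num(table$q_level),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(mz = as.numeric(df$mz), t_stat = as.numeric(df$t_stat),
                    p_value = as.numeric(df$p_value), fc = as.numeric(df$fc),
                    direction = df$direction, stratum = df$stratum,
                    significant = df$significant,
                    q_level = as.numeric(df$q_level))
  class(out) <- c("de_table", "data.frame")
  out
}

#' Write / read a consistency report as JSON
#'
#' @param report A `consistency_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consistency_report <- function(report, path) {
  x <- unclass(report)
  for (f in c("po", "e_po", "n_po", "p_value", "shift")) {
    x[[f]] <- fmt_num(x[[f]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_consistency_report
#' @export
read_consistency_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("po", "e_po", "n_po", "p_value", "shift")) {
    x[[f]] <- as.numeric(x[[f]])
  }
  for (f in c("l1", "l2", "k", "n_perm", "seed")) {
    x[[f]] <- as.integer(x[[f]])
  }
  structure(x, class = "consistency_report")
}
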