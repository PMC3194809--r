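#' Construct a mass spectrum
#'
#' A spectrum is a pair of equal-length vectors: a strictly increasing m/z
#' axis (Daltons) and the corresponding intensities, plus the sample
#' bookkeeping carried through pre-processing (sample id, technical
#' replicate id, group label).
#'
#' @param mz Numeric vector of m/z values (Da), strictly increasing.
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @param sample_id Sample identifier.
#' @param replicate_id Technical replicate identifier (e.g. 1 or 2).
#' @param group Group label, conventionally `"cancer"` or `"normal"`.
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, sample_id = NA_character_,
                          replicate_id = NA_integer_, group = NA_character_) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) < 2L) stop("a spectrum needs at least 2 points")
  if (length(mz) != length(intensity)) {
    stop("'mz' and 'intensity' must have the same length")
  }
  if (any(diff(mz) <= 0)) stop("'mz' must be strictly increasing")
  if (anyNA(intensity)) stop("'intensity' must not contain NA")
  structure(
    list(mz = mz, intensity = intensity,
         sample_id = as.character(sample_id),
         replicate_id = replicate_id, group = as.character(group)),
    class = "mass_spectrum"
  )
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf(
    "<mass_spectrum> %d points, m/z %.6g-%.6g Da, sample=%s rep=%s group=%s\n",
    length(x$mz), min(x$mz), max(x$mz), x$sample_id,
    as.character(x$replicate_id), x$group))
  invisible(x)
}

# Replace the intensity of a spectrum, keeping metadata.
set_intensity <- function(sp, y) {
  sp$intensity <- as.numeric(y)
  sp
}

# TRUE when all spectra share one m/z grid (exact equality up to tiny fp slop).
same_grid <- function(spectra) {
  ref <- spectra[[1L]]$mz
  all(vapply(spectra, function(s) {
    length(s$mz) == length(ref) && max(abs(s$mz - ref)) <= 1e-9 * max(abs(ref))
  }, logical(1L)))
}

spectrum_label <- function(sp) {
  sprintf("%s/r%s", sp$sample_id, as.character(sp$replicate_id))
}

#' Pointwise average spectrum
#'
#' Averages a set of spectra that share an identical m/z grid. No implicit
#' resampling is performed: mismatched grids are an error.
#'
#' @param spectra List of [mass_spectrum()] objects on one common grid.
#' @return A `mass_spectrum` whose intensity is the pointwise mean.
#' @export
average_spectrum <- function(spectra) {
  if (!length(spectra)) stop("no spectra to average")
  if (!same_grid(spectra)) {
    stop("spectra are not on a common m/z grid; resample before averaging")
  }
  y <- rowMeans(vapply(spectra, `[[`, numeric(length(spectra[[1L]]$mz)),
                       "intensity"))
  mass_spectrum(spectra[[1L]]$mz, y, sample_id = "average",
                replicate_id = NA_integer_, group = NA_character_)
}
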