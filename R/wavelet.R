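# Undecimated (stationary) wavelet transform via the a-trous scheme with the
# B3-spline scaling kernel [1,4,6,4,1]/16. The decomposition is additive:
# y = smooth + sum(details), so reconstruction after thresholding is a plain
# sum and the threshold-0 transform is an exact identity.

# One a-trous smoothing pass with holes of size `step`; reflected boundaries.
atrous_smooth <- function(y, step) {
  n <- length(y)
  kern <- c(1, 4, 6, 4, 1) / 16
  offs <- c(-2L, -1L, 0L, 1L, 2L) * step
  out <- numeric(n)
  idx0 <- seq_len(n)
  for (k in seq_along(offs)) {
    idx <- idx0 + offs[k]
    # reflect indices around the edges
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    out <- out + kern[k] * y[idx]
  }
  out
}

#' Undecimated discrete wavelet decomposition
#'
#' Additive a-trous decomposition of a signal into `levels` detail bands and
#' a residual smooth, each the same length as the input. The finest detail
#' band carries essentially the measurement noise and is the basis of the
#' noise-scale estimate used by SNR thresholds.
#'
#' @param y Numeric signal.
#' @param levels Number of decomposition levels; must satisfy
#'   `2^levels <= length(y)`.
#' @return List with `details` (list of numeric vectors, finest first) and
#'   `smooth`.
#' @export
udwt <- function(y, levels = 6L) {
  n <- length(y)
  if (!is_count(levels) || 2^levels > n) {
    stop("'levels' must be a positive integer with 2^levels <= length(y)")
  }
  cj <- as.numeric(y)
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    cnext <- atrous_smooth(cj, 2L^(j - 1L))
    details[[j]] <- cj - cnext
    cj <- cnext
  }
  list(details = details, smooth = cj)
}

# Robust noise scale: 1.4826 * median absolute deviation of the finest-level
# detail coefficients (stats::mad applies the 1.4826 factor).
noise_mad <- function(y) {
  stats::mad(udwt(y, levels = 1L)$details[[1L]], center = 0)
}

#' Denoise a signal by hard-thresholding its undecimated wavelet details
#'
#' Detail coefficients smaller in magnitude than `k` times the robust noise
#' scale of the finest band are zeroed; the signal is rebuilt by summation.
#' With `k = 0` the input is returned unchanged (perfect reconstruction).
#'
#' @param y Numeric signal.
#' @param levels Decomposition depth.
#' @param k Threshold in noise-sd units (default 3).
#' @return Denoised numeric vector, same length as `y`.
#' @export
udwt_denoise <- function(y, levels = 6L, k = 3) {
  if (k < 0) stop("'k' must be non-negative")
  dec <- udwt(y, levels)
  if (k > 0) {
    sigma <- stats::mad(dec$details[[1L]], center = 0)
    thr <- k * sigma
    dec$details <- lapply(dec$details, function(w) ifelse(abs(w) < thr, 0, w))
  }
  dec$smooth + Reduce(`+`, dec$details)
}
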