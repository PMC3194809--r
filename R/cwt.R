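# Continuous wavelet transform peak picking (Mexican-hat, ridge lines),
# following the published defaults of wavelet-based MS peak detectors:
# 12 dyadically spaced scales, ridge gap tolerance 2, minimum ridge length 6.

# Mexican-hat CWT coefficients, one column per scale; FFT convolution with
# zero padding.
mexhat_cwt <- function(y, scales) {
  n <- length(y)
  coefs <- matrix(0, n, length(scales))
  for (j in seq_along(scales)) {
    a <- scales[j]
    half <- max(1L, ceiling(8 * a))
    t <- seq.int(-half, half) / a
    psi <- (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2)
    psi <- psi / sqrt(a)
    m <- length(psi)
    nf <- stats::nextn(n + m, 2L)
    conv <- Re(stats::fft(stats::fft(c(y, numeric(nf - n))) *
                            stats::fft(c(psi, numeric(nf - m))),
                          inverse = TRUE)) / nf
    coefs[, j] <- conv[(half + 1L):(half + n)]
  }
  coefs
}

local_maxima_idx <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0L))
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
}

# Link per-scale local maxima of the coefficient matrix into ridge lines,
# walking from the coarsest scale down; returns candidate peak indices.
cwt_ridge_peaks <- function(coefs, scales, gap_tol = 2L, min_length = 6L,
                            snr_threshold = 3, sigma = NULL,
                            min_peak_scale = 3) {
  n <- nrow(coefs); ns <- length(scales)
  maxima <- lapply(seq_len(ns), function(j) local_maxima_idx(coefs[, j]))
  # active ridges: list of (positions per scale, gap count)
  ridges <- list()
  done <- list()
  for (j in rev(seq_len(ns))) {        # coarse -> fine
    win <- max(2L, ceiling(scales[j]))
    avail <- maxima[[j]]
    used <- logical(length(avail))
    if (length(ridges)) {
      for (r in seq_along(ridges)) {
        rd <- ridges[[r]]
        if (rd$dead) next
        if (length(avail)) {
          d <- abs(avail - rd$pos)
          cand <- which(d <= win & !used)
          if (length(cand)) {
            pick <- cand[which.min(d[cand])]
            used[pick] <- TRUE
            rd$pos <- avail[pick]
            rd$len <- rd$len + 1L
            rd$gap <- 0L
            rd$scale_idx <- j
            best <- coefs[avail[pick], j]
            if (best > rd$max_coef) {
              rd$max_coef <- best
              rd$max_pos <- avail[pick]
              rd$max_scale <- scales[j]
            }
            ridges[[r]] <- rd
            next
          }
        }
        rd$gap <- rd$gap + 1L
        if (rd$gap > gap_tol) rd$dead <- TRUE
        ridges[[r]] <- rd
      }
    }
    if (length(avail)) {
      for (p in avail[!used]) {
        ridges[[length(ridges) + 1L]] <-
          list(pos = p, len = 1L, gap = 0L, dead = FALSE, scale_idx = j,
               max_coef = coefs[p, j], max_pos = p, max_scale = scales[j])
      }
    }
  }
  if (is.null(sigma)) sigma <- stats::mad(coefs[, 1L], center = 0)
  keep <- Filter(function(rd) {
    rd$len >= min_length && rd$scale_idx <= 3L &&
      rd$max_scale >= min_peak_scale &&  # noise ridges peak at fine scales
      (if (sigma > 0) rd$max_coef / sigma >= snr_threshold else
         rd$max_coef > 0)
  }, ridges)
  if (!length(keep)) {
    return(data.frame(idx = integer(0L), snr = numeric(0L)))
  }
  idx <- as.integer(round(vapply(keep, `[[`, numeric(1L), "max_pos")))
  snr <- vapply(keep, function(rd) {
    if (sigma > 0) rd$max_coef / sigma else Inf
  }, numeric(1L))
  # one entry per position, keeping the strongest ridge
  ord <- order(idx, -snr)
  idx <- idx[ord]; snr <- snr[ord]
  first <- !duplicated(idx)
  data.frame(idx = idx[first], snr = snr[first])
}
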