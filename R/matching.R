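#' Match two peak lists within a relative m/z window
#'
#' Two peaks may represent the same molecule when their m/z difference is
#' within a relative shift window (commonly +/-0.3%). Matching is greedy and
#' one-to-one: candidate pairs with `|mzA - mzB| <= shift * mzA` (the window
#' is anchored on list A) are accepted in order of increasing relative
#' distance, skipping peaks already matched. When directions are supplied
#' (DE peak lists), a pair is only a candidate if both peaks are regulated in
#' the same direction; peaks with direction `"none"` never match.
#'
#' @param list_a,list_b Sorted numeric m/z vectors (Da).
#' @param shift Positive relative window (0.001-0.003 typical).
#' @param dir_a,dir_b Optional direction labels (`"up"`/`"down"`/`"none"`),
#'   one per peak.
#' @return A `match_result`: `pairs` (two-column index matrix), `k` (number
#'   of pairs), `shift`, `unmatched_a`, `unmatched_b`.
#' @export
match_peaks <- function(list_a, list_b, shift, dir_a = NULL, dir_b = NULL) {
  if (shift < 0) stop("'shift' must be non-negative")
  na <- length(list_a); nb <- length(list_b)
  empty <- matrix(integer(0L), 0L, 2L, dimnames = list(NULL, c("a", "b")))
  if (na == 0L || nb == 0L) {
    return(structure(list(pairs = empty, k = 0L, shift = shift,
                          unmatched_a = seq_len(na),
                          unmatched_b = seq_len(nb)),
                     class = "match_result"))
  }
  # candidate pairs via interval search on the sorted lists
  eps <- 1e-12
  lo <- findInterval(list_a * (1 - shift) - eps, list_b) + 1L
  hi <- findInterval(list_a * (1 + shift) + eps, list_b)
  counts <- pmax(hi - lo + 1L, 0L)
  ci <- rep.int(seq_len(na), counts)
  cj <- unlist(lapply(which(counts > 0L), function(i) lo[i]:hi[i]),
               use.names = FALSE)
  if (length(ci)) {
    keep <- abs(list_a[ci] - list_b[cj]) <= shift * list_a[ci] + eps
    ci <- ci[keep]; cj <- cj[keep]
  }
  if (length(ci) && !is.null(dir_a)) {
    agree <- dir_a[ci] == dir_b[cj] & dir_a[ci] != "none"
    ci <- ci[agree]; cj <- cj[agree]
  }
  if (!length(ci)) {
    return(structure(list(pairs = empty, k = 0L, shift = shift,
                          unmatched_a = seq_len(na),
                          unmatched_b = seq_len(nb)),
                     class = "match_result"))
  }
  rel <- abs(list_a[ci] - list_b[cj]) / list_a[ci]
  ord <- order(rel, ci, cj)
  ci <- ci[ord]; cj <- cj[ord]
  used_a <- logical(na); used_b <- logical(nb)
  pairs <- matrix(NA_integer_, min(na, nb), 2L)
  np <- 0L
  for (r in seq_along(ci)) {
    i <- ci[r]; j <- cj[r]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      np <- np + 1L
      pairs[np, ] <- c(i, j)
    }
  }
  pairs <- pairs[seq_len(np), , drop = FALSE]
  colnames(pairs) <- c("a", "b")
  structure(list(pairs = pairs, k = nrow(pairs), shift = shift,
                 unmatched_a = which(!used_a), unmatched_b = which(!used_b)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> k = %d shared peaks (shift +/-%.2g%%), %d/%d unmatched\n",
              x$k, 100 * x$shift, length(x$unmatched_a),
              length(x$unmatched_b)))
  invisible(x)
}

#' Average duplicate-replicate profiles into a consensus profile
#'
#' Duplicate technical spectra are pre-processed separately (one profile per
#' replicate, same detection run) and then averaged peak-wise to produce one
#' consensus intensity row per biological sample.
#'
#' @param profile_rep1,profile_rep2 [peak_profile] objects with identical
#'   peak sets and the same biological samples.
#' @return Consensus [peak_profile], one row per sample.
#' @export
consensus_profile <- function(profile_rep1, profile_rep2) {
  if (length(profile_rep1$peak_mz) != length(profile_rep2$peak_mz) ||
      (length(profile_rep1$peak_mz) &&
       max(abs(profile_rep1$peak_mz - profile_rep2$peak_mz)) > 1e-9)) {
    stop("replicate profiles carry different peak sets")
  }
  o1 <- order(profile_rep1$sample_id)
  o2 <- order(profile_rep2$sample_id)
  if (!identical(profile_rep1$sample_id[o1], profile_rep2$sample_id[o2])) {
    stop("replicate profiles cover different samples")
  }
  new_peak_profile(
    peak_mz = profile_rep1$peak_mz, intervals = profile_rep1$intervals,
    intensity = (profile_rep1$intensity[o1, , drop = FALSE] +
                   profile_rep2$intensity[o2, , drop = FALSE]) / 2,
    sample_id = profile_rep1$sample_id[o1],
    replicate_id = rep("consensus", length(o1)),
    group = profile_rep1$group[o1], preset = profile_rep1$preset,
    snr_threshold = profile_rep1$snr_threshold,
    peak_snr = profile_rep1$peak_snr)
}

# Split a per-spectrum profile by replicate and average into the consensus.
consensus_by_replicate <- function(profile) {
  reps <- sort(unique(profile$replicate_id))
  if (length(reps) == 1L) return(profile)
  if (length(reps) != 2L) {
    stop("consensus averaging expects duplicate spectra (2 replicates)")
  }
  consensus_profile(
    profile_select_rows(profile, profile$replicate_id == reps[1L]),
    profile_select_rows(profile, profile$replicate_id == reps[2L]))
}

#' Restrict a peak profile to an m/z range
#'
#' Keeps peaks with `low <= mz <= high` (closed interval); intensity columns
#' are dropped consistently. An empty result is permitted (with a warning).
#'
#' @param profile A [peak_profile].
#' @param low,high Range bounds in Da, `low < high`.
#' @return Restricted [peak_profile].
#' @export
restrict_mz_range <- function(profile, low, high) {
  if (low >= high) stop("'low' must be below 'high'")
  keep <- profile$peak_mz >= low & profile$peak_mz <= high
  if (!any(keep)) {
    warning(sprintf("no peaks left in m/z range [%g, %g]", low, high))
  }
  profile_select_peaks(profile, keep)
}
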