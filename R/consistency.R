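#' Percentage-of-overlap score between two peak lists
#'
#' With lists of length l1 and l2 sharing k peaks (shift-window matching,
#' optionally direction-aware for DE lists), the PO score from list 1 to
#' list 2 is k/l1. Scores are reported from the shorter list to the longer
#' one: the roles are swapped if needed so the score measures how well the
#' shorter list is covered.
#'
#' @param list_1,list_2 Sorted numeric m/z vectors.
#' @param shift Relative matching window.
#' @param dir_1,dir_2 Optional direction labels (one per peak); shared DE
#'   peaks must agree in direction.
#' @return List with `k`, `po`, `l1`, `l2` (after the shorter-first swap)
#'   and `swapped`.
#' @export
po_score <- function(list_1, list_2, shift = 0.003,
                     dir_1 = NULL, dir_2 = NULL) {
  if (shift <= 0) stop("'shift' must be positive")
  if (length(list_1) == 0L || length(list_2) == 0L) {
    stop("PO is undefined for an empty peak list")
  }
  swapped <- length(list_2) < length(list_1)
  if (swapped) {
    tmp <- list_1; list_1 <- list_2; list_2 <- tmp
    tmpd <- dir_1; dir_1 <- dir_2; dir_2 <- tmpd
  }
  k <- match_peaks(list_1, list_2, shift, dir_a = dir_1, dir_b = dir_2)$k
  list(k = k, po = k / length(list_1),
       l1 = length(list_1), l2 = length(list_2), swapped = swapped)
}

#' Permutation null distribution of the PO score
#'
#' Draws `n_perm` pairs of random peak lists (lengths l1 and l2, sampled
#' without replacement from the two m/z universes - the raw m/z lists for
#' peak-level scores, the profiles' peak lists for DE-level scores), scores
#' each pair, and returns the mean as the chance expectation E(PO). In
#' direction-aware mode each drawn peak carries its observed direction.
#'
#' @param universe_1,universe_2 m/z universes to draw from.
#' @param l1,l2 List lengths (l1 <= l2 after the shorter-first convention).
#' @param shift Relative matching window.
#' @param n_perm Number of draws (default 1000).
#' @param seed Integer seed.
#' @param dir_universe_1,dir_universe_2 Optional directions carried by the
#'   universe peaks.
#' @return List with `e_po` and `po_null` (the `n_perm` null scores).
#' @export
null_distribution <- function(universe_1, universe_2, l1, l2, shift = 0.003,
                              n_perm = 1000L, seed = 1L,
                              dir_universe_1 = NULL,
                              dir_universe_2 = NULL) {
  if (n_perm < 1L) stop("'n_perm' must be at least 1")
  if (l1 > length(universe_1) || l2 > length(universe_2)) {
    stop("list lengths exceed the universes")
  }
  lo <- min(l1, l2)
  with_seed(seed, {
    po_null <- vapply(seq_len(n_perm), function(i) {
      i1 <- sort(sample.int(length(universe_1), l1))
      i2 <- sort(sample.int(length(universe_2), l2))
      match_peaks(universe_1[i1], universe_2[i2], shift,
                  dir_a = dir_universe_1[i1],
                  dir_b = dir_universe_2[i2])$k / lo
    }, numeric(1L))
    list(e_po = mean(po_null), po_null = po_null)
  })
}

#' Consistency report for a pair of peak lists
#'
#' Combines the observed PO score (shorter list to longer), its permutation
#' expectation E(PO), the normalised score nPO = (PO - E(PO))/(1 - E(PO)) -
#' the fraction of the maximum possible beyond-chance overlap attained - and
#' the permutation p-value, the proportion of null scores not less than the
#' observed one (plain empirical proportion; resolution floor 1/n_perm).
#'
#' @param list_1,list_2 Observed peak lists (m/z).
#' @param universe_1,universe_2 Universes the null lists are drawn from,
#'   in the same order as `list_1`/`list_2`.
#' @param shift Relative matching window (default 0.003).
#' @param n_perm Permutation draws (default 1000).
#' @param seed Integer seed.
#' @param dir_1,dir_2 Optional directions for the observed DE lists.
#' @param dir_universe_1,dir_universe_2 Directions carried by the universe
#'   peaks (direction-aware nulls).
#' @return A `consistency_report` object.
#' @export
consistency_report <- function(list_1, list_2, universe_1, universe_2,
                               shift = 0.003, n_perm = 1000L, seed = 1L,
                               dir_1 = NULL, dir_2 = NULL,
                               dir_universe_1 = NULL,
                               dir_universe_2 = NULL) {
  obs <- po_score(list_1, list_2, shift, dir_1, dir_2)
  if (obs$swapped) {
    tmp <- universe_1; universe_1 <- universe_2; universe_2 <- tmp
    tmpd <- dir_universe_1; dir_universe_1 <- dir_universe_2
    dir_universe_2 <- tmpd
  }
  nul <- null_distribution(universe_1, universe_2, obs$l1, obs$l2, shift,
                           n_perm = n_perm, seed = seed,
                           dir_universe_1 = dir_universe_1,
                           dir_universe_2 = dir_universe_2)
  e_po <- nul$e_po
  n_po <- if (e_po >= 1) {
    warning("degenerate universes: E(PO) = 1; nPO reported as 1")
    1
  } else {
    (obs$po - e_po) / (1 - e_po)
  }
  p_value <- mean(nul$po_null >= obs$po - 1e-12)
  structure(list(l1 = obs$l1, l2 = obs$l2, k = obs$k, po = obs$po,
                 e_po = e_po, n_po = n_po, p_value = p_value,
                 n_perm = as.integer(n_perm),
                 direction_aware = !is.null(dir_1), shift = shift,
                 seed = as.integer(seed)),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "<consistency_report>%s l1 = %d, l2 = %d, k = %d\n  PO = %.3f, E(PO) = %.3f, nPO = %.3f, p = %s (%d draws, shift +/-%.2g%%)\n",
    if (x$direction_aware) " [direction-aware]" else "",
    x$l1, x$l2, x$k, x$po, x$e_po, x$n_po,
    format(x$p_value), x$n_perm, 100 * x$shift))
  invisible(x)
}
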