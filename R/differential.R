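#' Per-peak two-group differential expression tests
#'
#' Equal-variance (Student's) two-sample t-test for each peak of a profile,
#' comparing the intensity means of the case (cancer) and control (normal)
#' samples, with the fold change defined as mean(case)/mean(control).
#' Direction is `"up"` for fold change above 1, `"down"` below 1, and the
#' sentinel `"none"` at exactly 1 (such a peak can never count as a shared
#' DE peak). A peak with zero pooled variance gets p = 1 when the group
#' means are equal and the smallest representable positive p otherwise
#' (logged).
#'
#' @param profile A [peak_profile] (typically the consensus profile), or a
#'   plain samples x peaks matrix.
#' @param labels Group label per row; taken from the profile when omitted.
#' @param case,control Label values for the two groups.
#' @param log2_transform Test log2-transformed intensities instead of raw
#'   ones (all intensities must then be positive). The fold change is always
#'   computed from the raw group means.
#' @param mz Peak m/z values when `profile` is a bare matrix.
#' @return A `de_table` data frame with columns `mz`, `t_stat`, `p_value`,
#'   `fc`, `direction`, `stratum`, `significant`, `q_level`.
#' @export
test_peaks <- function(profile, labels = NULL, case = "cancer",
                       control = "normal", log2_transform = FALSE,
                       mz = NULL) {
  if (inherits(profile, "peak_profile")) {
    x <- profile$intensity
    if (is.null(labels)) labels <- profile$group
    mz <- profile$peak_mz
  } else {
    x <- as.matrix(profile)
    if (is.null(mz)) mz <- seq_len(ncol(x))
  }
  i1 <- which(labels == case); i2 <- which(labels == control)
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("both groups need at least 2 samples")
  }
  m1r <- colMeans(x[i1, , drop = FALSE])
  m2r <- colMeans(x[i2, , drop = FALSE])
  xt <- if (log2_transform) {
    if (any(x <= 0)) stop("log2 transform requires positive intensities")
    log2(x)
  } else x
  n1 <- length(i1); n2 <- length(i2); df <- n1 + n2 - 2L
  m1 <- colMeans(xt[i1, , drop = FALSE])
  m2 <- colMeans(xt[i2, , drop = FALSE])
  v1 <- apply(xt[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(xt[i2, , drop = FALSE], 2L, stats::var)
  sp <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
  se <- sqrt(sp * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- which(se == 0)
  if (length(degen)) {
    pc_log("de", "%d peak(s) with zero pooled variance", length(degen))
    eq <- m1[degen] == m2[degen]
    tt[degen] <- ifelse(eq, 0, sign(m1[degen] - m2[degen]) * Inf)
    p[degen] <- ifelse(eq, 1, .Machine$double.xmin)
  }
  fc <- ifelse(m2r == 0, ifelse(m1r == 0, 1, Inf), m1r / m2r)
  direction <- ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none"))
  out <- data.frame(mz = mz, t_stat = tt, p_value = p, fc = fc,
                    direction = direction, stratum = 1L,
                    significant = FALSE, q_level = NA_real_,
                    row.names = NULL)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up selection
#'
#' Finds the largest i with `p_(i) <= i * q / m` and declares every p-value
#' at or below that order statistic significant. Returns the realized
#' cutoff (`p_(i)`, or 0 when nothing is selected).
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param q_level Target FDR level.
#' @return List with `significant` (logical), `cutoff`, `n_selected`.
#' @export
bh_select <- function(p_values, q_level) {
  stopifnot_scalar_prob(q_level, "q_level")
  m <- length(p_values)
  if (m == 0L) {
    return(list(significant = logical(0L), cutoff = 0, n_selected = 0L))
  }
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * q_level / m)
  cutoff <- if (length(ok)) ps[max(ok)] else 0
  sig <- if (length(ok)) p_values <= cutoff else rep(FALSE, m)
  list(significant = sig, cutoff = cutoff, n_selected = sum(sig))
}

#' Configuration for stratified FDR control
#'
#' @param q_level FDR level (default 0.10).
#' @param k_range Candidate numbers of strata for the k-means step.
#' @param n_restarts Seeded k-means restarts per k (default 25).
#' @param seed Integer seed for the restarts.
#' @return A `stratified_config` list.
#' @export
stratified_config <- function(q_level = 0.10, k_range = 2:10,
                              n_restarts = 25L, seed = 1L) {
  stopifnot_scalar_prob(q_level, "q_level")
  if (q_level <= 0 || q_level >= 1) stop("'q_level' must be in (0, 1)")
  if (min(k_range) < 2L) stop("'k_range' must start at 2 or above")
  structure(list(q_level = q_level, k_range = as.integer(k_range),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "stratified_config")
}

#' Stratify peaks by fold change with silhouette-selected k-means
#'
#' Clusters the peaks on |log2 fold change| (so strong up- and
#' down-regulation land in the same "large fold change" stratum) by 1-D
#' k-means, choosing k from `k_range` as the partition with the maximal mean
#' silhouette value; ties go to the smaller k. Peaks with infinite fold
#' change join the stratum with the largest centre. If all fold changes are
#' identical (no spread to cluster), stratification is refused and a single
#' stratum returned, with a logged warning.
#'
#' @param table A `de_table` from [test_peaks()].
#' @param config A [stratified_config()].
#' @return List with `assignment` (stratum id per peak), `k`,
#'   `mean_silhouette`, `centers`.
#' @export
stratify_by_fc <- function(table, config = stratified_config()) {
  val <- abs(log2(table$fc))
  n <- length(val)
  finite <- is.finite(val)
  x <- val[finite]
  if (length(unique(x)) < 2L) {
    pc_log("stratify", "fold changes carry no spread; single stratum")
    return(list(assignment = rep(1L, n), k = 1L,
                mean_silhouette = NA_real_, centers = mean(val[finite])))
  }
  k_range <- config$k_range[config$k_range <= length(unique(x)) - 1L]
  if (!length(k_range)) k_range <- 2L
  with_seed(config$seed, {
    d <- stats::dist(x)
    best <- NULL; best_sil <- -Inf; best_k <- NA_integer_
    for (k in k_range) {
      km <- suppressWarnings(stats::kmeans(x, centers = k,
                                           nstart = config$n_restarts,
                                           iter.max = 50L))
      sil <- mean(cluster::silhouette(km$cluster, d)[, 3L])
      if (sil > best_sil + 1e-12) {   # strict: ties keep the smaller k
        best_sil <- sil; best <- km; best_k <- k
      }
    }
    assignment <- integer(n)
    assignment[finite] <- best$cluster
    if (any(!finite)) {
      assignment[!finite] <- which.max(best$centers)
    }
    list(assignment = assignment, k = best_k, mean_silhouette = best_sil,
         centers = as.numeric(best$centers))
  })
}

#' Select DE peaks with per-stratum FDR control
#'
#' Applies [bh_select()] independently inside each stratum at the same
#' level and reports the union. The strata are disjoint, so the FDR of the
#' union stays below the level.
#'
#' @param table A `de_table`.
#' @param assignment Stratum id per peak (e.g. from [stratify_by_fc()]).
#' @param q_level FDR level.
#' @return The `de_table` with `significant`, `stratum` and `q_level`
#'   filled in; per-stratum realized cutoffs in attribute `"cutoffs"`.
#' @export
stratified_select <- function(table, assignment, q_level = 0.10) {
  if (length(assignment) != nrow(table)) {
    stop("'assignment' must cover every peak")
  }
  table$stratum <- assignment
  table$q_level <- q_level
  table$significant <- FALSE
  strata <- sort(unique(assignment))
  cutoffs <- stats::setNames(numeric(length(strata)),
                             as.character(strata))
  for (s in strata) {
    rows <- assignment == s
    sel <- bh_select(table$p_value[rows], q_level)
    table$significant[rows] <- sel$significant
    cutoffs[as.character(s)] <- sel$cutoff
  }
  attr(table, "cutoffs") <- cutoffs
  table
}

#' Select DE peaks at an FDR level
#'
#' Convenience wrapper: simple BH over all peaks, or fold-change-stratified
#' BH when `stratified = TRUE`.
#'
#' @param table A `de_table`.
#' @param q_level FDR level (default 0.10).
#' @param stratified Use the stratified procedure.
#' @param config [stratified_config()] for the stratification step.
#' @return The `de_table` with selection columns filled in.
#' @export
select_de <- function(table, q_level = 0.10, stratified = FALSE,
                      config = stratified_config(q_level = q_level)) {
  if (stratified) {
    strat <- stratify_by_fc(table, config)
    stratified_select(table, strat$assignment, q_level)
  } else {
    stratified_select(table, rep(1L, nrow(table)), q_level)
  }
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("<de_table> %d peaks, %d significant (q = %s, %d strata)\n",
              nrow(x), sum(x$significant),
              format(x$q_level[1L]), length(unique(x$stratum))))
  NextMethod()
}
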