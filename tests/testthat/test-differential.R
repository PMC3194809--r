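mk_table <- function(p, fc = rep(2, length(p)), mz = NULL) {
  out <- data.frame(mz = if (is.null(mz)) seq_along(p) * 100 + 1000 else mz,
                    t_stat = 0, p_value = p, fc = fc,
                    direction = ifelse(fc > 1, "up",
                                       ifelse(fc < 1, "down", "none")),
                    stratum = 1L, significant = FALSE, q_level = NA_real_)
  class(out) <- c("de_table", "data.frame")
  out
}

test_that("t statistics match the textbook pooled-variance formula", {
  x <- rbind(matrix(c(5.1, 4.9, 5.0), 3, 1),
             matrix(c(3.1, 2.9, 3.0), 3, 1))
  tab <- test_peaks(x, labels = rep(c("cancer", "normal"), each = 3),
                    mz = 1234)
  g1 <- c(5.1, 4.9, 5.0); g2 <- c(3.1, 2.9, 3.0)
  sp <- sqrt((2 * var(g1) + 2 * var(g2)) / 4)
  t_oracle <- (mean(g1) - mean(g2)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(tab$t_stat, t_oracle, tolerance = 1e-12)
  expect_equal(tab$p_value, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)
  expect_equal(tab$fc, 5 / 3, tolerance = 1e-12)
  expect_equal(tab$direction, "up")
})

test_that("degenerate groups behave as documented", {
  # identical groups with spread: t = 0, p = 1, fc = 1, direction none
  x <- cbind(c(1, 2, 3, 1, 2, 3))
  tab <- test_peaks(x, labels = rep(c("cancer", "normal"), each = 3))
  expect_equal(tab$t_stat, 0)
  expect_equal(tab$p_value, 1)
  expect_equal(tab$fc, 1)
  expect_equal(tab$direction, "none")
  # zero pooled variance: p = 1 when means equal, p -> 0 otherwise
  x <- cbind(rep(2, 6), rep(c(1, 3), each = 3))
  expect_message(
    tab <- test_peaks(x, labels = rep(c("cancer", "normal"), each = 3)),
    "zero pooled variance")
  expect_equal(tab$p_value[1L], 1)
  expect_lt(tab$p_value[2L], 1e-300)
  # the log2 switch requires positive intensities
  x <- cbind(c(0, 1, 2, 3, 4, 5))
  expect_error(test_peaks(x, labels = rep(c("cancer", "normal"), each = 3),
                          log2_transform = TRUE), "positive")
})

test_that("BH step-up matches hand computation and the exhaustive oracle", {
  sel <- bh_select(c(0.001, 0.01, 0.02, 0.9), 0.05)
  expect_equal(sel$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sel$cutoff, 0.02)
  expect_equal(bh_select(rep(1, 10), 0.1)$n_selected, 0L)
  expect_equal(bh_select(numeric(0), 0.1)$cutoff, 0)
  set.seed(20)
  for (i in 1:1000) {
    m <- sample(1:50, 1L)
    p <- round(runif(m)^sample(1:3, 1L), 4)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1L)
    got <- bh_select(p, q)
    oracle <- bh_brute_force(p, q)
    expect_identical(got$significant, oracle$significant)
    expect_equal(got$cutoff, oracle$cutoff)
    # cross-check against the adjusted-p route
    expect_identical(got$significant, p.adjust(p, "BH") <= q)
  }
})

test_that("BH selection is monotone in the level", {
  set.seed(21)
  for (i in 1:50) {
    p <- runif(40)^2
    lo <- bh_select(p, 0.05)$significant
    hi <- bh_select(p, 0.15)$significant
    expect_true(all(hi[lo]))  # superset at the larger level
  }
})

test_that("fold-change stratification recovers separated clusters", {
  set.seed(22)
  fc <- c(1, 1, 1, 8, 8, 8) * exp(rnorm(6, 0, 0.01))
  tab <- mk_table(runif(6), fc = fc)
  strat <- stratify_by_fc(tab, stratified_config(k_range = 2:4, seed = 1))
  expect_equal(strat$k, 2L)
  expect_gt(strat$mean_silhouette, 0.9)
  expect_equal(length(unique(strat$assignment[1:3])), 1L)
  expect_equal(length(unique(strat$assignment[4:6])), 1L)
  expect_false(strat$assignment[1L] == strat$assignment[4L])
})

test_that("k = 2 clustering matches the exhaustive 1-D split oracle", {
  set.seed(23)
  for (i in 1:10) {
    v <- sort(abs(rnorm(30, 0, 1)) + rep(c(0, 3), c(20, 10)))
    tab <- mk_table(runif(30), fc = 2^v)
    strat <- stratify_by_fc(tab, stratified_config(k_range = 2L, seed = i))
    # oracle: best of the n-1 ordered splits by within-cluster SS
    wss <- vapply(1:29, function(s) {
      sum((v[1:s] - mean(v[1:s]))^2) +
        sum((v[(s + 1):30] - mean(v[(s + 1):30]))^2)
    }, numeric(1L))
    split <- which.min(wss)
    oracle <- rep(1:2, c(split, 30 - split))
    agree <- max(mean(strat$assignment == oracle),
                 mean(strat$assignment == 3 - oracle))
    expect_equal(agree, 1)
  }
})

test_that("a breast-like fold-change mixture is split into low/high strata", {
  set.seed(24)
  v <- c(abs(rnorm(259, 0, 0.25)), rnorm(28, 2.2, 0.35))
  tab <- mk_table(runif(287), fc = 2^v)
  strat <- stratify_by_fc(tab, stratified_config(seed = 2))
  expect_equal(strat$k, 2L)
  sizes <- sort(as.integer(table(strat$assignment)))
  expect_lte(abs(sizes[1L] - 28L), 3L)
  expect_lte(abs(sizes[2L] - 259L), 3L)
})

test_that("identical fold changes refuse stratification gracefully", {
  tab <- mk_table(runif(20), fc = rep(2, 20))
  expect_message(strat <- stratify_by_fc(tab), "single stratum")
  expect_equal(strat$k, 1L)
  expect_equal(unique(strat$assignment), 1L)
})

test_that("single-stratum selection reduces to simple BH", {
  set.seed(25)
  tab <- mk_table(runif(50)^2)
  simple <- bh_select(tab$p_value, 0.1)
  strat <- stratified_select(tab, rep(1L, 50), 0.1)
  expect_identical(strat$significant, simple$significant)
  expect_equal(unname(attr(strat, "cutoffs")), simple$cutoff)
})

test_that("concentrating signal in a small stratum gains discoveries", {
  # 300 nulls + 20 alternatives confined to a 30-test stratum; every small
  # p-value sits in the small stratum
  set.seed(26)
  p <- c(runif(300, 0.05, 1), pnorm(rnorm(20, 3.2), lower.tail = FALSE),
         runif(10, 0.05, 1))
  assign <- rep(c(1L, 2L), c(300, 30))
  tab <- mk_table(p)
  simple <- stratified_select(tab, rep(1L, 330), 0.1)
  strat <- stratified_select(tab, assign, 0.1)
  expect_gte(sum(strat$significant), sum(simple$significant))
  expect_true(all(which(simple$significant) %in% which(strat$significant)))
  expect_gt(sum(strat$significant[301:320]), 0)
})

test_that("adding pure-null tests never helps the original tests", {
  set.seed(27)
  for (i in 1:20) {
    p0 <- runif(40)^3
    sel0 <- bh_select(p0, 0.1)
    p1 <- c(p0, runif(200, 0.5, 1))  # diluting with nulls
    sel1 <- bh_select(p1, 0.1)
    expect_true(all(sel1$significant[1:40][!sel0$significant] == FALSE) ||
                  sel1$cutoff <= sel0$cutoff + 1e-12)
    expect_lte(sum(sel1$significant[1:40]), sel0$n_selected)
  }
})
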