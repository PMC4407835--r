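mk_ranked <- function(ids) {
  structure(list(direction = "patients_for_trial", anchor_id = "T",
                 items = data.frame(rank = seq_along(ids), candidate_id = ids,
                                    score = rev(seq_along(ids)),
                                    shared_terms = 0L, contradictions = 0L,
                                    stringsAsFactors = FALSE)),
            class = "ranked_list")
}

test_that("workload is the deepest positive, with full-review fallbacks", {
  rl <- mk_ranked(c("P3", "P1", "P7", "P2"))
  expect_equal(workload(rl, c("P1", "P2"), 10), 4L)
  expect_equal(workload(mk_ranked(paste0("P", 1:10)), character(0), 215), 10L)
  # a filtered-out positive forces exhaustive review of the universe
  expect_equal(workload(rl, "P9", 215), 215L)
  expect_equal(workload(rl, "P3", 215), 1L)
})

test_that("metrics at the workload cutoff follow the stated identities", {
  m <- metrics_at_workload(4, 2, 10)
  expect_equal(m$precision, 0.5)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$recall, 1)
  expect_equal(m$npv, 1)

  m <- metrics_at_workload(24, 3, 215)
  expect_equal(m$precision, 0.125)
  expect_equal(m$specificity, 191 / 212)

  m <- metrics_at_workload(5, 5, 5)
  expect_equal(m$precision, 1)
  expect_equal(m$specificity, 1)

  expect_error(metrics_at_workload(2, 3, 10), "<=")
})

test_that("metrics agree with brute-force confusion-matrix counting", {
  set.seed(31)
  for (rep in 1:200) {
    N <- sample(3:40, 1)
    ids <- paste0("P", sample(1000, N))
    k <- sample(0:min(N, 6), 1)
    positives <- sample(ids, k)
    rl <- mk_ranked(sample(ids))
    wl <- workload(rl, positives, N)
    m <- metrics_at_workload(wl, k, N)
    reviewed <- if (wl <= nrow(rl$items) && all(positives %in% rl$items$candidate_id)) {
      rl$items$candidate_id[seq_len(wl)]
    } else ids
    TP <- sum(positives %in% reviewed)
    FP <- length(reviewed) - TP
    FN <- k - TP
    TN <- N - length(reviewed) - FN
    expect_equal(FN, 0)
    expect_equal(m$precision, if (wl == 0) 0 else TP / (TP + FP))
    if (TN + FP > 0) expect_equal(m$specificity, TN / (TN + FP))
    expect_equal(m$recall, 1)
    expect_equal(m$npv, 1)
  }
})

test_that("workload is k for a perfect ranking, never below k, monotone in rank", {
  set.seed(17)
  for (rep in 1:50) {
    N <- sample(4:30, 1)
    ids <- paste0("P", sprintf("%02d", 1:N))
    k <- sample(1:3, 1)
    positives <- sample(ids, k)
    perfect <- mk_ranked(c(sort(positives), setdiff(ids, positives)))
    expect_equal(workload(perfect, positives, N), k)
    shuffled <- mk_ranked(sample(ids))
    wl <- workload(shuffled, positives, N)
    expect_gte(wl, k)
    # improving a positive's rank never increases workload
    perm <- shuffled$items$candidate_id
    pos_idx <- which(perm %in% positives)[1]
    if (pos_idx > 1) {
      better <- mk_ranked(c(perm[pos_idx], perm[-pos_idx]))
      expect_lte(workload(better, positives, N), wl)
    }
  }
})

test_that("expected random workload matches exhaustive enumeration for N <= 7", {
  for (N in 1:7) {
    for (k in 0:N) {
      expect_equal(expected_random_workload(N, k),
                   oracle_expected_max_rank(N, k), info = paste(N, k))
    }
  }
  expect_equal(expected_random_workload(10, 2), 22 / 3)
  expect_equal(expected_random_workload(5, 5), 5)
  expect_equal(expected_random_workload(7, 0), 7)
})

test_that("aggregation reports t-based CI and micro/macro pools", {
  mk <- function(wl, k, N) metrics_at_workload(wl, k, N)
  ms <- list(mk(3, 1, 10), mk(4, 1, 10), mk(5, 1, 10))
  agg <- aggregate_metrics(ms)
  expect_equal(agg$mean_workload, 4)
  half <- stats::qt(0.975, 2) * stats::sd(c(3, 4, 5)) / sqrt(3)
  expect_equal(agg$ci_low, 4 - half)
  expect_equal(agg$ci_high, 4 + half)
  expect_equal(agg$precision_micro, 3 / 12)
  expect_equal(agg$precision_macro, mean(c(1 / 3, 1 / 4, 1 / 5)))

  # single anchor: degenerate CI collapses to the point
  agg1 <- aggregate_metrics(ms[1])
  expect_equal(agg1$ci_low, 3)
  expect_equal(agg1$ci_high, 3)

  # micro and macro differ when workloads are unequal
  ms2 <- list(mk(2, 1, 10), mk(8, 1, 10))
  agg2 <- aggregate_metrics(ms2)
  expect_equal(agg2$precision_micro, 2 / 10)
  expect_equal(agg2$precision_macro, mean(c(1 / 2, 1 / 8)))
  expect_false(isTRUE(all.equal(agg2$precision_micro, agg2$precision_macro)))
})

test_that("paired workload test matches the textbook t formula", {
  expect_equal(paired_workload_test(c(3, 4, 5), c(3, 4, 5)), 1)
  # constant non-zero shift: documented degenerate branch
  expect_equal(paired_workload_test(c(1, 2, 3), c(2, 3, 4)), 0)
  expect_error(paired_workload_test(1:3, 1:4), "length")

  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    a <- stats::rnorm(n, 10, 3)
    b <- a + stats::rnorm(n, 0.5, 1)
    d <- a - b
    tstat <- mean(d) / (stats::sd(d) / sqrt(n))
    p_ref <- 2 * stats::pt(-abs(tstat), df = n - 1)
    expect_equal(paired_workload_test(a, b), p_ref, tolerance = 1e-10)
  }
})

test_that("chart-review precision arithmetic", {
  tab <- load_chart_review()
  expect_equal(sum(tab$n_enrolled), 38L)
  expect_equal(sum(tab$n_output), 76L)
  res <- chart_review_precision(tab)
  expect_equal(res$historical_precision, 0.38)
  expect_equal(res$adjusted_precision, 0.45)
  expect_equal(res$relative_improvement, 18.4)

  none <- chart_review_table("T1", 2, 4, 1, 0)
  res <- chart_review_precision(none)
  expect_equal(res$adjusted_precision, res$historical_precision)
  expect_equal(res$relative_improvement, 0)

  expect_error(chart_review_table("T1", 2, 5, 1, 0), "2 \\* n_enrolled")
  expect_error(chart_review_table("T1", 2, 4, 3, 0), "n_hits")
})

test_that("projection applies relative improvement with a cap", {
  expect_equal(project_adjusted_precision(0.126, 18.4), 0.149)
  expect_equal(project_adjusted_precision(0.5, 0), 0.5)
  expect_equal(project_adjusted_precision(0.5, 100), 1)
})

test_that("error-category fractions", {
  counts <- c(3, 4, 5, 5, 13, 12)
  res <- error_category_fractions(counts)
  expect_equal(res$total, 42L)
  expect_equal(res$grouped_3_5_pct, 54.7)
  expect_equal(res$per_category_pct[2], 10)
  expect_equal(error_category_fractions(c(0, 0, 1, 0, 0, 0))$grouped_3_5_pct, 100)
  expect_error(error_category_fractions(rep(0, 6)), "zero")
})
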