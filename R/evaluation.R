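#' Load a reference standard of historical enrollments
#'
#' CSV with header `patient_id,nct_id,enrollment_date`. Each row is one
#' historical trial-patient match used as a retrospective positive.
#'
#' @param path Path to the CSV.
#' @return data.frame with those three columns (`enrollment_date` as Date).
#' @export
load_reference <- function(path) {
  ref <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("patient_id", "nct_id") %in% names(ref))) {
    stop("reference CSV must have patient_id and nct_id columns")
  }
  if (!"enrollment_date" %in% names(ref)) ref$enrollment_date <- NA_character_
  ref$enrollment_date <- as.Date(ref$enrollment_date)
  ref[, c("patient_id", "nct_id", "enrollment_date")]
}

#' Screening workload for one ranked list
#'
#' The number of candidates a reviewer must inspect, top-down, to capture
#' every reference-standard positive for this anchor. No positives means
#' the whole ranked list must be reviewed to confirm ineligibility. A
#' positive that the pre-filter removed before ranking can never be reached
#' from the list, so the reviewer is forced back to the entire universe:
#' workload is then `n_universe` (and recall stays 1 by construction).
#'
#' @param ranked A `ranked_list` (or its `items` data.frame).
#' @param positives Character vector of reference-positive candidate ids.
#' @param n_universe Size of the unfiltered candidate universe.
#' @return Integer workload.
#' @export
workload <- function(ranked, positives, n_universe) {
  items <- if (inherits(ranked, "ranked_list")) ranked$items else ranked
  positives <- unique(positives)
  if (length(positives) == 0L) return(nrow(items))
  pos_ranks <- items$rank[items$candidate_id %in% positives]
  if (length(pos_ranks) < length(positives)) {
    return(as.integer(n_universe))
  }
  as.integer(max(pos_ranks))
}

#' Screening metrics at the workload cutoff
#'
#' Reviewing the top `wl` candidates captures all `n_positives` positives
#' (FN = 0 by construction of the cutoff), so recall and NPV are identically
#' 1; precision is `n_positives / wl` and specificity
#' `(n_candidates - wl) / (n_candidates - n_positives)` (defined as 1 when
#' no true negatives exist).
#'
#' @param wl Workload (cutoff depth).
#' @param n_positives Number of reference positives for the anchor.
#' @param n_candidates Size of the candidate universe for the anchor.
#' @return A list of class `screening_metrics`.
#' @export
metrics_at_workload <- function(wl, n_positives, n_candidates) {
  if (n_positives < 0 || wl < n_positives || n_candidates < wl) {
    stop("need 0 <= n_positives <= wl <= n_candidates (got ",
         n_positives, ", ", wl, ", ", n_candidates, ")")
  }
  precision <- if (wl == 0) 0 else n_positives / wl
  specificity <- if (n_candidates > n_positives) {
    (n_candidates - wl) / (n_candidates - n_positives)
  } else 1
  structure(list(workload = as.integer(wl), precision = precision,
                 specificity = specificity, recall = 1, npv = 1,
                 n_candidates = as.integer(n_candidates),
                 n_positives = as.integer(n_positives)),
            class = "screening_metrics")
}

#' Expected workload under random shuffling
#'
#' With `k` positives placed uniformly among `N` shuffled candidates, the
#' reviewer must read down to the deepest positive; the expectation of the
#' maximum of `k` uniform ranks without replacement is `k (N + 1) / (k + 1)`.
#' With no positives the whole list is reviewed: expectation `N`.
#'
#' @param n_candidates N, post-filter list length.
#' @param n_positives k.
#' @return Expected workload (real).
#' @export
expected_random_workload <- function(n_candidates, n_positives) {
  stopifnot(n_positives >= 0, n_positives <= n_candidates)
  if (n_positives == 0) return(as.numeric(n_candidates))
  n_positives * (n_candidates + 1) / (n_positives + 1)
}

#' Aggregate per-anchor screening metrics
#'
#' Mean workload with a 95 percent t-interval over anchors, plus pooled
#' (micro: ratio of sums) and averaged (macro: mean of per-anchor ratios)
#' precision and specificity. A single anchor yields a degenerate CI equal
#' to the point estimate.
#'
#' @param metrics List of `screening_metrics`.
#' @return A list: `n_anchors`, `mean_workload`, `ci_low`, `ci_high`,
#'   `precision_micro`, `precision_macro`, `specificity_micro`,
#'   `specificity_macro`.
#' @export
aggregate_metrics <- function(metrics) {
  stopifnot(length(metrics) > 0L)
  wl <- vapply(metrics, `[[`, numeric(1L), "workload")
  k <- vapply(metrics, function(m) as.numeric(m$n_positives), numeric(1L))
  N <- vapply(metrics, function(m) as.numeric(m$n_candidates), numeric(1L))
  n <- length(wl)
  m_wl <- mean(wl)
  if (n >= 2L && stats::sd(wl) > 0) {
    half <- stats::qt(0.975, df = n - 1L) * stats::sd(wl) / sqrt(n)
  } else {
    half <- 0
  }
  micro_p <- if (sum(wl) > 0) sum(k) / sum(wl) else 0
  sp_num <- sum(N - wl)
  sp_den <- sum(N - k)
  list(
    n_anchors = n,
    mean_workload = m_wl,
    ci_low = m_wl - half,
    ci_high = m_wl + half,
    precision_micro = micro_p,
    precision_macro = mean(vapply(metrics, `[[`, numeric(1L), "precision")),
    specificity_micro = if (sp_den > 0) sp_num / sp_den else 1,
    specificity_macro = mean(vapply(metrics, `[[`, numeric(1L), "specificity"))
  )
}

#' Paired t-test on two workload vectors
#'
#' Two-sided paired t-test comparing per-anchor workloads of two
#' algorithms. Degenerate variance of the differences is handled
#' explicitly: all differences zero gives p = 1 (the algorithms are
#' identical), a non-zero constant difference gives p = 0 (the limit of the
#' t statistic as the variance vanishes).
#'
#' @param wl_a,wl_b Equal-length numeric vectors (length >= 2).
#' @return Two-sided p-value.
#' @export
paired_workload_test <- function(wl_a, wl_b) {
  if (length(wl_a) != length(wl_b)) stop("workload vectors differ in length")
  if (length(wl_a) < 2L) stop("need at least two paired anchors")
  d <- wl_a - wl_b
  if (stats::sd(d) == 0) {
    return(if (all(d == 0)) 1 else 0)
  }
  stats::t.test(wl_a, wl_b, paired = TRUE)$p.value
}

#' Build a chart-review table
#'
#' Per-trial counts from a physician chart review of the algorithm's top
#' `2 N` candidates, where `N` is the trial's number of historical
#' enrollments: how many of the outputs were historical enrollments
#' (`n_hits`) and how many additional truly eligible patients the reviewer
#' found among them (`n_additional`).
#'
#' @param nct_id,n_enrolled,n_output,n_hits,n_additional Parallel vectors.
#' @return data.frame of class `chart_review_table`.
#' @export
chart_review_table <- function(nct_id, n_enrolled, n_output, n_hits,
                               n_additional) {
  df <- data.frame(nct_id = as.character(nct_id),
                   n_enrolled = as.integer(n_enrolled),
                   n_output = as.integer(n_output),
                   n_hits = as.integer(n_hits),
                   n_additional = as.integer(n_additional),
                   stringsAsFactors = FALSE)
  if (any(df$n_output != 2L * df$n_enrolled)) {
    stop("n_output must equal 2 * n_enrolled for every trial")
  }
  if (any(df$n_hits > pmin(df$n_enrolled, df$n_output)) || any(df$n_hits < 0L)) {
    stop("n_hits must lie in [0, min(n_enrolled, n_output)]")
  }
  if (any(df$n_additional < 0L)) stop("n_additional must be non-negative")
  class(df) <- c("chart_review_table", "data.frame")
  df
}

#' Load a chart-review table from CSV
#'
#' @param path CSV with columns `nct_id`, `n_enrolled`, `n_output`,
#'   `n_hits`, `n_additional`. The default is the review table bundled with
#'   the package.
#' @return A `chart_review_table`.
#' @export
load_chart_review <- function(path = system.file("extdata", "chart_review.csv",
                                                 package = "espre")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  chart_review_table(df$nct_id, df$n_enrolled, df$n_output, df$n_hits,
                     df$n_additional)
}

#' Precision before and after chart-review adjustment
#'
#' Historical precision pools hits over outputs across trials; adjusted
#' precision adds the reviewer-identified additional eligibles to the
#' numerator. Both are reported to two decimals, the relative improvement
#' (computed on the rounded values) as a percentage to one decimal — the
#' conventional presentation for this kind of review table.
#'
#' @param table A `chart_review_table`.
#' @return List: `historical_precision`, `adjusted_precision`,
#'   `relative_improvement` (percent).
#' @export
chart_review_precision <- function(table) {
  total_out <- sum(table$n_output)
  if (total_out == 0L) stop("chart-review table has zero algorithm outputs")
  hist <- round(sum(table$n_hits) / total_out, 2)
  adj <- round(sum(table$n_hits + table$n_additional) / total_out, 2)
  impr <- if (hist > 0) round((adj - hist) / hist * 100, 1) else NA_real_
  list(historical_precision = hist, adjusted_precision = adj,
       relative_improvement = impr)
}

#' Project a chart-review improvement onto a base precision
#'
#' Scales a cohort-level precision by the relative improvement measured in
#' the chart review, capped at 1, reported to three decimals.
#'
#' @param base_precision Proportion in `[0, 1]`.
#' @param relative_improvement Percentage.
#' @return Projected precision (proportion).
#' @export
project_adjusted_precision <- function(base_precision, relative_improvement) {
  stopifnot(base_precision >= 0, base_precision <= 1)
  min(1, round(base_precision * (1 + relative_improvement / 100), 3))
}

#' False-positive error-category fractions
#'
#' Six error categories from the chart review's false-positive analysis.
#' Reports the total, each category's share rounded to the nearest integer
#' percent, and the combined share of categories 3-5 (the
#' phrase-confusion errors: wrong stage, wrong relapse status, confused
#' disease sub-category) truncated to one decimal.
#'
#' @param counts Integer vector of 6 non-negative category counts.
#' @return List: `total`, `per_category_pct` (length 6),
#'   `grouped_3_5_pct`.
#' @export
error_category_fractions <- function(counts) {
  stopifnot(length(counts) == 6L, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("all error counts are zero")
  per <- round(100 * counts / total)
  grouped <- trunc(1000 * sum(counts[3:5]) / total) / 10
  list(total = as.integer(total), per_category_pct = as.numeric(per),
       grouped_3_5_pct = grouped)
}

#' Load the bundled error-category counts
#'
#' @param path CSV with columns `category`, `description`, `n_errors`.
#' @return Integer vector of the six counts, in category order.
#' @export
load_error_categories <- function(path = system.file("extdata",
                                                     "error_categories.csv",
                                                     package = "espre")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[order(df$category), ]
  as.integer(df$n_errors)
}
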