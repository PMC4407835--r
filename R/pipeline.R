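#' Read a flat key:value run configuration file
#'
#' One `key: value` pair per line; `#` comments and blank lines ignored.
#' Unknown keys are rejected so typos fail fast.
#'
#' @param path Path to the config file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*:\\s*(.*)$", lines))
  if (any(vapply(kv, length, integer(1L)) != 3L)) {
    stop("malformed config line: ", lines[vapply(kv, length, integer(1L)) != 3L][1L])
  }
  cfg <- stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, character(1L), 2L))
  known <- c("trials_dir", "patients", "terminology", "icd9_map", "triggers",
             "reference", "out_dir", "lambda", "window", "include_raw_tokens",
             "negex_in_exclusion", "use_diagnoses", "use_notes", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in c("lambda", "window", "seed")) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  }
  for (k in c("include_raw_tokens", "negex_in_exclusion", "use_diagnoses",
              "use_notes")) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- toupper(cfg[[k]]) %in% c("TRUE", "YES", "1")
  }
  structure(cfg, class = "run_config")
}

#' Load all pipeline inputs into a screening context
#'
#' Reads the terminology, ICD-9 map, trigger lexicon, trial files,
#' patient records and reference standard; pre-vectorizes every patient
#' entry once (each note and diagnosis keeps its date and key set), so the
#' per-trial temporal cutoff reduces to filtering cached entries by date.
#' Reference ids that resolve to no loaded trial or patient are an error.
#'
#' @param trials_dir Directory of trial criteria files (`*.txt`).
#' @param patients Path to the patient JSONL file.
#' @param terminology,icd9_map Paths to the terminology and map TSVs.
#' @param triggers Path to a trigger lexicon (default: bundled).
#' @param reference Path to the reference CSV (optional).
#' @param lambda,window,include_raw_tokens,negex_in_exclusion,use_diagnoses,use_notes
#'   Matching parameters, stored on the context.
#' @return A list of class `espre_context`.
#' @export
load_context <- function(trials_dir, patients, terminology, icd9_map = NULL,
                         triggers = NULL, reference = NULL,
                         lambda = 1, window = 5L, include_raw_tokens = TRUE,
                         negex_in_exclusion = TRUE,
                         use_diagnoses = TRUE, use_notes = TRUE) {
  index <- load_terminology(terminology)
  map <- if (!is.null(icd9_map)) load_icd9_map(icd9_map, index) else NULL
  trig <- if (!is.null(triggers)) load_triggers(triggers) else load_triggers()

  files <- sort(list.files(trials_dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) stop("no trial files in ", trials_dir)
  trials <- lapply(files, function(f) {
    build_trial_profile(read_trial_file(f), index, trig,
                        include_raw_tokens = include_raw_tokens,
                        negex_in_exclusion = negex_in_exclusion,
                        window = window)
  })
  names(trials) <- vapply(trials, `[[`, character(1L), "nct_id")

  records <- read_patients(patients, trials)

  ref <- NULL
  if (!is.null(reference)) {
    ref <- load_reference(reference)
    bad_t <- setdiff(ref$nct_id, names(trials))
    bad_p <- setdiff(ref$patient_id, names(records))
    if (length(bad_t)) stop("reference names unknown trial(s): ",
                            paste(bad_t, collapse = ", "))
    if (length(bad_p)) stop("reference names unknown patient(s): ",
                            paste(bad_p, collapse = ", "))
  }

  cache <- lapply(records, function(rec) .entry_cache(rec, index, map, trig,
                                                      include_raw_tokens,
                                                      window))
  structure(list(trials = trials, records = records, reference = ref,
                 index = index, icd9map = map, triggers = trig,
                 lambda = lambda, window = window,
                 include_raw_tokens = include_raw_tokens,
                 use_diagnoses = use_diagnoses, use_notes = use_notes,
                 cache = cache),
            class = "espre_context")
}

# Vectorize each entry of a record once; profiles for any cutoff are then
# unions of cached key sets.
.entry_cache <- function(rec, index, map, trig, include_raw_tokens, window) {
  dx <- lapply(seq_len(nrow(rec$diagnoses)), function(i) {
    toks <- tokenize(rec$diagnoses$text[i])
    keys <- extract_mentions(toks, index)$concept_id
    code <- rec$diagnoses$icd9[i]
    if (!is.null(map) && !is.na(code) && nzchar(code)) {
      keys <- c(keys, map_icd9(code, map))
    }
    unique(keys)
  })
  nt <- lapply(seq_len(nrow(rec$notes)), function(i) {
    unclass(text_to_vector(rec$notes$text[i], index, trig, negation = TRUE,
                           include_raw_tokens = include_raw_tokens,
                           window = window))
  })
  list(dx_keys = dx, dx_dates = as.Date(rec$diagnoses$date),
       note_keys = nt, note_dates = as.Date(rec$notes$date))
}

# Patient vector for one trial's temporal cutoff, from the entry cache.
.cached_profile <- function(ctx, patient_id, trial) {
  rec <- ctx$records[[patient_id]]
  cache <- ctx$cache[[patient_id]]
  hit <- which(rec$enrollments$nct_id == trial$nct_id)
  keep <- function(d) {
    if (length(hit)) d < as.Date(rec$enrollments$date[hit[1L]])
    else d <= trial$close_date
  }
  keys <- character(0)
  if (ctx$use_diagnoses && length(cache$dx_keys)) {
    keys <- c(keys, unlist(cache$dx_keys[keep(cache$dx_dates)], use.names = FALSE))
  }
  if (ctx$use_notes && length(cache$note_keys)) {
    keys <- c(keys, unlist(cache$note_keys[keep(cache$note_dates)],
                           use.names = FALSE))
  }
  term_vector(keys)
}

#' Score every surviving trial-patient pair
#'
#' Applies the demographics/window pre-filter to every pair and scores the
#' survivors. Both screening directions rank from this one matrix, so
#' trial-centered and patient-centered runs agree on the underlying scores
#' by construction.
#'
#' @param ctx An `espre_context`.
#' @return data.frame with columns `nct_id`, `patient_id`, `score`,
#'   `shared_terms`, `contradictions` (one row per pair passing the filter).
#' @export
score_pairs <- function(ctx) {
  rows <- list()
  for (tr in ctx$trials) {
    for (rec in ctx$records) {
      if (!demographics_filter(rec, tr)) next
      pv <- .cached_profile(ctx, rec$patient_id, tr)
      s <- match_score(tr$vector, pv, ctx$lambda)
      rows[[length(rows) + 1L]] <- data.frame(
        nct_id = tr$nct_id, patient_id = rec$patient_id,
        score = s$value, shared_terms = s$shared_terms,
        contradictions = s$contradictions, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(nct_id = character(0), patient_id = character(0),
                      score = numeric(0), shared_terms = integer(0),
                      contradictions = integer(0)))
  }
  do.call(rbind, rows)
}

.rank_from_scores <- function(scores, anchor_col, cand_col, anchor_id,
                              direction) {
  sub <- scores[scores[[anchor_col]] == anchor_id, , drop = FALSE]
  items <- data.frame(candidate_id = sub[[cand_col]], score = sub$score,
                      shared_terms = sub$shared_terms,
                      contradictions = sub$contradictions,
                      stringsAsFactors = FALSE)
  items <- items[order(-items$score, items$candidate_id), , drop = FALSE]
  items$rank <- seq_len(nrow(items))
  rownames(items) <- NULL
  structure(list(direction = direction, anchor_id = anchor_id,
                 items = items[, c("rank", "candidate_id", "score",
                                   "shared_terms", "contradictions")]),
            class = "ranked_list")
}

.metrics_row <- function(anchor_id, m) {
  data.frame(anchor_id = anchor_id, workload = m$workload,
             n_candidates = m$n_candidates, n_positives = m$n_positives,
             precision = m$precision, specificity = m$specificity,
             recall = m$recall, npv = m$npv, stringsAsFactors = FALSE)
}

.run_direction <- function(ctx, direction, anchors, out_dir = NULL,
                           scores = NULL) {
  if (is.null(scores)) scores <- score_pairs(ctx)
  trial_centered <- direction == "patients_for_trial"
  anchor_col <- if (trial_centered) "nct_id" else "patient_id"
  cand_col <- if (trial_centered) "patient_id" else "nct_id"
  n_universe <- if (trial_centered) length(ctx$records) else length(ctx$trials)

  ref <- ctx$reference
  metrics <- list()
  rows <- list()
  baseline_wl <- numeric(0)
  es_wl <- numeric(0)
  for (a in anchors) {
    ranked <- .rank_from_scores(scores, anchor_col, cand_col, a, direction)
    if (!is.null(out_dir)) write_ranked_list(ranked, out_dir)
    positives <- if (trial_centered) ref$patient_id[ref$nct_id == a]
    else ref$nct_id[ref$patient_id == a]
    positives <- unique(positives)
    n_cand <- nrow(ranked$items)
    if (n_cand == 0L && length(positives) == 0L) {
      warning("anchor ", a, " has zero post-filter candidates")
      m <- metrics_at_workload(0L, 0L, n_universe)
    } else {
      wl <- workload(ranked, positives, n_universe)
      m <- metrics_at_workload(wl, length(positives), n_universe)
    }
    metrics[[a]] <- m
    rows[[a]] <- .metrics_row(a, m)
    es_wl <- c(es_wl, m$workload)
    k_in <- sum(positives %in% ranked$items$candidate_id)
    baseline_wl <- c(baseline_wl,
                     if (k_in < length(positives)) n_universe
                     else expected_random_workload(n_cand, length(positives)))
  }
  per_anchor <- do.call(rbind, rows)
  rownames(per_anchor) <- NULL
  agg <- aggregate_metrics(metrics)
  summary <- c(agg, list(
    direction = direction,
    baseline_mean_workload = mean(baseline_wl),
    workload_reduction = if (mean(baseline_wl) > 0)
      1 - agg$mean_workload / mean(baseline_wl) else 0,
    paired_p_value = if (length(es_wl) >= 2L)
      paired_workload_test(es_wl, baseline_wl) else NA_real_
  ))
  list(per_anchor = per_anchor, summary = summary, scores = scores)
}

#' Run trial-centered patient cohort identification
#'
#' For every trial: pre-filter the population, build patient profiles under
#' the trial's temporal cutoff, rank by matching score and measure the
#' screening workload against the reference standard. The random-shuffle
#' demographics-only baseline is reported as its closed-form expected
#' workload, and a paired t-test compares the two workload vectors.
#'
#' @param ctx An `espre_context` (see [load_context()]).
#' @param out_dir Optional output directory for ranked TSVs, the per-trial
#'   metrics CSV and the JSON summary.
#' @param scores Optional pre-computed matrix from [score_pairs()].
#' @return List with `per_anchor` (data.frame), `summary` (list), `scores`.
#' @export
run_trial_centered <- function(ctx, out_dir = NULL, scores = NULL) {
  res <- .run_direction(ctx, "patients_for_trial", names(ctx$trials),
                        out_dir, scores)
  if (!is.null(out_dir)) .write_reports(res, out_dir, "trial_centered")
  res
}

#' Run patient-centered trial recommendation
#'
#' Symmetric to [run_trial_centered()], ranking open trials for every
#' patient. Reports both the sub-population summary (patients with at least
#' one historical enrollment) and the full-population summary (all
#' patients; a patient with no enrollments forces review of their entire
#' post-filter trial list).
#'
#' @param ctx An `espre_context`.
#' @param out_dir Optional output directory.
#' @param scores Optional pre-computed matrix from [score_pairs()].
#' @return List with `per_anchor`, `summary` (full population),
#'   `summary_sub` (sub-population), `scores`.
#' @export
run_patient_centered <- function(ctx, out_dir = NULL, scores = NULL) {
  res <- .run_direction(ctx, "trials_for_patient", names(ctx$records),
                        out_dir, scores)
  enrolled <- unique(ctx$reference$patient_id)
  sub_anchors <- intersect(names(ctx$records), enrolled)
  res$summary_sub <- if (length(sub_anchors)) {
    .run_direction(ctx, "trials_for_patient", sub_anchors,
                   out_dir = NULL, scores = res$scores)$summary
  } else NULL
  if (!is.null(out_dir)) .write_reports(res, out_dir, "patient_centered")
  res
}

.write_reports <- function(res, out_dir, prefix) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$per_anchor,
                   file.path(out_dir, paste0(prefix, "_metrics.csv")),
                   row.names = FALSE, quote = FALSE)
  summ <- res[c("summary", "summary_sub")]
  summ <- summ[!vapply(summ, is.null, logical(1L))]
  jsonlite::write_json(summ, file.path(out_dir, paste0(prefix, "_summary.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
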