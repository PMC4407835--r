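#' Demographics and enrollment-window pre-filter
#'
#' A patient survives the pre-filter for a trial when (a) the trial accepts
#' the patient's gender (or accepts any), (b) the patient's age interval
#' over the enrollment window `[open_date, close_date]` intersects the
#' trial's age bounds (eligible on any day of the window — the least
#' restrictive reading, which never filters a truly eligible patient), and
#' (c) at least one clinical note is dated inside the window. A patient
#' with no notes in the window was not in the institution's care during
#' enrollment and is ruled out.
#'
#' @param record A `patient_record`.
#' @param trial A `trial_profile`.
#' @return `TRUE` if the patient passes the filter.
#' @export
demographics_filter <- function(record, trial) {
  if (trial$gender != "any" && trial$gender != record$gender) return(FALSE)
  age_open <- as.integer(trial$open_date - record$birth_date)
  age_close <- as.integer(trial$close_date - record$birth_date)
  if (age_close < trial$age$min_days || age_open > trial$age$max_days) {
    return(FALSE)
  }
  nd <- as.Date(record$notes$date)
  any(nd >= trial$open_date & nd <= trial$close_date)
}

#' Trial-patient matching score
#'
#' Binary cosine over signed keys with a subtractive polarity-contradiction
#' penalty:
#' \deqn{score = \frac{|T \cap P|}{\sqrt{|T||P|}} -
#'       \lambda \frac{c(T,P)}{\sqrt{|T||P|}}}
#' where \eqn{c(T,P)} counts concepts asserted on one side and negated on
#' the other. The penalty is what makes exclusion-criterion violations (a
#' trial's `NEGc` against a patient's `c`) push a candidate down the
#' ranking. Either vector empty gives score 0.
#'
#' @param trial_v,patient_v `term_vector`s (binary key sets).
#' @param lambda Contradiction penalty weight, `>= 0` (default 1).
#'   `lambda = 0` is plain cosine.
#' @return A list of class `match_score`: `value`, `shared_terms`,
#'   `contradictions`.
#' @export
match_score <- function(trial_v, patient_v, lambda = 1) {
  if (lambda < 0) stop("lambda must be non-negative")
  t_keys <- unclass(trial_v)
  p_keys <- unclass(patient_v)
  nt <- length(t_keys)
  np <- length(p_keys)
  if (nt == 0L || np == 0L) {
    return(structure(list(value = 0, shared_terms = 0L, contradictions = 0L),
                     class = "match_score"))
  }
  shared <- length(intersect(t_keys, p_keys))
  contra <- length(intersect(paste0("NEG", t_keys), p_keys)) +
    length(intersect(t_keys, paste0("NEG", p_keys)))
  denom <- sqrt(nt * np)
  structure(list(value = (shared - lambda * contra) / denom,
                 shared_terms = shared, contradictions = as.integer(contra)),
            class = "match_score")
}

.ranked_list <- function(direction, anchor_id, ids, scores) {
  items <- data.frame(
    candidate_id = ids,
    score = vapply(scores, `[[`, numeric(1L), "value"),
    shared_terms = vapply(scores, function(s) as.integer(s$shared_terms), integer(1L)),
    contradictions = vapply(scores, `[[`, integer(1L), "contradictions"),
    stringsAsFactors = FALSE
  )
  items <- items[order(-items$score, items$candidate_id), , drop = FALSE]
  items$rank <- seq_len(nrow(items))
  rownames(items) <- NULL
  structure(list(direction = direction, anchor_id = anchor_id,
                 items = items[, c("rank", "candidate_id", "score",
                                   "shared_terms", "contradictions")]),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("<ranked_list> ", x$direction, " for ", x$anchor_id, ": ",
      nrow(x$items), " candidates\n", sep = "")
  print(utils::head(x$items, 10L))
  invisible(x)
}

#' Rank patients for a trial
#'
#' Applies the demographics/window pre-filter, builds each survivor's
#' profile under this trial's temporal cutoff, scores it against the trial
#' vector and sorts descending; ties break by candidate id ascending for
#' reproducibility.
#'
#' @param trial A `trial_profile`.
#' @param records List of `patient_record`s.
#' @param index,icd9map,triggers Terminology resources.
#' @param lambda Contradiction penalty weight.
#' @param ... Passed to [build_patient_profile()] (e.g. `use_notes`).
#' @return A `ranked_list` with direction `"patients_for_trial"`.
#' @export
rank_patients_for_trial <- function(trial, records, index, icd9map = NULL,
                                    triggers = load_triggers(), lambda = 1,
                                    ...) {
  pass <- Filter(function(r) demographics_filter(r, trial), records)
  scores <- lapply(pass, function(r) {
    prof <- build_patient_profile(r, trial, index, icd9map, triggers, ...)
    match_score(trial$vector, prof$vector, lambda)
  })
  .ranked_list("patients_for_trial", trial$nct_id,
               vapply(pass, `[[`, character(1L), "patient_id"), scores)
}

#' Rank trials for a patient
#'
#' Symmetric to [rank_patients_for_trial()]: a trial is excluded when the
#' patient fails its pre-filter; the patient profile is rebuilt per trial
#' because the temporal cutoff is trial-specific.
#'
#' @param record A `patient_record`.
#' @param trials List of `trial_profile`s.
#' @param index,icd9map,triggers Terminology resources.
#' @param lambda Contradiction penalty weight.
#' @param ... Passed to [build_patient_profile()].
#' @return A `ranked_list` with direction `"trials_for_patient"`.
#' @export
rank_trials_for_patient <- function(record, trials, index, icd9map = NULL,
                                    triggers = load_triggers(), lambda = 1,
                                    ...) {
  pass <- Filter(function(tr) demographics_filter(record, tr), trials)
  scores <- lapply(pass, function(tr) {
    prof <- build_patient_profile(record, tr, index, icd9map, triggers, ...)
    match_score(tr$vector, prof$vector, lambda)
  })
  .ranked_list("trials_for_patient", record$patient_id,
               vapply(pass, `[[`, character(1L), "nct_id"), scores)
}

#' Random-shuffle baseline ranking
#'
#' The demographics-only screening baseline: candidates that passed the
#' pre-filter are ordered by a uniform random permutation, reproducible by
#' seed. Scores are absent (NA).
#'
#' @param candidates Character vector of post-filter candidate ids.
#' @param seed Integer seed (mandatory).
#' @param anchor_id Anchor id recorded on the list.
#' @return A `ranked_list` with direction `"baseline_shuffle"`.
#' @export
baseline_shuffle <- function(candidates, seed, anchor_id = "baseline") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  ord <- withr_seed(seed, sample.int(length(candidates)))
  items <- data.frame(rank = seq_along(candidates),
                      candidate_id = candidates[ord],
                      score = NA_real_, shared_terms = NA_integer_,
                      contradictions = NA_integer_, stringsAsFactors = FALSE)
  structure(list(direction = "baseline_shuffle", anchor_id = anchor_id,
                 items = items),
            class = "ranked_list")
}

# Evaluate an expression under a local RNG seed without touching the
# caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Write a ranked list to TSV
#'
#' Columns `rank`, `candidate_id`, `score`, `shared_terms`,
#' `contradictions`; the file is named `<anchor_id>.ranked.tsv`.
#'
#' @param ranked A `ranked_list`.
#' @param dir Output directory (created if needed).
#' @return The file path, invisibly.
#' @export
write_ranked_list <- function(ranked, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(ranked$anchor_id, ".ranked.tsv"))
  utils::write.table(ranked$items, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
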