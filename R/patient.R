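#' Read patient records from JSON Lines
#'
#' One JSON object per line with keys `patient_id`, `birth_date`, `gender`,
#' `diagnoses` (array of `{text, icd9, date}`), `notes` (array of
#' `{text, date}`) and `enrollments` (array of `{nct_id, date}`). When a
#' list of trial profiles is supplied, enrollment dates outside the named
#' trial's window raise a warning (the record still loads).
#'
#' @param path Path to the JSONL file.
#' @param trials Optional named list of `trial_profile`s for window checks.
#' @return A list of `patient_record` objects, named by patient id.
#' @export
read_patients <- function(path, trials = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyDataFrame = TRUE)
    rec <- patient_record(
      patient_id = obj$patient_id,
      birth_date = as.Date(obj$birth_date),
      gender = obj$gender,
      diagnoses = .as_entry_df(obj$diagnoses, c("text", "icd9", "date")),
      notes = .as_entry_df(obj$notes, c("text", "date")),
      enrollments = .as_entry_df(obj$enrollments, c("nct_id", "date"))
    )
    rec
  })
  names(recs) <- vapply(recs, `[[`, character(1L), "patient_id")
  if (!is.null(trials)) {
    for (rec in recs) {
      for (i in seq_len(nrow(rec$enrollments))) {
        tid <- rec$enrollments$nct_id[i]
        tr <- trials[[tid]]
        if (is.null(tr)) next
        d <- as.Date(rec$enrollments$date[i])
        if (d < tr$open_date || d > tr$close_date) {
          warning("enrollment of ", rec$patient_id, " in ", tid,
                  " dated outside the trial window: ", format(d))
        }
      }
    }
  }
  recs
}

.as_entry_df <- function(x, cols) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA_character_
  df[, cols, drop = FALSE]
}

#' Construct a patient record
#'
#' @param patient_id Identifier string.
#' @param birth_date Date of birth.
#' @param gender `"male"` or `"female"`.
#' @param diagnoses data.frame with columns `text`, `icd9`, `date`.
#' @param notes data.frame with columns `text`, `date`.
#' @param enrollments data.frame with columns `nct_id`, `date`.
#' @return A list of class `patient_record`.
#' @export
patient_record <- function(patient_id, birth_date, gender,
                           diagnoses = NULL, notes = NULL, enrollments = NULL) {
  diagnoses <- .as_entry_df(diagnoses, c("text", "icd9", "date"))
  notes <- .as_entry_df(notes, c("text", "date"))
  enrollments <- .as_entry_df(enrollments, c("nct_id", "date"))
  birth_date <- as.Date(birth_date)
  stopifnot(gender %in% c("male", "female"))
  all_dates <- as.Date(c(diagnoses$date, notes$date))
  if (length(all_dates) && any(all_dates < birth_date)) {
    stop("entry dated before birth for patient ", patient_id)
  }
  structure(list(patient_id = as.character(patient_id),
                 birth_date = birth_date, gender = gender,
                 diagnoses = diagnoses, notes = notes,
                 enrollments = enrollments),
            class = "patient_record")
}

#' Temporal cutoff for one patient and one trial
#'
#' Entries documented after a trial closed, or at/after the patient's own
#' enrollment in that trial, were not available when the screening decision
#' was made, so they never enter the profile. If the patient enrolled in
#' this trial, only entries strictly before the enrollment date survive;
#' otherwise entries up to and including the closing date survive (dates
#' are whole days, no clock times).
#'
#' @param record A `patient_record`.
#' @param trial A `trial_profile` (or list with `nct_id`, `close_date`).
#' @return The record with `diagnoses` and `notes` filtered.
#' @export
temporal_filter <- function(record, trial) {
  enr <- record$enrollments
  hit <- which(enr$nct_id == trial$nct_id)
  keep <- function(dates) {
    d <- as.Date(dates)
    if (length(hit)) d < as.Date(enr$date[hit[1L]])
    else d <= trial$close_date
  }
  record$diagnoses <- record$diagnoses[keep(record$diagnoses$date), , drop = FALSE]
  record$notes <- record$notes[keep(record$notes$date), , drop = FALSE]
  record
}

#' Build a patient profile for a specific trial
#'
#' After the temporal cutoff for this trial, structured diagnoses yield
#' concepts through text extraction on the diagnosis string (negation off:
#' a problem-list label asserts presence) plus the ICD-9 map, each concept
#' counted once per patient regardless of how many visits repeat it; notes
#' run through the full text pipeline (mentions, negation, raw tokens).
#' Everything is unioned into one signed vector, asserted keys winning
#' conflicts.
#'
#' @param record A `patient_record`.
#' @param trial A `trial_profile` (sets the temporal cutoff).
#' @param index An `espre_terminology`.
#' @param icd9map An `espre_icd9map` (optional: `NULL` skips code mapping).
#' @param triggers An `espre_triggers` lexicon.
#' @param include_raw_tokens Raw word keys from notes (default TRUE).
#' @param window NegEx scope window.
#' @param use_diagnoses,use_notes Toggle the two data sources (both TRUE by
#'   default; turning one off reproduces the structured-only / notes-only
#'   algorithm variants).
#' @return A list of class `patient_profile`: `patient_id`, `vector`,
#'   `note_dates` (Dates of the notes used).
#' @export
build_patient_profile <- function(record, trial, index, icd9map = NULL,
                                  triggers = load_triggers(),
                                  include_raw_tokens = TRUE, window = 5L,
                                  use_diagnoses = TRUE, use_notes = TRUE) {
  rec <- temporal_filter(record, trial)
  keys <- character(0)

  if (use_diagnoses) {
    dx_concepts <- character(0)
    for (i in seq_len(nrow(rec$diagnoses))) {
      toks <- tokenize(rec$diagnoses$text[i])
      men <- extract_mentions(toks, index)
      dx_concepts <- c(dx_concepts, men$concept_id)
      code <- rec$diagnoses$icd9[i]
      if (!is.null(icd9map) && !is.na(code) && nzchar(code)) {
        dx_concepts <- c(dx_concepts, map_icd9(code, icd9map))
      }
    }
    keys <- c(keys, unique(dx_concepts))
  }

  note_vecs <- list()
  if (use_notes) {
    for (i in seq_len(nrow(rec$notes))) {
      note_vecs[[length(note_vecs) + 1L]] <-
        text_to_vector(rec$notes$text[i], index, triggers,
                       negation = TRUE,
                       include_raw_tokens = include_raw_tokens,
                       window = window)
    }
  }
  vec <- term_vector(c(keys, unlist(note_vecs, use.names = FALSE)))
  structure(list(patient_id = record$patient_id, vector = vec,
                 note_dates = as.Date(rec$notes$date)),
            class = "patient_profile")
}
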