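#' Simulation configuration
#'
#' Parameters of the synthetic trial/EHR world. Defaults are sized for desk
#' scale: 20 trials, 100 patients, 150 concepts, 2-40 notes per patient of
#' 50-300 tokens — the order of magnitude of a pediatric oncology study
#' population, not its exact distributions. `enrollment_prob` defaults to
#' 0.9, mirroring the near-universal trial participation of eligible
#' pediatric oncology patients; `signal` is the probability that each
#' signature concept of a trial is planted into an eligible patient's
#' record, and `distractor_rate` the per-slot probability of an off-target
#' concept mention.
#'
#' @param n_trials,n_patients,n_concepts Corpus dimensions.
#' @param notes_per_patient Integer range `c(lo, hi)`.
#' @param note_length Token-count range `c(lo, hi)`.
#' @param eligible_fraction Fraction of patients truly eligible per trial.
#' @param enrollment_prob P(enrolled | eligible).
#' @param signal Planted-overlap strength in `[0, 1]`.
#' @param distractor_rate Off-target concept mention rate in `[0, 1]`.
#' @param demographic_fail_rate Fraction of patients whose demographics
#'   (age) fail every trial's filter.
#' @param female_only_fraction Fraction of trials restricted to females.
#' @param sig_size,exc_size Signature / exclusion concepts per trial.
#' @param seed Integer seed (mandatory; the whole world is a deterministic
#'   function of the config).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trials = 20L, n_patients = 100L, n_concepts = 150L,
                       notes_per_patient = c(2L, 40L),
                       note_length = c(50L, 300L),
                       eligible_fraction = 0.05, enrollment_prob = 0.9,
                       signal = 1.0, distractor_rate = 0.3,
                       demographic_fail_rate = 0.15,
                       female_only_fraction = 0.1,
                       sig_size = 4L, exc_size = 2L, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  props <- c(eligible_fraction, enrollment_prob, signal, distractor_rate,
             demographic_fail_rate, female_only_fraction)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (round(eligible_fraction * n_patients) < 1) {
    stop("infeasible config: eligible_fraction * n_patients < 1")
  }
  if (n_concepts < n_trials * (sig_size + exc_size) + 10L) {
    stop("n_concepts too small for disjoint trial signatures plus a ",
         "background pool")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Deterministic pseudo-word bank: unique 3-syllable CV words, filtered
# against stopwords and negation trigger tokens so generated terms never
# collide with function words.
.make_words <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vow, paste0))
  ns <- length(syll)
  idx <- sample.int(ns^3, n + 80L) - 1L
  words <- paste0(syll[idx %% ns + 1L],
                  syll[(idx %/% ns) %% ns + 1L],
                  syll[(idx %/% (ns^2)) %% ns + 1L])
  bad <- c(espre_stopwords(),
           unlist(strsplit(unlist(unclass(load_triggers())), " ")))
  words <- setdiff(unique(words), bad)
  if (length(words) < n) stop("word bank exhausted")
  words[seq_len(n)]
}

.filler_words <- function() {
  c("the", "and", "so", "it", "was", "that", "they", "were", "all", "then",
    "of", "to", "in", "on", "for", "as", "at", "by", "an", "or")
}

#' Build a synthetic trial/EHR world in memory
#'
#' Constructs a terminology, an ICD-9 map, trial criteria, patient records
#' and the ground truth (eligibility and sampled enrollments) as R objects.
#' Each trial owns a disjoint signature of `sig_size` concepts (mentioned in
#' its inclusion criteria) and `exc_size` exclusion concepts; eligible
#' patients carry the signature in a note written inside the enrollment
#' window before their enrollment date, plus a structured diagnosis for the
#' first signature concept; ineligible patients draw only from a background
#' concept pool disjoint from every signature. Sentence templates use
#' function-word filler only, so concept terms are the sole non-stopword
#' content. Everything is a deterministic function of `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_world`: `config`, `terminology` (data.frame),
#'   `icd9_map` (data.frame), `trials` (list), `patients` (list),
#'   `truth` (list with `eligibility` and `enrollments` data.frames).
#' @export
build_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, .build_world_impl(config))
}

.build_world_impl <- function(cfg) {
  nC <- cfg$n_concepts
  words <- .make_words(3L * nC)
  terms <- paste(words[seq(1L, 2L * nC, by = 2L)],
                 words[seq(2L, 2L * nC, by = 2L)])
  aliases <- words[(2L * nC + 1L):(3L * nC)]
  cids <- sprintf("%08d", 10000019 + seq_len(nC) * 97L)
  icd9 <- sprintf("%03d.%02d", 100L + (seq_len(nC) - 1L) %/% 100L,
                  (seq_len(nC) - 1L) %% 100L)
  terminology <- data.frame(
    concept_id = cids, preferred_term = terms,
    synonyms = paste(terms, aliases, sep = "|"),
    vocabulary = "SYNTH", stringsAsFactors = FALSE
  )
  icd9_map <- data.frame(icd9_code = icd9, concept_id = cids,
                         stringsAsFactors = FALSE)

  # concept partition: per-trial signatures, per-trial exclusions, background
  n_sig <- cfg$n_trials * cfg$sig_size
  n_exc <- cfg$n_trials * cfg$exc_size
  sig_idx <- matrix(seq_len(n_sig), nrow = cfg$n_trials, byrow = TRUE)
  exc_idx <- matrix(n_sig + seq_len(n_exc), nrow = cfg$n_trials, byrow = TRUE)
  bg_pool <- (n_sig + n_exc + 1L):nC

  base_open <- as.Date("2009-12-01")
  base_close <- as.Date("2011-10-31")

  trials <- vector("list", cfg$n_trials)
  female_only <- stats::runif(cfg$n_trials) < cfg$female_only_fraction
  for (t in seq_len(cfg$n_trials)) {
    open <- base_open + sample.int(180L, 1L) - 1L
    close <- open + 300L + sample.int(250L, 1L)
    if (close > base_close) close <- base_close
    min_y <- sample(0:1, 1L)
    max_y <- sample(c(18L, 21L, 30L), 1L)
    gender_line <- if (female_only[t]) "Female" else "Both"
    inc_lines <- paste("  - must have", terms[sig_idx[t, ]])
    exc_lines <- paste("  - has", terms[exc_idx[t, ]])
    text <- paste(c(
      sprintf("Ages Eligible for Study: %d Years to %d Years", min_y, max_y),
      sprintf("Genders Eligible for Study: %s", gender_line),
      "", "Inclusion Criteria:", "", inc_lines, "",
      "Exclusion Criteria:", "", exc_lines
    ), collapse = "\n")
    trials[[t]] <- list(
      nct_id = sprintf("NCT%08d", 10000000L + t),
      open_date = open, close_date = close, text = text,
      signature = cids[sig_idx[t, ]], exclusion = cids[exc_idx[t, ]],
      female_only = female_only[t]
    )
  }
  names(trials) <- vapply(trials, `[[`, character(1L), "nct_id")

  # patients: demographics
  pid <- sprintf("P%03d", seq_len(cfg$n_patients))
  gender <- sample(c("male", "female"), cfg$n_patients, replace = TRUE)
  n_fail <- round(cfg$demographic_fail_rate * cfg$n_patients)
  failer <- seq_len(cfg$n_patients) %in% sample.int(cfg$n_patients, n_fail)
  birth <- as.Date(ifelse(
    failer,
    as.Date("1955-01-01") + sample.int(3650L, cfg$n_patients, replace = TRUE),
    as.Date("1996-01-01") + sample.int(4380L, cfg$n_patients, replace = TRUE)
  ), origin = "1970-01-01")

  # eligibility: per trial, a subset of demographically screenable patients
  k_elig <- round(cfg$eligible_fraction * cfg$n_patients)
  elig_pairs <- list()
  for (t in seq_len(cfg$n_trials)) {
    pool <- which(!failer)
    if (trials[[t]]$female_only) pool <- pool[gender[pool] == "female"]
    k <- min(k_elig, length(pool))
    chosen <- sort(sample(pool, k))
    elig_pairs[[t]] <- chosen
  }

  # enrollment sampling
  enr_rows <- list()
  elig_rows <- list()
  enrolled_in <- vector("list", cfg$n_patients)  # trial indices per patient
  elig_in <- vector("list", cfg$n_patients)
  for (t in seq_len(cfg$n_trials)) {
    for (p in elig_pairs[[t]]) {
      elig_rows[[length(elig_rows) + 1L]] <-
        data.frame(nct_id = trials[[t]]$nct_id, patient_id = pid[p],
                   stringsAsFactors = FALSE)
      elig_in[[p]] <- c(elig_in[[p]], t)
      if (stats::runif(1L) < cfg$enrollment_prob) {
        span <- as.integer(trials[[t]]$close_date - trials[[t]]$open_date)
        enr_date <- trials[[t]]$close_date - sample.int(max(span %/% 10L, 1L), 1L) + 1L
        enr_rows[[length(enr_rows) + 1L]] <-
          data.frame(patient_id = pid[p], nct_id = trials[[t]]$nct_id,
                     enrollment_date = format(enr_date),
                     stringsAsFactors = FALSE)
        enrolled_in[[p]] <- c(enrolled_in[[p]], t)
      }
    }
  }
  eligibility <- if (length(elig_rows)) do.call(rbind, elig_rows) else
    data.frame(nct_id = character(0), patient_id = character(0))
  enrollments <- if (length(enr_rows)) do.call(rbind, enr_rows) else
    data.frame(patient_id = character(0), nct_id = character(0),
               enrollment_date = character(0))

  filler <- .filler_words()
  mk_sentence <- function(concept_idx) {
    paste("there is", terms[concept_idx], ".")
  }
  mk_note <- function(planted_idx, target_len) {
    sents <- character(0)
    if (length(planted_idx)) sents <- mk_sentence(planted_idx)
    # distractor sentences from the background pool
    n_slots <- max(1L, target_len %/% 25L)
    n_dis <- stats::rbinom(1L, n_slots, cfg$distractor_rate)
    if (n_dis > 0L) {
      sents <- c(sents, mk_sentence(sample(bg_pool, n_dis, replace = TRUE)))
    }
    body <- paste(sents, collapse = " ")
    n_have <- length(strsplit(body, " ")[[1L]])
    pad <- max(0L, target_len - n_have)
    if (pad > 0L) {
      body <- paste(c(body, sample(filler, pad, replace = TRUE)), collapse = " ")
    }
    trimws(body)
  }

  patients <- vector("list", cfg$n_patients)
  for (p in seq_len(cfg$n_patients)) {
    n_notes <- sample(cfg$notes_per_patient[1L]:cfg$notes_per_patient[2L], 1L)
    lens <- sample(cfg$note_length[1L]:cfg$note_length[2L], n_notes,
                   replace = TRUE)
    dates <- base_open + sample.int(as.integer(base_close - base_open) + 1L,
                                    n_notes, replace = TRUE) - 1L
    notes <- data.frame(text = vapply(lens, function(L) mk_note(integer(0), L),
                                      character(1L)),
                        date = format(dates), stringsAsFactors = FALSE)
    diagnoses <- data.frame(text = character(0), icd9 = character(0),
                            date = character(0), stringsAsFactors = FALSE)
    enr <- data.frame(nct_id = character(0), date = character(0),
                      stringsAsFactors = FALSE)

    for (t in elig_in[[p]]) {
      tr <- trials[[t]]
      enr_here <- t %in% enrolled_in[[p]]
      enr_date <- if (enr_here) {
        as.Date(enrollments$enrollment_date[
          enrollments$patient_id == pid[p] & enrollments$nct_id == tr$nct_id])
      } else NA
      # anchor note: inside the window, strictly before any enrollment date
      span <- as.integer(tr$close_date - tr$open_date)
      anchor_date <- tr$open_date + sample.int(max(span %/% 2L, 1L), 1L) - 1L
      if (enr_here && anchor_date >= enr_date) anchor_date <- enr_date - 1L
      sig_local <- which(cids %in% tr$signature)
      planted <- sig_local[stats::runif(length(sig_local)) < cfg$signal]
      anchor_text <- mk_note(planted, sample(cfg$note_length[1L]:
                                               cfg$note_length[2L], 1L))
      notes <- rbind(notes, data.frame(text = anchor_text,
                                       date = format(anchor_date),
                                       stringsAsFactors = FALSE))
      if (length(planted)) {
        diagnoses <- rbind(diagnoses, data.frame(
          text = terms[planted[1L]], icd9 = icd9[planted[1L]],
          date = format(anchor_date), stringsAsFactors = FALSE))
      }
      if (enr_here) {
        enr <- rbind(enr, data.frame(nct_id = tr$nct_id,
                                     date = format(enr_date),
                                     stringsAsFactors = FALSE))
      }
    }
    # screenable non-eligible patients occasionally get a background diagnosis
    if (!failer[p] && length(elig_in[[p]]) == 0L && stats::runif(1L) < 0.5) {
      b <- sample(bg_pool, 1L)
      diagnoses <- rbind(diagnoses, data.frame(
        text = terms[b], icd9 = icd9[b],
        date = format(notes$date[1L]), stringsAsFactors = FALSE))
    }
    patients[[p]] <- list(patient_id = pid[p], birth_date = format(birth[p]),
                          gender = gender[p], diagnoses = diagnoses,
                          notes = notes, enrollments = enr)
  }
  names(patients) <- pid

  structure(list(config = cfg, terminology = terminology, icd9_map = icd9_map,
                 trials = trials, patients = patients,
                 truth = list(eligibility = eligibility,
                              enrollments = enrollments)),
            class = "sim_world")
}

#' Write a synthetic world to disk in the pipeline's input formats
#'
#' Writes `terminology.tsv`, `icd9_map.tsv`, one trial file per trial under
#' `trials/`, `patients.jsonl`, `reference.csv` (the sampled enrollments),
#' `eligibility.csv` (the full truth) and `simconfig.json`.
#'
#' @param world A `sim_world`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "sim_world"))
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(world$terminology, file.path(dir, "terminology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$icd9_map, file.path(dir, "icd9_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (tr in world$trials) {
    lines <- c(paste0("NCT_ID: ", tr$nct_id),
               paste0("OPEN_DATE: ", format(tr$open_date)),
               paste0("CLOSE_DATE: ", format(tr$close_date)),
               "", tr$text)
    writeLines(lines, file.path(dir, "trials", paste0(tr$nct_id, ".txt")))
  }
  con <- file(file.path(dir, "patients.jsonl"), open = "w", encoding = "UTF-8")
  for (p in world$patients) {
    writeLines(jsonlite::toJSON(p, dataframe = "rows", auto_unbox = TRUE), con)
  }
  close(con)
  utils::write.csv(world$truth$enrollments, file.path(dir, "reference.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(world$truth$eligibility, file.path(dir, "eligibility.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- world$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "simconfig.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Generate a synthetic world and write it to disk
#'
#' @param config A `sim_config`.
#' @param dir Output directory.
#' @return The `sim_world`, invisibly.
#' @export
generate_world <- function(config, dir) {
  world <- build_world(config)
  write_world(world, dir)
  invisible(world)
}

#' Apply a controlled corruption to a synthetic world
#'
#' Stress harness for robustness experiments that mimic real error modes
#' (disease sub-category confusion, wrong assertion status, stale entries):
#' \describe{
#'   \item{typo_injection}{each non-filler word in a note is mutated (two
#'     adjacent characters swapped) with probability `rate`, breaking
#'     dictionary matches;}
#'   \item{negation_flip}{each planted concept sentence gains a leading
#'     negation trigger with probability `rate`, flipping its polarity;}
#'   \item{date_shift}{each note is shifted 1000 days into the future with
#'     probability `rate`, pushing it past temporal cutoffs.}
#' }
#'
#' @param world A `sim_world`.
#' @param op One of `"typo_injection"`, `"negation_flip"`, `"date_shift"`.
#' @param rate Corruption rate in `[0, 1]`.
#' @param seed Integer seed.
#' @return The corrupted `sim_world`.
#' @export
corrupt_world <- function(world, op, rate, seed) {
  stopifnot(inherits(world, "sim_world"), rate >= 0, rate <= 1)
  if (!op %in% c("typo_injection", "negation_flip", "date_shift")) {
    stop("unknown corruption op: ", op)
  }
  if (rate == 0) return(world)
  withr_seed(seed, {
    filler <- c(.filler_words(), "there", "is", ".")
    for (p in names(world$patients)) {
      notes <- world$patients[[p]]$notes
      for (i in seq_len(nrow(notes))) {
        if (op == "date_shift") {
          if (stats::runif(1L) < rate) {
            notes$date[i] <- format(as.Date(notes$date[i]) + 1000L)
          }
        } else if (op == "typo_injection") {
          ws <- strsplit(notes$text[i], " ", fixed = TRUE)[[1L]]
          for (j in seq_along(ws)) {
            w <- ws[j]
            if (w %in% filler || nchar(w) < 3L) next
            if (stats::runif(1L) < rate) {
              k <- nchar(w) - 1L
              ws[j] <- paste0(substr(w, 1L, k - 1L),
                              substr(w, k + 1L, k + 1L), substr(w, k, k))
            }
          }
          notes$text[i] <- paste(ws, collapse = " ")
        } else if (op == "negation_flip") {
          notes$text[i] <- gsub("there is ", "there is no ", notes$text[i],
                                fixed = TRUE)
          if (rate < 1) {
            # re-flip a (1 - rate) share back deterministically
            parts <- strsplit(notes$text[i], "there is no ", fixed = TRUE)[[1L]]
            if (length(parts) > 1L) {
              keep <- stats::runif(length(parts) - 1L) < rate
              sep <- ifelse(keep, "there is no ", "there is ")
              notes$text[i] <- paste0(parts[1L],
                                      paste0(sep, parts[-1L], collapse = ""))
            }
          }
        }
      }
      world$patients[[p]]$notes <- notes
    }
    world
  })
}
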