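# Shared fixtures and independent oracles for the test suite.

fixture_index <- function() {
  load_terminology(system.file("extdata", "mini_terminology.tsv",
                               package = "espre"))
}

fixture_icd9 <- function(index = NULL) {
  load_icd9_map(system.file("extdata", "icd9_to_concept.tsv",
                            package = "espre"), index)
}

# Build a terminology index from in-code rows: list(c(id, pref, "s1|s2")).
tiny_index <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  lines <- c("concept_id\tpreferred_term\tsynonyms\tvocabulary",
             vapply(rows, function(r) paste(r[1], r[2], r[3], "TEST",
                                            sep = "\t"), character(1)))
  writeLines(lines, path)
  load_terminology(path)
}

# Oracle: leftmost-longest dictionary matching by exhaustive sub-span
# enumeration (independent of the scanning implementation).
oracle_mentions <- function(token_texts, phrases) {
  # phrases: named character vector phrase -> concept_id
  n <- length(token_texts)
  out <- list()
  i <- 1
  while (i <= n) {
    best_len <- 0
    best_id <- NA
    for (j in n:i) {           # longest first
      cand <- paste(token_texts[i:j], collapse = " ")
      if (!is.na(phrases[cand])) {
        best_len <- j - i + 1
        best_id <- unname(phrases[cand])
        break
      }
    }
    if (best_len > 0) {
      out[[length(out) + 1]] <- list(concept_id = best_id,
                                     span_start = i - 1L,
                                     span_end = i - 1L + best_len)
      i <- i + best_len
    } else {
      i <- i + 1
    }
  }
  out
}

# Oracle: negation scope by literal enumeration of the rule — for a mention
# at token ms (0-based), scan every pre-trigger occurrence, check distance
# and interveners directly.
oracle_negated <- function(token_texts, ms, triggers, window = 5) {
  occ <- function(phrases) {
    res <- list()
    for (ph in phrases) {
      w <- strsplit(ph, " ")[[1]]
      L <- length(w)
      if (L > length(token_texts)) next
      for (i in seq_len(length(token_texts) - L + 1)) {
        if (all(token_texts[i:(i + L - 1)] == w)) {
          res[[length(res) + 1]] <- c(i - 1, i - 1 + L)
        }
      }
    }
    res
  }
  pre <- occ(triggers$pre)
  pseudo <- occ(triggers$pseudo)
  term <- occ(triggers$term)
  inside_pseudo <- function(span) {
    any(vapply(pseudo, function(p) p[1] <= span[1] && span[2] <= p[2],
               logical(1)))
  }
  for (tr in pre) {
    if (inside_pseudo(tr)) next
    if (tr[2] > ms || ms - tr[2] > window) next
    blocked <- any(vapply(c(term, pseudo), function(b)
      b[1] >= tr[2] && b[2] <= ms, logical(1)))
    if (!blocked) return(TRUE)
  }
  FALSE
}

# Oracle: expected maximum rank of k positives uniformly placed among N
# candidates, by exhaustive enumeration of position sets.
oracle_expected_max_rank <- function(N, k) {
  if (k == 0) return(N)
  sets <- utils::combn(N, k)
  mean(apply(sets, 2, max))
}

# Make a minimal patient record quickly.
quick_patient <- function(id = "P1", birth = "2000-01-01", gender = "male",
                          notes = NULL, diagnoses = NULL, enrollments = NULL) {
  patient_record(id, birth, gender, diagnoses = diagnoses, notes = notes,
                 enrollments = enrollments)
}

# Make a trial profile without text parsing, for matching/evaluation tests.
quick_trial <- function(nct_id = "NCT00000001", open = "2010-01-01",
                        close = "2010-12-31", min_days = 0, max_days = Inf,
                        gender = "any", keys = character(0)) {
  structure(list(nct_id = nct_id, age = list(min_days = min_days,
                                             max_days = max_days),
                 gender = gender, open_date = as.Date(open),
                 close_date = as.Date(close), vector = term_vector(keys)),
            class = "trial_profile")
}
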