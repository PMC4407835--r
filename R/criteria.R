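DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.44

#' Split an eligibility description into inclusion and exclusion text
#'
#' Splits at the case-insensitive headers "Inclusion Criteria" and
#' "Exclusion Criteria" (trailing colon optional). A missing exclusion
#' header yields empty exclusion text; a missing inclusion header is an
#' error, because criteria without an inclusion section are unusable.
#'
#' @param text Eligibility description.
#' @return A list with elements `inclusion` and `exclusion`.
#' @export
split_sections <- function(text) {
  inc <- regexpr("inclusion criteria\\s*:?", text, ignore.case = TRUE)
  if (inc == -1L) stop("no 'Inclusion Criteria' header found in eligibility text")
  exc <- regexpr("exclusion criteria\\s*:?", text, ignore.case = TRUE)
  inc_from <- as.integer(inc) + attr(inc, "match.length")
  if (exc == -1L) {
    return(list(inclusion = trimws(substring(text, inc_from)), exclusion = ""))
  }
  if (exc < inc) stop("'Exclusion Criteria' header precedes 'Inclusion Criteria'")
  list(
    inclusion = trimws(substring(text, inc_from, as.integer(exc) - 1L)),
    exclusion = trimws(substring(text, as.integer(exc) + attr(exc, "match.length")))
  )
}

.unit_days <- function(unit) {
  switch(tolower(sub("s$", "", unit)),
         year = DAYS_PER_YEAR, month = DAYS_PER_MONTH, day = 1,
         stop("unknown age unit: ", unit))
}

#' Extract age bounds from eligibility text
#'
#' Recognizes, in order (first match wins):
#' \itemize{
#'   \item "X Year(s)/Month(s)/Day(s) to Y ..." (the ClinicalTrials.gov
#'     "Ages Eligible for Study" dialect) — inclusive bounds;
#'   \item "at most / no more than / <= N years" — inclusive maximum;
#'   \item "younger than / under / < N years" — exclusive maximum;
#'   \item "at least / >= N years" — inclusive minimum;
#'   \item "older than / over / > N years" — exclusive minimum.
#' }
#' Durations convert at 365.25 days/year and 30.44 days/month and are
#' rounded to whole days; exclusive bounds become the tightest inclusive
#' whole-day bound. Absent age language leaves a side unbounded.
#'
#' @param text Eligibility description.
#' @return A list `(min_days, max_days)`; `0` and `Inf` mark unbounded sides.
#' @export
extract_age_bounds <- function(text) {
  num <- "([0-9]+(?:\\.[0-9]+)?)"
  unit <- "(years?|months?|days?)"
  to_days <- function(n, u) as.numeric(n) * .unit_days(u)

  m <- regmatches(text, regexec(
    paste0(num, "\\s*", unit, "\\s+to\\s+", num, "\\s*", unit),
    text, ignore.case = TRUE))[[1L]]
  if (length(m)) {
    lo <- round(to_days(m[2L], m[3L]))
    hi <- round(to_days(m[4L], m[5L]))
    if (lo > hi) stop("contradictory age bounds: min ", lo, "d > max ", hi, "d")
    return(list(min_days = lo, max_days = hi))
  }

  pats <- list(
    list(re = paste0("(?:at most|no more than|not older than|<=|≤)\\s*",
                     num, "\\s*", unit),
         side = "max", excl = FALSE),
    list(re = paste0("(?:younger than|under|less than|<)\\s*", num, "\\s*", unit),
         side = "max", excl = TRUE),
    list(re = paste0("(?:at least|no younger than|>=|≥)\\s*", num, "\\s*", unit),
         side = "min", excl = FALSE),
    list(re = paste0("(?:older than|over|more than|>)\\s*", num, "\\s*", unit),
         side = "min", excl = TRUE)
  )
  lo <- 0
  hi <- Inf
  for (p in pats) {
    m <- regmatches(text, regexec(p$re, text, ignore.case = TRUE))[[1L]]
    if (!length(m)) next
    d <- to_days(m[2L], m[3L])
    if (p$side == "max") {
      hi <- if (p$excl) ceiling(d) - 1 else round(d)
    } else {
      lo <- if (p$excl) floor(d) + 1 else round(d)
    }
    break  # first matching pattern wins
  }
  if (lo > hi) stop("contradictory age bounds: min ", lo, "d > max ", hi, "d")
  list(min_days = lo, max_days = hi)
}

#' Extract the gender constraint from eligibility text
#'
#' "female(s) only" / "women" map to `"female"`, "male(s) only" / "men" to
#' `"male"`; "both" or absent gender language maps to `"any"`.
#'
#' @param text Eligibility description.
#' @return One of `"male"`, `"female"`, `"any"`.
#' @export
extract_gender <- function(text) {
  t <- tolower(text)
  if (grepl("\\bboth\\b", t)) return("any")
  if (grepl("females?\\s+(patients\\s+)?only|\\bwomen\\b|female\\s+patients\\s+only|gender[s]?[^.]*:\\s*female", t)) {
    return("female")
  }
  if (grepl("\\bmales?\\s+(patients\\s+)?only|\\bmen\\b|male\\s+patients\\s+only|gender[s]?[^.]*:\\s*male", t)) {
    return("male")
  }
  "any"
}

# Strip bullet markers and numbering from criteria lines before tokenization.
.strip_bullets <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- sub("^\\s*(?:[-*•·]|[0-9]+[.)])\\s*", "", lines, perl = TRUE)
  paste(lines, collapse = "\n")
}

#' Read a trial criteria file
#'
#' Format: UTF-8 text with header lines `NCT_ID: NCTxxxxxxxx`,
#' `OPEN_DATE: YYYY-MM-DD`, `CLOSE_DATE: YYYY-MM-DD`, a blank line, then the
#' eligibility description verbatim.
#'
#' @param path Path to a trial file.
#' @return A list of class `trial_criteria` with `nct_id`, `open_date`,
#'   `close_date` (Date) and `text`.
#' @export
read_trial_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(hit)) stop("trial file missing ", key, " header: ", path)
    trimws(sub(paste0("^", key, ":"), "", hit[1L]))
  }
  nct <- get_field("NCT_ID")
  if (!grepl("^NCT[0-9]{8}$", nct)) stop("invalid NCT id: ", nct)
  open <- as.Date(get_field("OPEN_DATE"))
  close <- as.Date(get_field("CLOSE_DATE"))
  if (is.na(open) || is.na(close)) stop("invalid trial dates in ", path)
  if (open > close) stop("trial open date after close date: ", nct)
  blank <- which(!nzchar(trimws(lines)))[1L]
  body <- if (is.na(blank)) "" else paste(lines[(blank + 1L):length(lines)],
                                          collapse = "\n")
  structure(list(nct_id = nct, open_date = open, close_date = close,
                 text = body),
            class = "trial_criteria")
}

#' Build a trial profile from parsed criteria
#'
#' The inclusion section is vectorized through the standard text pipeline
#' (with negation detection, so "No CNS disease" written inside inclusion
#' yields a negated key directly). The exclusion section is vectorized the
#' same way and then polarity-flipped, implementing the rule that exclusion
#' terms enter the trial vector in negated form. The profile vector is the
#' union. Age bounds, gender and the enrollment window come from the same
#' description.
#'
#' Note the mechanical consequence for doubly negated exclusions: "no prior
#' chemotherapy" under Exclusion is negated by the detector and re-asserted
#' by the flip, ending as an asserted prior-chemotherapy key. Whether that
#' composition or a flip of raw asserted terms is wanted is controlled by
#' `negex_in_exclusion`.
#'
#' @param criteria A `trial_criteria` (from [read_trial_file()]) or a list
#'   with the same fields.
#' @param index An `espre_terminology`.
#' @param triggers An `espre_triggers` lexicon.
#' @param include_raw_tokens Include raw word keys (default TRUE).
#' @param negex_in_exclusion Run negation detection inside the exclusion
#'   section before flipping (default TRUE).
#' @param window NegEx scope window.
#' @return A list of class `trial_profile`: `nct_id`, `age`
#'   (min_days/max_days), `gender`, `open_date`, `close_date`, `vector`.
#' @export
build_trial_profile <- function(criteria, index, triggers = load_triggers(),
                                include_raw_tokens = TRUE,
                                negex_in_exclusion = TRUE, window = 5L) {
  secs <- split_sections(criteria$text)
  inc_v <- text_to_vector(.strip_bullets(secs$inclusion), index, triggers,
                          negation = TRUE,
                          include_raw_tokens = include_raw_tokens,
                          window = window)
  exc_v <- term_vector()
  if (nzchar(secs$exclusion)) {
    exc_v <- text_to_vector(.strip_bullets(secs$exclusion), index, triggers,
                            negation = negex_in_exclusion,
                            include_raw_tokens = include_raw_tokens,
                            window = window)
    exc_v <- flip_polarity(exc_v)
  }
  structure(
    list(nct_id = criteria$nct_id,
         age = extract_age_bounds(criteria$text),
         gender = extract_gender(criteria$text),
         open_date = criteria$open_date,
         close_date = criteria$close_date,
         vector = tv_union(inc_v, exc_v)),
    class = "trial_profile"
  )
}

#' @export
print.trial_profile <- function(x, ...) {
  cat("<trial_profile> ", x$nct_id, "  window ", format(x$open_date), "..",
      format(x$close_date), "  age [", x$age$min_days, ", ",
      ifelse(is.finite(x$age$max_days), x$age$max_days, "Inf"),
      "] days  gender ", x$gender, "  |v| = ", length(x$vector), "\n", sep = "")
  invisible(x)
}
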