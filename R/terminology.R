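#' Normalize clinical text
#'
#' Lowercases, replaces every character outside `[a-z0-9]` with a space and
#' collapses runs of whitespace. This is the single normalization used
#' everywhere a phrase is compared against the terminology, so dictionary
#' lookup is case- and punctuation-insensitive by construction.
#'
#' @param x Character vector.
#' @return Character vector of normalized strings.
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Load a flat-file terminology and build a phrase index
#'
#' Reads a tab-separated terminology with columns `concept_id`,
#' `preferred_term`, `synonyms` (pipe-separated) and `vocabulary`, and
#' indexes every synonym (the preferred term is always indexed as a synonym
#' of itself) under its normalized token sequence. The index is the
#' dictionary used for longest-match concept extraction; it stands in for a
#' full licensed vocabulary, of which the matching pipeline only needs the
#' phrase-to-code contract.
#'
#' @param path Path to the terminology TSV (header row required).
#' @return An object of class `espre_terminology` with elements
#'   `concepts` (data.frame of the loaded rows), `phrase_map` (environment
#'   mapping normalized phrase to concept id) and `max_phrase_len`
#'   (longest indexed phrase, in tokens).
#' @export
load_terminology <- function(path) {
  if (!file.exists(path)) stop("terminology file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(raw) == 0L) stop("terminology file is empty (header row required): ", path)
  header <- strsplit(raw[1L], "\t", fixed = TRUE)[[1L]]
  required <- c("concept_id", "preferred_term", "synonyms", "vocabulary")
  if (!identical(tolower(header)[seq_along(required)], required)) {
    stop("terminology header must be: ", paste(required, collapse = "\t"))
  }
  body <- raw[-1L]
  body <- body[nzchar(trimws(body))]

  concepts <- data.frame(
    concept_id = character(0), preferred_term = character(0),
    synonyms = character(0), vocabulary = character(0),
    stringsAsFactors = FALSE
  )
  phrase_map <- new.env(parent = emptyenv(), hash = TRUE)
  max_len <- 0L
  seen_ids <- new.env(parent = emptyenv(), hash = TRUE)

  for (i in seq_along(body)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 4L || !nzchar(fields[1L])) {
      stop("malformed terminology row at line ", i + 1L, ": ", body[i])
    }
    cid <- fields[1L]
    if (!is.null(seen_ids[[cid]])) {
      stop("duplicate concept_id at line ", i + 1L, ": ", cid)
    }
    seen_ids[[cid]] <- TRUE
    syns <- strsplit(fields[3L], "|", fixed = TRUE)[[1L]]
    syns <- unique(c(fields[2L], syns))
    syns <- syns[nzchar(trimws(syns))]
    if (length(syns) == 0L) stop("concept with no synonyms at line ", i + 1L, ": ", cid)
    for (s in syns) {
      key <- normalize_text(s)
      if (!nzchar(key)) next
      prev <- phrase_map[[key]]
      if (!is.null(prev) && !identical(prev, cid)) {
        stop("phrase '", key, "' maps to two concepts: ", prev, " and ", cid)
      }
      phrase_map[[key]] <- cid
      max_len <- max(max_len, length(strsplit(key, " ", fixed = TRUE)[[1L]]))
    }
    concepts[nrow(concepts) + 1L, ] <- list(cid, fields[2L], fields[3L], fields[4L])
  }

  structure(
    list(concepts = concepts, phrase_map = phrase_map, max_phrase_len = max_len),
    class = "espre_terminology"
  )
}

#' @export
print.espre_terminology <- function(x, ...) {
  cat("<espre_terminology> ", nrow(x$concepts), " concepts, ",
      length(ls(x$phrase_map)), " indexed phrases, max phrase length ",
      x$max_phrase_len, " tokens\n", sep = "")
  invisible(x)
}

#' Look up a normalized phrase in a terminology index
#'
#' @param index An `espre_terminology`.
#' @param phrase A raw phrase; it is normalized before lookup.
#' @return The concept id, or `NA_character_` if the phrase is not indexed.
#' @export
lookup_phrase <- function(index, phrase) {
  stopifnot(inherits(index, "espre_terminology"))
  hit <- index$phrase_map[[normalize_text(phrase)]]
  if (is.null(hit)) NA_character_ else hit
}

#' Normalize an ICD-9 code to dotted form
#'
#' EHR extracts carry ICD-9 codes both with and without the decimal point
#' ("204.00" and "20400"). Codes are normalized to the dotted dialect before
#' any map lookup: the dot sits after the third character (after the fourth
#' for E-codes).
#'
#' @param code ICD-9 code string, dotted or undotted, optionally V/E-prefixed.
#' @return The dotted code string.
#' @export
normalize_icd9 <- function(code) {
  code <- toupper(trimws(code))
  if (grepl("^E\\d{3}(\\.\\d{1})?$", code) || grepl("^E\\d{4}$", code)) {
    if (!grepl(".", code, fixed = TRUE) && nchar(code) > 4L) {
      code <- paste0(substr(code, 1L, 4L), ".", substring(code, 5L))
    }
    return(code)
  }
  if (!grepl("^[V0-9]\\d{2}(\\.\\d{1,2})?$", code) &&
      !grepl("^[V0-9]\\d{2}\\d{1,2}$", code)) {
    stop("syntactically invalid ICD-9 code: ", code)
  }
  if (!grepl(".", code, fixed = TRUE) && nchar(code) > 3L) {
    code <- paste0(substr(code, 1L, 3L), ".", substring(code, 4L))
  }
  code
}

#' Load an ICD-9 to concept map
#'
#' Reads a two-column TSV (`icd9_code`, `concept_id`). When a terminology is
#' supplied, every target concept id must exist in it.
#'
#' @param path Path to the map TSV (header row required).
#' @param terminology Optional `espre_terminology` used to validate targets.
#' @return An object of class `espre_icd9map` (named character vector,
#'   names are dotted ICD-9 codes).
#' @export
load_icd9_map <- function(path, terminology = NULL) {
  if (!file.exists(path)) stop("ICD-9 map file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("icd9_code", "concept_id") %in% names(tab))) {
    stop("ICD-9 map header must contain icd9_code and concept_id")
  }
  codes <- vapply(tab$icd9_code, normalize_icd9, character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(codes)) {
    stop("duplicate ICD-9 code in map: ", codes[duplicated(codes)][1L])
  }
  if (!is.null(terminology)) {
    known <- terminology$concepts$concept_id
    bad <- setdiff(tab$concept_id, known)
    if (length(bad)) stop("ICD-9 map targets unknown concept id(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(stats::setNames(tab$concept_id, codes), class = "espre_icd9map")
}

#' Map an ICD-9 code to concept ids
#'
#' The code is normalized to dotted form first. An unknown (but well-formed)
#' code returns an empty vector: structured problem lists routinely carry
#' codes outside any bundled map and must not abort a run.
#'
#' @param code ICD-9 code string.
#' @param map An `espre_icd9map`.
#' @return Character vector of concept ids (length 0 or 1).
#' @export
map_icd9 <- function(code, map) {
  stopifnot(inherits(map, "espre_icd9map"))
  key <- normalize_icd9(code)
  hit <- unname(map[key])
  hit[!is.na(hit)]
}
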