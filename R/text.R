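#' Tokenize free text
#'
#' Splits text into lowercase alphanumeric tokens, keeping the 0-based
#' character offsets of each token in the original string (`end` exclusive).
#' Anything outside `[A-Za-z0-9]` separates tokens, matching the
#' normalization used by the terminology index, so a token sequence can be
#' compared against indexed phrases directly.
#'
#' @param text A single character string (may be empty).
#' @return A data.frame with columns `text`, `start`, `end`; zero rows for
#'   empty input.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(text = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[A-Za-z0-9]+", text)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(text = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(
    text = tolower(substring(text, starts, starts + lens - 1L)),
    start = starts - 1L,
    end = starts + lens - 1L,
    stringsAsFactors = FALSE
  )
}

#' Extract concept mentions by greedy longest dictionary match
#'
#' Scans the token sequence left to right; at each position the longest
#' indexed phrase starting there wins, the cursor jumps past it, and matched
#' spans never overlap. All mentions start out asserted; polarity is decided
#' later by [detect_negation()].
#'
#' @param tokens Token data.frame from [tokenize()].
#' @param index An `espre_terminology`.
#' @return A data.frame with columns `concept_id`, `span_start`, `span_end`
#'   (0-based token indices, half-open) and `polarity` (all "asserted").
#' @export
extract_mentions <- function(tokens, index) {
  stopifnot(inherits(index, "espre_terminology"))
  n <- nrow(tokens)
  out <- list()
  i <- 1L
  maxlen <- max(index$max_phrase_len, 1L)
  while (i <= n) {
    hit_len <- 0L
    hit_id <- NA_character_
    upper <- min(maxlen, n - i + 1L)
    for (len in seq_len(upper)) {
      key <- paste(tokens$text[i:(i + len - 1L)], collapse = " ")
      cid <- index$phrase_map[[key]]
      if (!is.null(cid)) {
        hit_len <- len
        hit_id <- cid
      }
    }
    if (hit_len > 0L) {
      out[[length(out) + 1L]] <- list(concept_id = hit_id,
                                      span_start = i - 1L,
                                      span_end = i - 1L + hit_len)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(concept_id = character(0), span_start = integer(0),
                      span_end = integer(0), polarity = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    concept_id = vapply(out, `[[`, character(1L), "concept_id"),
    span_start = vapply(out, `[[`, integer(1L), "span_start"),
    span_end = vapply(out, `[[`, integer(1L), "span_end"),
    polarity = "asserted",
    stringsAsFactors = FALSE
  )
}

#' Load a negation trigger lexicon
#'
#' Plain text, one phrase per line, with section headers `[PRE]`
#' (pre-negation triggers such as "no", "denies"), `[PSEUDO]`
#' (pseudo-negations such as "not only" that look like triggers but negate
#' nothing) and `[TERM]` (scope terminators such as "but"). Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path Path to the lexicon file; the default is the lexicon bundled
#'   with the package.
#' @return A list with character-vector elements `pre`, `pseudo`, `term`
#'   (each phrase normalized), of class `espre_triggers`.
#' @export
load_triggers <- function(path = system.file("extdata", "negex_triggers.txt",
                                             package = "espre")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(pre = character(0), pseudo = character(0), term = character(0))
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[(PRE|PSEUDO|TERM)\\]$", ln)) {
      section <- tolower(gsub("\\[|\\]", "", ln))
      next
    }
    if (is.null(section)) stop("trigger lexicon line before any section: ", ln)
    out[[section]] <- c(out[[section]], normalize_text(ln))
  }
  structure(out, class = "espre_triggers")
}

# Token lengths of each phrase in a normalized phrase list.
.phrase_token_lens <- function(phrases) {
  vapply(strsplit(phrases, " ", fixed = TRUE), length, integer(1L))
}

# Locate occurrences of normalized multi-token phrases in a token sequence.
# Returns a data.frame (start, end: 0-based half-open token indices).
.find_phrase_spans <- function(token_texts, phrases) {
  hits <- list()
  lens <- .phrase_token_lens(phrases)
  n <- length(token_texts)
  for (p in seq_along(phrases)) {
    L <- lens[p]
    if (L > n) next
    words <- strsplit(phrases[p], " ", fixed = TRUE)[[1L]]
    for (i in seq_len(n - L + 1L)) {
      if (all(token_texts[i:(i + L - 1L)] == words)) {
        hits[[length(hits) + 1L]] <- c(i - 1L, i - 1L + L)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, hits)
  data.frame(start = m[, 1L], end = m[, 2L])
}

#' Detect negated concept mentions (NegEx-style)
#'
#' A mention becomes negated when a pre-negation trigger phrase ends within
#' `window` tokens before the mention's first token, with no scope
#' terminator and no pseudo-negation phrase between the trigger and the
#' mention. A trigger occurrence that is part of a pseudo-negation phrase
#' ("not" inside "not only") does not negate. Only pre-negation triggers are
#' implemented; the lexicon is a plain file so users can extend it.
#'
#' @param tokens Token data.frame from [tokenize()].
#' @param mentions Mention data.frame from [extract_mentions()].
#' @param triggers An `espre_triggers` lexicon (default: bundled lexicon).
#' @param window Scope window in tokens between trigger end and mention
#'   start (default 5, the customary NegEx scope).
#' @return The mention data.frame with `polarity` set to "negated" where the
#'   rule fires; concept ids and spans are never changed.
#' @export
detect_negation <- function(tokens, mentions,
                            triggers = load_triggers(), window = 5L) {
  stopifnot(inherits(triggers, "espre_triggers"))
  if (nrow(mentions) == 0L) return(mentions)
  txt <- tokens$text
  pre_spans <- .find_phrase_spans(txt, triggers$pre)
  pseudo_spans <- .find_phrase_spans(txt, triggers$pseudo)
  term_spans <- .find_phrase_spans(txt, triggers$term)

  # drop pre-trigger occurrences contained in a pseudo-negation occurrence
  if (nrow(pre_spans) && nrow(pseudo_spans)) {
    keep <- vapply(seq_len(nrow(pre_spans)), function(i) {
      !any(pseudo_spans$start <= pre_spans$start[i] &
             pre_spans$end[i] <= pseudo_spans$end)
    }, logical(1L))
    pre_spans <- pre_spans[keep, , drop = FALSE]
  }
  blockers <- rbind(term_spans, pseudo_spans)

  for (k in seq_len(nrow(mentions))) {
    ms <- mentions$span_start[k]
    if (nrow(pre_spans) == 0L) break
    cand <- pre_spans[pre_spans$end <= ms & (ms - pre_spans$end) <= window, ,
                      drop = FALSE]
    if (nrow(cand) == 0L) next
    # nearest qualifying trigger; blocked if any terminator/pseudo starts
    # between the trigger end and the mention start
    negated <- FALSE
    for (j in order(-cand$end)) {
      te <- cand$end[j]
      blocked <- nrow(blockers) > 0L &&
        any(blockers$start >= te & blockers$end <= ms)
      if (!blocked) {
        negated <- TRUE
        break
      }
    }
    if (negated) mentions$polarity[k] <- "negated"
  }
  mentions
}

#' Load the bundled stopword list
#'
#' Roughly 150 English function words excluded from raw-token vector keys.
#'
#' @return Character vector of stopwords.
#' @export
espre_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "espre")
  readLines(path, warn = FALSE)
}

#' Build a signed bag-of-words term vector
#'
#' Asserted mentions contribute their concept id as key `"c"`, negated
#' mentions `"NEGc"`. With `include_raw_tokens`, every non-stopword token
#' outside any mention span contributes a raw key `"w:"<token>`. Weights are
#' binary: a vector is a set of keys. A vector never holds both `"c"` and
#' `"NEGc"`: the asserted key wins, on the view that clinical text asserting
#' a finding anywhere outweighs a negated mention of it for matching.
#'
#' @param mentions Mention data.frame (after negation detection).
#' @param tokens Token data.frame the mentions refer to.
#' @param include_raw_tokens Add raw word keys for uncovered tokens
#'   (default TRUE, the setting used for notes and criteria; structured
#'   diagnosis strings are vectorized without raw tokens).
#' @param stopwords Stopword list for raw keys.
#' @return A `term_vector`: sorted character set of signed keys.
#' @export
to_term_vector <- function(mentions, tokens, include_raw_tokens = TRUE,
                           stopwords = espre_stopwords()) {
  keys <- character(0)
  if (nrow(mentions)) {
    keys <- ifelse(mentions$polarity == "negated",
                   paste0("NEG", mentions$concept_id),
                   mentions$concept_id)
  }
  if (include_raw_tokens && nrow(tokens)) {
    covered <- rep(FALSE, nrow(tokens))
    for (k in seq_len(nrow(mentions))) {
      covered[(mentions$span_start[k] + 1L):mentions$span_end[k]] <- TRUE
    }
    raw <- tokens$text[!covered]
    raw <- raw[!(raw %in% stopwords) & nzchar(raw)]
    if (length(raw)) keys <- c(keys, paste0("w:", raw))
  }
  term_vector(keys)
}

#' Construct a term vector from signed keys
#'
#' Deduplicates, resolves asserted/negated conflicts (asserted wins) and
#' sorts, so vector identity is well-defined regardless of build order.
#'
#' @param keys Character vector of signed keys.
#' @return A sorted character vector of class `term_vector`.
#' @export
term_vector <- function(keys = character(0)) {
  keys <- unique(as.character(keys))
  neg <- startsWith(keys, "NEG")
  conflicted <- neg & substring(keys, 4L) %in% keys[!neg]
  structure(sort(keys[!conflicted]), class = "term_vector")
}

#' Flip the polarity of every concept key in a term vector
#'
#' Swaps `"c"` and `"NEGc"` for concept keys; raw `"w:"` keys are unchanged.
#' This is how exclusion-criterion terms enter a trial vector in negated
#' form. The operation is an involution: flipping twice restores the vector.
#'
#' @param v A `term_vector`.
#' @return The flipped `term_vector`.
#' @export
flip_polarity <- function(v) {
  keys <- unclass(v)
  raw <- startsWith(keys, "w:")
  neg <- startsWith(keys, "NEG") & !raw
  flipped <- keys
  flipped[neg] <- substring(keys[neg], 4L)
  flipped[!neg & !raw] <- paste0("NEG", keys[!neg & !raw])
  term_vector(flipped)
}

#' Union of term vectors with conflict resolution
#'
#' @param ... `term_vector`s (or plain key vectors).
#' @return A `term_vector` containing every key, asserted keys winning over
#'   their negated counterparts.
#' @export
tv_union <- function(...) {
  term_vector(unlist(lapply(list(...), unclass), use.names = FALSE))
}

#' Vectorize a piece of clinical text end to end
#'
#' Convenience wrapper: tokenize, extract mentions, optionally detect
#' negation, build the signed vector.
#'
#' @param text Character string.
#' @param index An `espre_terminology`.
#' @param triggers An `espre_triggers` lexicon.
#' @param negation Run negation detection (default TRUE).
#' @param include_raw_tokens Include raw word keys (default TRUE).
#' @param window NegEx scope window in tokens.
#' @return A `term_vector`.
#' @export
text_to_vector <- function(text, index, triggers = load_triggers(),
                           negation = TRUE, include_raw_tokens = TRUE,
                           window = 5L) {
  toks <- tokenize(text)
  men <- extract_mentions(toks, index)
  if (negation) men <- detect_negation(toks, men, triggers, window)
  to_term_vector(men, toks, include_raw_tokens = include_raw_tokens)
}
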