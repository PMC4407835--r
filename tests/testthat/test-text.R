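test_that("tokenizer splits on non-alphanumerics and keeps exact offsets", {
  toks <- tokenize("No CNS disease.")
  expect_equal(toks$text, c("no", "cns", "disease"))
  expect_equal(tokenize("")$text, character(0))
  toks <- tokenize("T-cell ALL (relapsed)")
  expect_equal(toks$text, c("t", "cell", "all", "relapsed"))
  # character-scan oracle for offsets: each token substring must equal the
  # lowercased original at [start, end)
  for (txt in c("T-cell ALL (relapsed)", "a  b\tc\nd", " x9 !! y")) {
    toks <- tokenize(txt)
    for (i in seq_len(nrow(toks))) {
      expect_equal(tolower(substr(txt, toks$start[i] + 1, toks$end[i])),
                   toks$text[i])
    }
    expect_true(all(diff(toks$start) > 0))
    expect_true(all(toks$start < toks$end))
  }
})

test_that("longest dictionary match beats shorter synonym routes", {
  idx <- fixture_index()
  toks <- tokenize("central nervous system disease present")
  men <- extract_mentions(toks, idx)
  expect_equal(nrow(men), 1L)
  expect_equal(men$concept_id, "23853001")
  expect_equal(men$span_end - men$span_start, 4L)
  expect_equal(nrow(extract_mentions(tokenize("nothing relevant here"), idx)), 0L)
  men2 <- extract_mentions(tokenize("cns disease cns disease"), idx)
  expect_equal(nrow(men2), 2L)
  expect_equal(men2$span_start, c(0L, 2L))
})

test_that("extraction equals the brute-force leftmost-longest oracle", {
  rows <- list(c("C1", "aa bb", "aa bb"),
               c("C2", "bb", "bb"),
               c("C3", "aa bb cc", "aa bb cc"),
               c("C4", "cc dd", "cc dd"),
               c("C5", "dd", "dd"))
  idx <- tiny_index(rows)
  phrases <- c("aa bb" = "C1", "bb" = "C2", "aa bb cc" = "C3",
               "cc dd" = "C4", "dd" = "C5")
  alphabet <- c("aa", "bb", "cc", "dd", "xx")
  set.seed(404)
  for (rep in 1:300) {
    n <- sample(0:12, 1)
    words <- sample(alphabet, n, replace = TRUE)
    toks <- tokenize(paste(words, collapse = " "))
    got <- extract_mentions(toks, idx)
    want <- oracle_mentions(toks$text, phrases)
    expect_equal(nrow(got), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$concept_id[i], want[[i]]$concept_id)
      expect_equal(got$span_start[i], want[[i]]$span_start)
      expect_equal(got$span_end[i], want[[i]]$span_end)
    }
    # spans pairwise disjoint and sorted
    if (nrow(got) > 1) {
      expect_true(all(got$span_start[-1] >= got$span_end[-nrow(got)]))
    }
  }
})

test_that("negation fires on triggers in scope and respects pseudo/terminators", {
  idx <- fixture_index()
  trig <- load_triggers()

  toks <- tokenize("No CNS disease")
  men <- detect_negation(toks, extract_mentions(toks, idx), trig)
  expect_equal(men$polarity, "negated")

  toks <- tokenize("not only leukemia")
  men <- detect_negation(toks, extract_mentions(toks, idx), trig)
  expect_equal(men$polarity, "asserted")

  toks <- tokenize("no fever but cns disease")
  men <- detect_negation(toks, extract_mentions(toks, idx), trig)
  expect_equal(men$polarity[men$concept_id == "386661006"], "negated")
  expect_equal(men$polarity[men$concept_id == "23853001"], "asserted")

  # outside the 5-token window the trigger does not reach
  toks <- tokenize("no x1 x2 x3 x4 x5 x6 fever")
  men <- detect_negation(toks, extract_mentions(toks, idx), trig)
  expect_equal(men$polarity, "asserted")
})

test_that("negation agrees with a brute-force scope enumerator on random text", {
  idx <- tiny_index(list(c("C1", "aa", "aa"), c("C2", "bb cc", "bb cc")))
  trig <- load_triggers()
  vocab <- c("aa", "bb", "cc", "no", "not", "only", "but", "without", "xx")
  set.seed(77)
  for (rep in 1:200) {
    words <- sample(vocab, sample(1:10, 1), replace = TRUE)
    toks <- tokenize(paste(words, collapse = " "))
    men <- extract_mentions(toks, idx)
    got <- detect_negation(toks, men, trig)
    for (i in seq_len(nrow(men))) {
      expect_equal(got$polarity[i] == "negated",
                   oracle_negated(toks$text, men$span_start[i], trig),
                   info = paste(words, collapse = " "))
    }
    # negation never changes concepts or spans
    expect_equal(got$concept_id, men$concept_id)
    expect_equal(got$span_start, men$span_start)
  }
})

test_that("term vectors are binary signed key sets with asserted-wins conflicts", {
  idx <- fixture_index()
  v <- text_to_vector("No CNS disease", idx)
  expect_equal(unclass(v), "NEG23853001")

  toks <- tokenize("")
  expect_length(to_term_vector(extract_mentions(toks, idx), toks), 0L)

  # same concept twice -> one key
  v <- text_to_vector("cns disease and cns disease", idx)
  expect_equal(sum(unclass(v) == "23853001"), 1L)

  # conflict: asserted key wins
  expect_equal(unclass(term_vector(c("A", "NEGA", "B"))), c("A", "B"))

  # raw tokens: non-stopwords outside mention spans, prefixed
  v <- text_to_vector("severe cns disease today", idx)
  expect_setequal(unclass(v), c("23853001", "w:severe", "w:today"))
  v <- text_to_vector("severe cns disease today", idx, include_raw_tokens = FALSE)
  expect_equal(unclass(v), "23853001")
})

test_that("flip_polarity swaps concept keys, keeps raw keys, and is an involution", {
  expect_equal(unclass(flip_polarity(term_vector("23853001"))), "NEG23853001")
  expect_equal(unclass(flip_polarity(term_vector("NEG23853001"))), "23853001")
  expect_length(flip_polarity(term_vector()), 0L)
  set.seed(11)
  for (rep in 1:50) {
    keys <- unique(c(
      sample(paste0("C", 1:8), sample(0:4, 1)),
      paste0("NEG", sample(paste0("D", 1:8), sample(0:4, 1))),
      paste0("w:", sample(letters, sample(0:3, 1)))
    ))
    v <- term_vector(keys)
    expect_equal(flip_polarity(flip_polarity(v)), v)
    raw_in <- grep("^w:", unclass(v), value = TRUE)
    expect_setequal(grep("^w:", unclass(flip_polarity(v)), value = TRUE), raw_in)
  }
})
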