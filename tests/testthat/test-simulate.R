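small_cfg <- function(seed, ...) {
  args <- list(n_trials = 4L, n_patients = 24L, n_concepts = 50L,
               notes_per_patient = c(2L, 4L), note_length = c(30L, 60L),
               eligible_fraction = 0.125, enrollment_prob = 1,
               signal = 1, distractor_rate = 0, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

test_that("the same seed reproduces the world byte for byte", {
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_world(small_cfg(7), d1)
  generate_world(small_cfg(7), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
  # a different seed changes the corpus
  d3 <- file.path(tempdir(), "sim_c")
  unlink(d3, recursive = TRUE)
  generate_world(small_cfg(8), d3)
  expect_false(identical(readLines(file.path(d1, "patients.jsonl")),
                         readLines(file.path(d3, "patients.jsonl"))))
})

test_that("at full signal every enrolled patient's vector contains the trial signature", {
  dir <- file.path(tempdir(), "sim_sig")
  unlink(dir, recursive = TRUE)
  w <- generate_world(small_cfg(21), dir)
  ctx <- load_context(file.path(dir, "trials"),
                      file.path(dir, "patients.jsonl"),
                      file.path(dir, "terminology.tsv"),
                      file.path(dir, "icd9_map.tsv"),
                      reference = file.path(dir, "reference.csv"))
  enr <- w$truth$enrollments
  expect_gt(nrow(enr), 0)
  for (i in seq_len(nrow(enr))) {
    tr <- w$trials[[enr$nct_id[i]]]
    prof <- build_patient_profile(ctx$records[[enr$patient_id[i]]],
                                  ctx$trials[[enr$nct_id[i]]],
                                  ctx$index, ctx$icd9map)
    expect_true(all(tr$signature %in% unclass(prof$vector)),
                info = paste(enr$nct_id[i], enr$patient_id[i]))
  }
})

test_that("truth invariants: enrollments subset of eligibility; zero enrollment probability", {
  w <- build_world(small_cfg(3))
  key <- function(df) paste(df$nct_id, df$patient_id)
  expect_true(all(key(w$truth$enrollments) %in% key(w$truth$eligibility)))

  w0 <- build_world(small_cfg(3, enrollment_prob = 0))
  expect_equal(nrow(w0$truth$enrollments), 0L)
  expect_gt(nrow(w0$truth$eligibility), 0L)
})

test_that("infeasible and invalid configs are rejected", {
  expect_error(small_cfg(1, eligible_fraction = 0.001), "infeasible")
  expect_error(small_cfg(1, signal = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_trials = 2), "seed")
  w <- build_world(small_cfg(2))
  expect_error(corrupt_world(w, "unknown_op", 0.5, 1), "unknown corruption")
})

test_that("corruption at rate zero is the identity; negation flip negates planted mentions", {
  w <- build_world(small_cfg(5))
  expect_identical(corrupt_world(w, "typo_injection", 0, 1), w)

  wneg <- corrupt_world(w, "negation_flip", 1, 1)
  # every planted sentence now carries a leading negation trigger
  for (p in wneg$patients) {
    for (txt in p$notes$text) {
      expect_false(grepl("there is (?!no )", txt, perl = TRUE), info = txt)
    }
  }
  # and the resulting profiles carry NEG keys instead of asserted ones
  dir <- file.path(tempdir(), "sim_neg")
  unlink(dir, recursive = TRUE)
  write_world(wneg, dir)
  ctx <- load_context(file.path(dir, "trials"),
                      file.path(dir, "patients.jsonl"),
                      file.path(dir, "terminology.tsv"),
                      file.path(dir, "icd9_map.tsv"),
                      use_diagnoses = FALSE)
  enr <- wneg$truth$enrollments
  tr <- wneg$trials[[enr$nct_id[1]]]
  prof <- build_patient_profile(ctx$records[[enr$patient_id[1]]],
                                ctx$trials[[enr$nct_id[1]]],
                                ctx$index, use_diagnoses = FALSE)
  expect_false(all(tr$signature %in% unclass(prof$vector)))

  wshift <- corrupt_world(w, "date_shift", 1, 1)
  d_orig <- as.Date(w$patients[[1]]$notes$date)
  d_new <- as.Date(wshift$patients[[1]]$notes$date)
  expect_true(all(d_new - d_orig == 1000))
})

test_that("typo injection degrades ranking monotonically on average", {
  # Monte-Carlo trend check: higher typo rates can only destroy dictionary
  # matches, so mean workload is non-decreasing in rate.
  rates <- c(0, 0.5, 1)
  mean_wl <- sapply(rates, function(r) {
    wl <- c()
    for (seed in 1:6) {
      w <- build_world(small_cfg(100 + seed))
      wc <- corrupt_world(w, "typo_injection", r, 200 + seed)
      dir <- file.path(tempdir(), paste0("sim_typo_", r, "_", seed))
      unlink(dir, recursive = TRUE)
      write_world(wc, dir)
      ctx <- load_context(file.path(dir, "trials"),
                          file.path(dir, "patients.jsonl"),
                          file.path(dir, "terminology.tsv"),
                          file.path(dir, "icd9_map.tsv"),
                          reference = file.path(dir, "reference.csv"),
                          use_diagnoses = FALSE)
      res <- run_trial_centered(ctx)
      wl <- c(wl, res$summary$mean_workload)
    }
    mean(wl)
  })
  expect_lte(mean_wl[1], mean_wl[2] + 1e-9)
  expect_lte(mean_wl[2], mean_wl[3] + 1e-9)
})
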