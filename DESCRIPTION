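Package: espre
Title: Automated Clinical Trial Eligibility Pre-Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks trial-patient matches for clinical trial eligibility
    pre-screening. Parses ClinicalTrials.gov-style narrative eligibility
    criteria into demographic constraints and signed concept vectors,
    builds patient profiles from structured diagnoses (ICD-9 coded) and
    free-text notes under per-trial temporal cutoffs, detects negation
    with a NegEx-style trigger/scope rule, scores trial-patient pairs
    with a polarity-aware binary cosine, and evaluates screening
    efficiency with workload, precision, specificity, recall and NPV at
    the workload cutoff. Includes a deterministic synthetic EHR/trial
    corpus generator so the full pipeline is testable without any
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
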