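---
title: "Eligibility pre-screening: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eligibility pre-screening: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(espre)
```

## The screening problem

Trial eligibility screening is an information-retrieval problem with two
symmetric directions: given a trial, rank the patient population by
eligibility (cohort identification); given a patient, rank the open trials
(trial recommendation). `espre` treats both sides as signed bags of
concepts and raw words, scores pairs with a polarity-aware cosine, and
evaluates the ranking by the chart-review workload needed to recover all
reference-standard matches. This vignette records the model assumptions,
the parameters that matter, and the places where the design was genuinely
open — together with what our synthetic evaluation does and does not
demonstrate.

## Text model

Tokenization lowercases and splits on anything outside `[a-z0-9]`; the
same normalization is applied to terminology synonyms, so dictionary
lookup is case- and punctuation-insensitive by construction. Concept
extraction is greedy leftmost-longest dictionary matching: at each token
the longest indexed phrase starting there wins and the scan jumps past it.
This is deterministic, auditable, and exactly matched by the brute-force
sub-span oracle in the test suite; it cannot, by design, resolve
ambiguous phrases by context (a known limitation shared with any
dictionary matcher).

Negation follows the NegEx recipe: a mention is negated when a
pre-negation trigger ends within `window` tokens of the mention start with
no scope terminator or pseudo-negation in between.

* `window = 5` tokens. This is the customary NegEx scope; shorter windows
  miss "no evidence of residual disease", longer ones over-negate across
  clause boundaries.
* Only pre-negation triggers are implemented. Post-position cues
  ("...was ruled out") are rarer in criteria text and problem lists; the
  lexicon is a plain file (`[PRE]`/`[PSEUDO]`/`[TERM]` sections) so users
  can extend it.
* Uncertainty, hypothetical and family-history assertion classes are out
  of scope.

A document vector is a binary set of signed keys (`c`, `NEGc`,
`w:token`). Three choices deserve a note:

* **Raw tokens** (`include_raw_tokens`, default on for notes and
  criteria, always off for structured diagnosis strings): criteria text
  and notes carry discriminative words that no small terminology covers,
  so both concept codes and residual words enter the vector at equal
  weight. Structured diagnosis labels are vectorized as concepts only,
  with negation off — a problem-list entry asserts presence, and running
  a negation detector over a bare label is meaningless.
* **Conflict rule**: a vector never holds both `c` and `NEGc`; the
  asserted key wins. Clinical text that asserts a finding anywhere is
  stronger evidence of the finding than a negated mention elsewhere is of
  its absence. The alternative (last-writer-wins) would make profiles
  depend on note ordering.
* **Exclusion flip**: all terms extracted from an exclusion section are
  polarity-flipped before joining the trial vector. A mechanical
  consequence is that a *negated* exclusion line ("no prior chemotherapy"
  under Exclusion) is negated by the detector and re-asserted by the
  flip. We believe flip-after-NegEx is the more faithful composition of
  the two rules, but the clinical intent of double-negated exclusions is
  genuinely ambiguous, so `negex_in_exclusion = FALSE` selects the other
  reading (flip raw asserted terms only).

## Demographics and time

Age bounds parse from the criteria text into whole-day durations
(365.25 days/year, 30.44 days/month, rounded; exclusive bounds become the
tightest inclusive whole-day bound). The filter passes a patient when
their age interval over the enrollment window intersects the trial's
bounds — eligibility on *any* day of the window suffices. The reference
date for "age" is never stated in trial registries; interval overlap is
the least restrictive reading and, crucially, filter-sound: it can admit
a borderline candidate but never removes a truly eligible one. The third
filter clause — at least one note inside the enrollment window — encodes
"was in our care during enrollment".

Profiles are built per (patient, trial) pair because the temporal cutoff
is trial-specific: entries after the trial's close date are invisible,
and for the patient's own enrollments only entries strictly before the
enrollment date count. Dates are whole days; the close date itself is
inclusive. The pipeline pre-vectorizes each entry once and assembles
cutoff-specific profiles as unions of cached key sets; a test verifies
this equals the direct per-pair builder.

## Matching score

The score is a binary cosine with a subtractive contradiction penalty,
`(|T∩P| − λ·c(T,P)) / sqrt(|T||P|)`, with λ = 1 by default and λ = 0
giving plain cosine. The vector-space framing calls for a set-overlap
similarity; the penalty term is the simplest way to make an exclusion
violation (trial `NEGc` against patient `c`) push a candidate down rather
than merely fail to push it up. λ = 1 weighs one contradiction as the
loss of one shared term, which keeps the score symmetric and bounded by
the cosine. Empty vectors score 0. Ties are broken by candidate id
ascending, for reproducibility. No tf-idf, learned weights or query
expansion: the point of this implementation is a transparent baseline.

## Evaluation conventions

Workload is the 1-based rank of the deepest reference positive. Two
degenerate branches are fixed by policy: an anchor with no positives
requires reviewing its whole post-filter list, and a positive that the
demographics filter removed forces review of the entire universe (the
ranked list can never surface it). Both keep recall and NPV identically 1
by construction — the identity asserted on every synthetic run.

* Specificity with no true negatives (`N = k`) is defined as 1.
* The random-baseline expectation `k(N+1)/(k+1)` is the exact mean of the
  maximum of `k` uniformly placed ranks; the test suite checks it against
  exhaustive enumeration for all `N ≤ 7` and against 2,000 seeded
  shuffles at `N = 50, k = 5`.
* Aggregation reports both micro (pooled counts) and macro (mean of
  per-anchor ratios) precision/specificity; single pooled figures in the
  literature are usually micro, so micro is the headline, but the choice
  is visible in the output rather than buried.
* The 95% CI on mean workload is a t-interval over anchors. Published
  screening evaluations rarely name their CI method; the t-interval is
  the standard small-sample default and degenerates to the point for a
  single anchor.
* The paired comparison of two workload vectors is a two-sided paired
  t-test, with explicit degenerate branches: all differences zero gives
  p = 1, a non-zero constant difference gives p = 0 (the limit of the t
  statistic as the variance of differences vanishes).
* Chart-review arithmetic follows the conventional presentation:
  precisions pooled over trials and rounded to 2 decimals, relative
  improvement computed on the rounded values to 1 decimal, projection
  onto a base precision to 3 decimals capped at 1, grouped
  error-category shares truncated (not rounded) to 1 decimal and single
  categories rounded to integer percent. These conventions are part of
  the operations' contracts so the worked examples reproduce exactly.

## What the synthetic generator emulates — and what it does not

`sim_config()`/`generate_world()` build a deterministic world: a
pseudo-word terminology (unique two-word terms plus a one-word alias per
concept), trials with disjoint concept signatures rendered through
sentence templates, patients with birth dates, genders, timestamped notes
and ICD-9-coded diagnoses, and a ground-truth eligibility/enrollment
sample. Defaults are desk-scale echoes of a pediatric oncology
population: 20 trials, 100 patients, 150 concepts, 2–40 notes per patient
of 50–300 tokens, ~5 eligible patients per trial, enrollment probability
0.9 (pediatric oncology enrollment among eligibles is near-universal),
15% of patients failing the demographic filter, 10% of trials
gender-restricted. Sentence templates use function-word filler only, so
planted concept terms are the sole non-stopword content — which is what
makes the recovery guarantee provable: at `signal = 1, distractor_rate =
0`, every eligible patient's vector strictly contains the trial
signature, ineligible vectors are disjoint from it, and both screening
directions recover the planted cohort with workload = k and precision 1.
The recovery acceptance run sets `enrollment_prob = 1`: with partial
enrollment the non-enrolled eligibles are indistinguishable from enrolled
ones by construction, so workload = k against an enrollment reference is
only a theorem when eligibility and enrollment coincide.

What this does *not* show: real clinical language (no misspellings,
abbreviations, section headers, template boilerplate), no lexical overlap
between trial signatures (real trials share disease vocabulary), no
quantitative criteria (lab thresholds are deliberately out of scope), and
a terminology whose phrases never collide. Passing the recovery suite
therefore certifies the pipeline's mechanics — extraction, polarity,
temporal cutoffs, filtering, ranking, metrics — not its accuracy on real
EHR text. The `corrupt_world()` harness (typo injection, negation flips,
date shifts) probes robustness trends, mirroring the dominant error modes
of dictionary matchers (sub-category confusion, wrong assertion status,
stale entries), but is a stress test, not a fidelity model.

Problem sizes in the test and acceptance suites (worlds of 4–24 trials
and 20–100 patients, 2,000 baseline shuffles, 200–300 randomized oracle
cases per property) were chosen as the smallest scales at which every
property is non-trivially exercised; all are deterministic under fixed
seeds.

## Known limitations

* One concept id per phrase: the terminology loader rejects ambiguous
  synonyms instead of disambiguating them.
* The matching score is a stand-in for whatever proprietary weighting a
  production IE system would learn; its interface (signed binary vectors
  in, bounded score out) is the stable part.
* Age parsing recognizes the common registry patterns only; exotic
  phrasings ("from the 29th day of life") fall back to unbounded.
* The demographics filter's note-in-window clause uses raw note dates,
  not the temporal cutoff, matching its screening-time semantics.
* Headline cohort numbers from real retrospective studies (workloads in
  the tens against populations in the hundreds) are not reproducible
  here: they depend on a private EHR corpus. The package reproduces the
  published arithmetic that is derivable from printed tables, and
  certifies everything else by construction on synthetic data.
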