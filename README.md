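# registrylink

Record linkage for administrative person registries, in the style of the
large Brazilian data-linkage centres that build population cohorts from
CadUnico (the Unified Registry for Social Programmes), SINASC (live
births), SIM (mortality) and SINAN (disease notification). These
registries share no reliable unique key, so individuals must be matched
on quasi-identifiers — name, sex, mother's name, date of birth,
municipality — that arrive with typos, lost accents, date-digit errors
and missing fields.

The package provides the whole stack:

* **Synthetic registries with ground truth** — Brazilian-style names
  (particles, accents, Zipf-weighted homonyms), configurable field
  corruption and overlap, and a gold standard of true pairs recorded at
  generation time (`generate_population()`, `derive_linked_registry()`,
  `generate_birth_scenario()`).
* **Preprocessing** — accent-folding name normalization, strict
  declared-dialect date standardization, 7-digit municipality / 11-digit
  NIS validation, exact-key deduplication (`clean_registry()`,
  `deduplicate()`).
* **Bloom-filter probabilistic linkage** — predicate blocking, per-field
  bigram Bloom encodings (double hashing, defaults m = 128, k = 3), Dice
  similarity, weighted composite scores with missing-field
  renormalization, greedy one-to-one classification (`link_bloom()`).
  The composite score for a pair is

  > score = Σ w_f · s_f / Σ w_f over fields f present in both records,

  with s_f the Dice coefficient 2|a∧b|/(|a|+|b|) for name fields and
  exact agreement ∈ {0,1} for birth date, sex and municipality.
* **TF-IDF inverted-index linkage** — token weights
  (1 + ln tf)·ln(1 + N/df), cosine scoring, and an
  exact / semi-exact / fuzzy query schedule with optional
  character-bigram tokens for typo robustness (`build_index()`,
  `query_index()`, `link_by_index()`).
* **Deterministic linkage** — unique-key joins with ambiguity surfacing
  (`link_by_key()`), and the two-stage strategy for birth records:
  mothers linked probabilistically, children attached deterministically
  via the linked mother plus the child's birth date and sex, so unnamed
  newborns are linkable (`link_births_two_stage()`).
* **Calibration** — review-sample drawing (default n = 2000, uniform or
  score-stratified), sensitivity/specificity over a cut-off grid,
  trapezoidal ROC-AUC, and cut-off selection by the Youden index
  J = sens + spec − 1 (`sample_pairs()`, `roc_report()`,
  `select_cutoff()`).
* **Pipeline & extraction** — a validated end-to-end run with
  provenance sidecars and JSON-line logs (`run_pipeline()`), plus
  research-extract construction with keyed pseudonyms and aggregation of
  sensitive fields (`extract_dataset()`). A thin CLI wrapper lives in
  `inst/scripts/registrylink-cli.R`.

## Worked example

Link a 1,000-person registry to a noisy copy of half of it, calibrating
the cut-off against the gold standard:

```r
library(registrylink)

base <- generate_population(1000, seed = 1)
d    <- derive_linked_registry(base, overlap_fraction = 0.5,
                               corruption_config(seed = 2))
left  <- deduplicate(clean_registry(base))$registry
right <- deduplicate(clean_registry(d$registry))$registry

scored <- score_candidates(left, right, build_blocks(left, right))
nrow(scored)
#> [1] 124231

best   <- links(classify(scored, 0))          # linked dataset for review
report <- calibrate_cutoff(best, d$gold, n = 500, seed = 3)
report
#> <cutoff_report> 101 candidate cut-offs, AUC = 1
#>   selected cut-off: 0.7 (youden)

linked <- links(classify(scored, report$selected_cutoff))
gkey <- paste(d$gold$left_id, d$gold$right_id)
key  <- paste(linked$left_id, linked$right_id)
sprintf("links: %d  recall: %.3f  precision: %.3f",
        nrow(linked), mean(gkey %in% key), mean(key %in% gkey))
#> [1] "links: 499  recall: 0.996  precision: 0.998"
```

Blocking reduced the 1,000 × 1,000 comparison space to ~124k candidate
pairs; the ROC-calibrated cut-off of 0.7 recovers 99.6% of the 500 true
pairs at 99.8% precision under the default moderate-corruption profile
(0.2 per-field edit probability, accent loss, date-digit errors, 5%
missingness).

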