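---
title: "Linking administrative person registries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking administrative person registries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(registrylink)
```

## The problem

Brazilian population-scale research cohorts are built by linking
administrative registries that were never designed to be linked: the
Unified Registry for Social Programmes (CadUnico), live-birth records
(SINASC), mortality records (SIM) and disease-notification records
(SINAN). Where a shared unique key exists — the Social Identification
Number (NIS) carried by social-programme data — linkage is a
deterministic join. Health registries carry no such key, so records must
be matched on quasi-identifiers: name, sex, mother's name, date of birth
and municipality of residence, all of which suffer typos, accent loss,
missingness and date-digit errors.

`registrylink` implements that full stack in one package: a synthetic
registry generator with known ground truth, preprocessing, two
probabilistic linkers (Bloom-filter/Dice and TF-IDF inverted-index), the
deterministic and two-stage mother–child strategies, and ROC-based
cut-off calibration.

## Synthetic registries: what the generator emulates

No real registry rows can ship with a package like this, so every
downstream stage is exercised against generated data whose true links
are known *by construction* — the gold standard is bookkeeping from the
copy step, never the output of a matcher.

`generate_population()` samples Brazilian-style names — a given name,
optional particles (DA, DE, DOS, ...), one or two surnames — with
Zipf-like weights, so frequent names dominate and homonyms occur, as in
real registries. Names carry accents and natural casing; dates are
generated in `DD/MM/YYYY` text; municipality codes come from a bundled
IBGE-style 7-digit pool (~100 codes). `derive_linked_registry()` then
builds the "health registry": a configurable fraction of the base
records are copied, given fresh identifiers, stripped of the NIS, and
corrupted.

The corruption model (`corruption_config()`) applies, independently per
field and record:

* single-character edits (substitute, delete, insert, transpose) on
  names, default probability 0.2 per name field;
* accent loss (folding to ASCII), default probability 0.2;
* date-digit errors (one digit replaced or two adjacent digits
  transposed), default probability 0.2 — these may produce impossible
  dates, which preprocessing flags as missing, exactly as real invalid
  dates are handled;
* missingness, default probability 0.05 per field.

These defaults are the package's declared benchmark conditions. The
error rates of the real registries are not publicly characterized, so
the defaults are stand-ins chosen to be *moderate*: high enough that
word-level matching visibly degrades, low enough that a skilled linker
should still recover nearly all pairs. They are set once, exposed as
configuration, and used unchanged by the benchmark, the acceptance
checks and the examples.

What the generator deliberately does **not** emulate: household
structure beyond mother–child, migration between registries, correlated
errors (a clerk who corrupts several fields at once), nickname and
abbreviation conventions, and duplicated enrolments inside one registry.
Passing benchmarks on this generator therefore show that the machinery
is correct and well-calibrated under realistic independent noise — not
that the same numeric accuracy would be observed on any particular real
registry pair.

In the birth scenario (`generate_birth_scenario()`), children of the
same mother are assigned distinct birth dates. Twins are real, but they
are *provably* unlinkable by the two-stage key (mother, child birth
date, sex) when unnamed; the two-stage linker reports such collisions as
ambiguous rather than guessing, and the generator keeps the default
scenario collision-free so that zero-noise recovery is exact.

## Preprocessing

Cleaning is deliberately boring and strict:

* names are uppercased, accent-folded, stripped of punctuation and
  digits, whitespace-collapsed; particles are **kept** by default (they
  feed the bigram encodings with real signal; `strip_particles = TRUE`
  is available);
* the date dialect of each file (`DMY` or `ISO`) must be declared, never
  sniffed — a silently misparsed date column is the worst linkage
  failure mode; impossible dates become missing plus an `invalid_date`
  flag;
* municipality codes must be exactly 7 digits and NIS keys exactly 11;
  violations become missing plus a flag;
* deduplication is exact on the full linkage key, keeping the first
  record in stable input order.

Missing values are `NA` in memory and empty strings on disk, so registry
CSVs round-trip exactly.

## Bloom-filter linkage

Each name field is encoded as an `m`-bit Bloom filter: the field's
padded character bigrams are hashed `k` times each by double hashing
(`index_i = (h1 + i*h2) mod m`), with a per-field salt. Similarity
between two encodings is the Dice coefficient over set bits,
`2|a AND b| / (|a|+|b|)` — for bigram sets this tracks the plaintext
bigram overlap without comparing plaintext, which is what makes the
approach privacy-preserving. Defaults `m = 128`, `k = 3` follow standard
practice in this literature; the base hashes are polynomial hashes
modulo $2^{31}-1$, exact in double arithmetic and therefore identical on
every platform.

Candidate pairs come from predicate blocking: the union, over a set of
predicates, of all within-block cross pairs. The default predicates are
municipality code, birth year, and first-two-letters-of-first-name plus
sex. A record with a missing predicate input gets no label from that
predicate — missingness must never glob records into one giant block.

The composite pair score is a weighted mean of per-field scores — bigram
Dice for the two names, exact agreement in $\{0,1\}$ for birth date, sex
and municipality — with weights renormalized over the fields present in
both records (default weights 0.3/0.2/0.2/0.1/0.2 favouring names).
Classification thresholds the composite at a cut-off and then resolves
links one-to-one greedily in descending score order, ties broken by
record identifiers so runs are bit-reproducible.

## TF-IDF inverted-index linkage

The second linker indexes the right-hand registry once and probes it
record by record. Tokens are name words (mother-name words prefixed to
keep the fields distinct) plus single tokens for birth date, sex and
municipality; the date also contributes its year and month–day halves,
so a single date-digit error leaves partial date evidence intact. Token
weights follow $(1+\ln tf)\,\ln(1+N/df)$ with cosine scoring over
L2-normalized vectors; the $1+N/df$ form keeps weights strictly positive
even for tokens present in every record.

Three query modes form a cheapest-first schedule:

* **exact** — candidates must agree on every linkage attribute that is
  non-missing in the probe; all results score 1;
* **semi-exact** — candidates must agree exactly on birth date and
  municipality; survivors are ranked by the all-token cosine. An earlier
  design ranked semi-exact candidates by name tokens alone, but that
  makes scores incomparable across modes (a true match with a corrupted
  name scores near zero although its date and municipality agree
  exactly), and a single calibrated cut-off then cannot govern the
  schedule; scoring all modes on the same scale fixes this;
* **fuzzy** — candidates sharing at least one token are gathered through
  the posting lists and ranked by the all-token cosine.

Word tokens are brittle: one typo erases a whole token, and short
records with a few intact common tokens can then outrank the true match.
`build_index(..., char_bigrams = TRUE)` additionally indexes padded
character bigrams of the name words, so similarity degrades gracefully
under edits. The default stays word-token-only (cheapest, and exact for
clean data); the benchmark profile turns bigrams on because its
corruption model injects exactly the errors bigrams are for.

One-to-one resolution runs greedily over the union of every probe's
retrieved candidates (not just each probe's single best): when a
homonym claims a record at a higher score, the losing probe falls back
to its next-best candidate instead of going unlinked. This mirrors the
Bloom linker's resolution over all scored pairs.

## Deterministic and two-stage linkage

`link_by_key()` joins on a unique key, forming pairs only for key values
occurring exactly once on both sides. A repeated "unique" key is a
data-quality event: it is reported (every record carrying it, both
sides) and produces no links. Missing keys never match.

Birth records may carry no child name at all, so
`link_births_two_stage()` first links each *distinct mother* appearing
in the birth registry to the target registry with a probabilistic linker
(probing with the mother's name, birth date where available, and
municipality), then attaches children deterministically through the
linked mother plus the child's exact birth date and sex. The child's own
name is never used. Children of unlinked mothers stay unlinked;
same-date same-sex children of one mother are reported ambiguous.
Stage 1 links mothers rather than births so that two children of one
mother cannot compete for (and lose) the same target record in
one-to-one resolution.

## Calibration

The accuracy-assessment procedure mirrors clerical-review practice: draw
a review sample (default $n = 2000$) from the *linked dataset* — each
record's best one-to-one pair — label it (in testing, from the gold
standard; in production, by reviewers via a CSV round-trip), compute
sensitivity and specificity over a cut-off grid (default 101 equally
spaced points), the ROC curve augmented with $(0,0)$ and $(1,1)$, and
the trapezoidal AUC. The operating cut-off maximizes the Youden index
$J = \mathrm{sens} + \mathrm{spec} - 1$, the standard single-number ROC
criterion; minimum distance to the $(0,1)$ corner is available as an
alternative. Ties go to the smallest cut-off, and cut-offs with
undefined measures are excluded.

Sampling from the linked dataset, not from the raw candidate space,
matters: blocking produces millions of candidate pairs of which only a
sliver are matches, so a 2000-pair sample of *candidates* contains
almost no matches and the estimated ROC is noise. The linked dataset is
roughly class-balanced and a stratified sample of it calibrates well.
Stratified sampling draws equally from deciles of the score
distribution; uniform sampling is also provided.

## Numerical and degenerate-input choices

* All randomness is scoped: generators take explicit seeds, restore the
  caller's RNG state, and derive per-stage streams from the master seed.
* Two all-zero Bloom vectors have Dice 0 with an `uninformative`
  marker; fields empty on either side drop out of the composite and the
  weights renormalize; a pair with no informative field scores 0.
* Ties are always broken lexicographically by record identifier.
* An empty blocking-predicate list is rejected rather than silently
  comparing all pairs; an empty registry cannot be indexed; a cut-off
  above 1 is legal and yields no links.
* Probe tokens unknown to an index are dropped before normalization
  (they can retrieve nothing).
* Sensitivity/specificity with empty denominators are reported missing
  (`NA`), never coerced to 0.

## Benchmark problem sizes

The declared benchmark runs two registries of 5,000 records with 2,500
true shared individuals (generator seed 42), calibrating on a stratified
2,000-pair review sample. At this size the Bloom linker scores ~3.2M
blocked candidate pairs and the index linker probes 5,000 records, which
keeps a full two-linker run in the low minutes on one CPU while leaving
score distributions dense enough for stable calibration. Unit and
property tests use registries of 35–300 records.

## Known limitations

* Bloom encodings here are for similarity computation, not hardened
  against cryptographic re-identification attacks (no record-level
  mixing, no bit folding).
* Within-registry deduplication is exact-key only.
* The semi-exact mode's agreement fields (birth date, municipality) are
  fixed by configuration, not learned.
* Calibration assumes review labels are correct; reviewer disagreement
  is out of scope.
* Synthetic benchmarks bound what the accuracy figures mean: they are
  properties of the declared noise model at the declared scale.
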