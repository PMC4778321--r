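---
title: "Example-based ICD-10 coding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Example-based ICD-10 coding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icd10coder)
```

## The coding problem

Clinical diagnoses in Chinese hospital records are short free-text phrases
("急性胃炎", acute gastritis) that must be mapped to ICD-10
subcategory (4-digit) codes for reporting. The mapping is conventionally done
by trained coders. `icd10coder` automates it with an *example-based* model:
a standard terminology assigns thousands of canonical diagnosis names to
codes, every candidate code `c` is described by the text `T_c` obtained by
concatenating all terminology terms filed under `c` or its descendants, and a
new diagnosis `D` is assigned the code whose description text is most similar
to it:

> `code(D) = argmax_c sim(D, T_c)`

Nothing is trained; all the modelling lives in the similarity function and in
how the candidate set is searched.

## The similarity metric

`sim` is a word-alignment metric over segmented text. Each word `w` of one
text is matched to its most similar word in the other text
(`maxSim(w, T)`), matches are weighted by inverse document frequency
(`idf(w)` = corpus document count divided by the number of documents
containing `w`, as a plain ratio without logarithm), and the two directions
are averaged:

```
sim(T1, T2) = 1/2 * [ sum_{w in S(T1,T2,theta)} maxSim(w,T2) idf(w) / sum_{w in T1} idf(w)
                    + sum_{w in S(T2,T1,theta)} maxSim(w,T1) idf(w) / sum_{w in T2} idf(w) ]
```

`S(T1, T2, theta)` keeps only words whose best match reaches the threshold
`theta`. The threshold exists because irrelevant word pairs often have low
but positive similarity — "男性" (male) and "女性"
(female) score around 0.23 under a lexical taxonomy — and letting such pairs
contribute makes "male pelvic inflammatory disease" look spuriously close to
"female pelvic inflammatory disease". With `theta = 0` the metric reduces
exactly to the classic unthresholded form; with `theta = 1` (under a backend
whose only similarity-1 pairs are identical strings) it degenerates to
idf-weighted exact overlap. The metric is symmetric, lies in `[0, 1]`, and
treats duplicate tokens as separate occurrences in both numerator and
denominator, exactly as the sums are written.

Numerical conventions for degenerate inputs: a text that is empty after
preprocessing has similarity 0 to everything (batch encoding must not
crash); words unseen by the idf corpus get their document frequency floored
at 1, i.e. maximal specificity. Both choices only matter at the boundary and
are covered by tests. A smoothed logarithmic idf (`log(1 + n/df)`) is
available behind `log_idf = TRUE` for experimentation; the plain ratio is
the reference behaviour. The logarithmic form is smoothed so that ubiquitous
words keep a strictly positive weight — an unsmoothed `log(n/df)` would give
weight zero to a word present in every document and an undefined metric on a
degenerate corpus.

## Word-to-word similarity backends

The metric is parameterised by a word-pair similarity in `[0, 1]`. Four
interchangeable backends are provided; all are symmetric and score 1 on
identical strings.

* **String (LCS)** — `|LCS|/(|w1|+|w2|-|LCS|)` with the longest common
  subsequence taken over characters. Chinese words are short character
  sequences in which shared characters carry real meaning, so character-level
  LCS is a reasonable zero-resource similarity.
* **Knowledge (sememe taxonomy)** — words map to concepts, concepts to
  ordered sememe lists, and sememe similarity is `alpha/(d + alpha)` with
  `d` the shortest path between sememes in the taxonomy tree. Word
  similarity is the maximum over concept pairs. Out-of-lexicon words
  (frequent for clinical vocabulary under a domain-independent lexicon) fall
  back to the LCS backend. Concept similarity is under-determined by the
  metric's published description, which defers to recommended parameter
  values of the original Chinese lexical-similarity work; this package takes
  the primary (first) sememe of each concept as definitional by default,
  with an optional `"greedy"` strategy that greedily matches best sememe
  pairs across the full lists and averages matched similarities over the
  longer list length. The primary-sememe reading keeps the dominant term of
  the original weighting without pretending to reproduce its unpublished
  constants. `alpha` defaults to 1.6 and is configurable, never hard-coded.
* **Distributional (context vectors)** — cosine of co-occurrence count
  vectors. In *word* mode the vector dimensions are content words and the
  window spans up to 3 content words on each side; in *char* mode the
  dimensions are content characters of the surrounding text (window 7 per
  side), while the rows remain words. Character dimensions trade a little
  precision for independence from word-segmentation errors, because CJK
  characters are themselves meaning-bearing. Stop words and tokens made of
  numerals/punctuation (Unicode categories N*, P*) are removed *before*
  windows are formed, so the window counts content units; the window is
  symmetric ("around the word" read as per-side). A word with an all-zero
  vector has no distributional evidence and scores 0 against every other
  word; identical strings short-circuit to 1 inside the backend so that
  self-similarity is always 1 regardless of corpus coverage.
* **Exact match** — the indicator of string equality; the no-semantics
  baseline that shows what semantic similarity buys.

## Flat and hierarchical search

The **flat** encoder scores every searchable subcategory. The
**hierarchical** encoder exploits the code tree: it first picks the best
*section* (description = concatenation of everything below it), then the
best category under that section, then the best subcategory under that
category. This cuts the number of scored candidates from all subcategories
(over 10,000 in full ICD-10) to roughly `#sections + #categories-per-section
+ #subcategories-per-category` (about 262 + <40 + ≤10 at full scale), and the
aggregated section texts also protect against isolated look-alike codes in
unrelated chapters: a neuralgia code elsewhere may out-score the true ear
code in a flat scan, but the whole ear section out-scores the whole
nervous-system section, after which the descent recovers the right code.
`gen_rescue_fixture()` packages a deterministic instance of exactly this
flip; hardware-dependent running times are replaced throughout by the
candidate-count invariant `n_candidates(hierarchical) < n_candidates(flat)`.

Deterministic conventions: ties at any level break to the lexicographically
smallest code; codes with no terminology below them (empty `T_c`) are never
scored, since similarity against empty text is meaningless; a category with
searchable text but no searchable subcategory is returned as a category-level
answer and counts as correct at 3-digit level only. If the best similarity at
any level does not exceed the abstain floor (default 0), the encoder returns
no code but still reports the best similarity seen, for diagnostics. An
abstention mechanism is required for precision and recall to differ at all in
single-label coding: an always-assigning coder has P = R by construction.
The floor of 0 means "abstain only when there is no evidence whatsoever";
raising it trades recall for precision.

## Confidence and triage

The confidence of an assignment is `sim(D, T_{c*})` for the chosen code
`c*` — how well the terminology examples under the chosen code actually
describe the diagnosis. In deployment, predictions at or above a confidence
threshold (0.875 in the workflow this package models) are recorded
automatically and the rest are routed to human coders; `triage()` reports
the automatic fraction and per-partition micro-F1, and exposes the
confidence samples of correct and incorrect predictions so that any standard
two-sample test can be applied externally (no bespoke test is bundled).

## Evaluation

`evaluate_coding()` reports micro-averaged precision, recall and F1 at the
4-digit level (codes equal through the subcategory digit) and the 3-digit
level (equal category truncations, so A01.0 vs A01.1 counts as correct).
False negatives are gold instances not correctly assigned, whether miscoded
or abstained; `n_abstained` is reported separately so either accounting of
recall can be recomputed. Useful identities, all asserted in the test suite:
3-digit F ≥ 4-digit F always; with zero abstentions P = R = F; F is
bracketed by min and max of P and R.

## What the synthetic generators emulate — and what they do not

The package is fully testable offline because every external resource is
emulated by a seeded generator (`fixture_spec()`, `gen_code_system()`,
`gen_queries()`, `gen_corpus()`, `gen_sememe_taxonomy()`, `gen_fixture()`):

* the terminology: contiguous sections, categories with shared *head words*,
  subcategories with distinguishing words, ~2 terms per subcategory by
  default (the real standard diagnostic library averages ≈2.3 diagnoses per
  4-digit code; default shapes here are that structure at desk scale);
* gold queries: terminology terms perturbed by synonym substitution
  (default rate 0.3) and single-character edits (default rate 0.1) — chosen
  as a moderate noise level in which most queries remain resolvable but
  string identity frequently fails, which is the regime the semantic
  backends exist for;
* the corpus: documents with category topic structure so that same-category
  words and synonyms genuinely co-occur (40 documents × 30 tokens by
  default in examples and checks — large enough for stable cosines at this
  vocabulary size);
* the sememe taxonomy: a tree in which grouped words share primary sememes,
  with partial lexicon coverage (default 0.8) so the LCS fallback is
  exercised.

Synthetic words are short strings over a CJK code-point range, so
character-level LCS and character-dimension vectors behave as they would on
real Chinese rather than on ASCII identifiers.

What passing tests on these fixtures shows: that every formula is
implemented exactly (each kernel is checked against an independent oracle —
full-matrix DP for LCS, breadth-first search for sememe distances, a naive
quadratic count for co-occurrence, a straight-line evaluation for the
metric, brute force for the argmax), and that the pipeline's structural
claims (hierarchical rescue, threshold benefit, candidate-count reduction,
perfect recovery of noise-free gold) hold mechanically. What it does not
show: absolute accuracy on real hospital data, which depends on the real
terminology's density, real corpus statistics, segmentation quality and
coder conventions — none of which a synthetic fixture can certify. The
published full-scale figures (micro-F around 0.91 for the hierarchical
encoder with the knowledge backend, and a 0.875-confidence triage that
auto-codes ~79 % of diagnoses at F ≈ 0.97) are therefore reference points
for the method at scale, not quantities this package claims to reproduce at
desk scale.

## Problem sizes used by the checks

The bundled checks (`tests/`, `scripts/acceptance.R`) run on 50 seeded
systems of 8–36 subcategories plus assorted hand fixtures, with 1,000-pair
string-similarity sweeps and 8–12-document corpora — sizes chosen so the
whole verification is a matter of seconds while every code path (all four
backends, both encoders, both co-occurrence modes, windows 1/3/7) is
exercised. The generators scale to hundreds of subcategories if heavier
experiments are wanted.

## Tokenization

The metric consumes segmented text. Pre-segmented input (whitespace
delimited) is used as-is — this is how terminology files and fixtures are
written, keeping the package independent of any particular segmenter.
Unsegmented strings fall back to greedy longest-match against a dictionary
(by default the terminology vocabulary), with unmatched characters becoming
single-character tokens. Industrial segmenters for Chinese exist and can be
applied upstream; the pluggable contract here is deliberate, since a
deterministic tokenizer is what makes the test suite exact.

## Known limitations

* Single-label assignment only: one code per diagnosis phrase, no
  multi-label documents.
* The knowledge backend implements the primary-sememe core of the cited
  Chinese lexical similarity, not its full four-feature weighting.
* The idf corpus layout (what counts as one "document") is a user choice;
  both a directory-of-files and a line-per-document reader are provided.
* Synthetic fixtures are structurally, not linguistically, realistic.
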