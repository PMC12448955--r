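---
title: "Mining free-text necropsy records: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining free-text necropsy records: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necrotext)
```

Wildlife pathology registers accumulate necropsy reports whose findings
live mostly in free text: gross pathology, histopathology, ancillary
diagnostics and diagnoses are typed into optional free-text sections, while
signalment (species, sex, age classification, submission date) is
semi-structured and riddled with typographic redundancy. Reviewing such a
register traditionally means close reading of every record. `necrotext`
implements a describe--explore--examine workflow that replaces the close
reading with three computational passes: summarise and filter the
population, surface candidate themes, then quantify specific
clinicopathologic findings with negation awareness.

This vignette explains the statistics and rules behind each pass, the
parameters that matter, and the design decisions taken where more than one
defensible choice existed.

## Corpus model

Each accession becomes one *document*: the configured free-text columns are
concatenated in column order and every remaining column is attached as
document-level metadata. Two choices deserve justification:

* **Sections are joined by a single newline**, and the tokeniser treats the
  newline as punctuation. The examine stage's phrase rule (below) uses
  punctuation as phrase boundaries, so this guarantees a negation cue at
  the end of one findings section can never negate a term at the start of
  the next.
* **Missing metadata becomes the explicit level `"Not recorded"`.**
  Missingness in a register is itself a finding — it shows where data entry
  can be improved — so it is displayed as a level rather than dropped.
  Symmetrically, nothing is ever merged: typographic variants of a species
  name stay separate rows in every table, because automatic consolidation
  would both hide register-quality problems and risk biasing downstream
  views. Consolidation is available to the user through filters.

Duplicate accession ids abort the load rather than being deduplicated:
accession numbers are assigned uniquely on entry, so a duplicate indicates
a corrupt export, not a modelling situation.

## Describe: tallies, periods, filters

`frequency_table()` and `cross_tab()` are plain contingency tallies;
`cross_tab()` additionally normalises within each level of the frequency
variable so it can be drawn as a proportion-by-frequency bar chart. Month
periods are labelled `"YYYY-MM"` rather than pooled calendar months — in a
multi-year corpus a pooled "July" would silently sum across years, which is
rarely what a surveillance question wants.

Filters (`apply_filter()`) combine as AND across roles and OR within a
role, mirroring a set of simultaneous dropdown selections. A filter is
applied once, at the corpus level, and recorded in the corpus provenance;
every later stage consumes the filtered corpus, so the filtered population
is consistent across the whole workflow.

## Text preparation

The tokeniser splits on whitespace and punctuation with two deliberate
exceptions:

* **Internal hyphens are kept** (`plasmodium-like` is one token) so that
  hyphenated clinical variants exist as selectable terms.
* **Slashes are punctuation** (`freeze/thaw` is two tokens), matching how
  such shorthand is used in necropsy prose.

Punctuation tokens are retained in the stream — the phrase rule needs them
— and only excluded when counting. Stop-word removal uses the standard
snowball English list shipped with the package (overridable by file);
pure-numeral tokens are excluded from the document-term matrix by default
(`keep_numerals = FALSE`) because weights and dates otherwise crowd TF-IDF
tables, but they remain in token streams so keyword windows are faithful to
the text.

**No stemming is performed.** Clinical and pathologic terminology stems
into unrecognisable fragments, which makes stemmed tables hard to read and
audit. Variant discovery is instead handled at the point of use by
case-insensitive substring search over the intact vocabulary
(`search_table()`): searching `plas` surfaces `plasmodium`, `plasmodial`
and `plasmodium-like` together, and the user selects the variants relevant
to their question.

One asymmetry is intentional and worth stating plainly: stop-word removal
applies to the *counting* stages (correlations, topics, TF-IDF) but **not**
to keyword-in-context analysis. Negation cues such as "no" and "not" are
themselves stop words; phrase-level negation detection on a stop-worded
stream would be blind to exactly the evidence it needs. KWIC therefore runs
on the raw token stream.

## Explore: co-occurrence and topics

### Word correlations

For terms occurring in at least `min_count` documents (default 5), the
package computes the phi coefficient between binary document-presence
indicators:

$$\phi = \frac{n_{11}n_{00} - n_{10}n_{01}}
{\sqrt{(n_{11}+n_{10})(n_{01}+n_{00})(n_{11}+n_{01})(n_{10}+n_{00})}}$$

which equals the Pearson correlation of the two indicator vectors (this
equivalence is tested against `cor()` on random matrices). Frequency and
position within a document are deliberately ignored — the statistic is a
screen for "which words travel together across records", interpreted by a
subject-matter expert, not a document-similarity metric. The `min_count`
floor exists because two hapax terms that happen to share their single
document correlate perfectly and would dominate the network with noise;
`min_corr` is the user-facing slider, and the edge set is provably
monotone (antitone) in both parameters. Pairs whose contingency table has a
zero marginal (e.g. a term present in every document) have undefined phi
and are skipped.

### Topic model

Topics are fitted with latent Dirichlet allocation via a collapsed Gibbs
sampler written in C++ inside the package. The modelling assumptions are
the standard LDA ones: each document is a mixture over `k` topics, each
topic a distribution over words, with symmetric Dirichlet priors
(`alpha` on mixtures, `beta` on topics). Defaults are `alpha = 50/k`,
`beta = 0.1`, 1000 sweeps, single chain, estimates taken from the final
state:

$$\hat\phi_{kw} = \frac{n_{kw} + \beta}{n_k + V\beta}, \qquad
  \hat\theta_{dk} = \frac{n_{dk} + \alpha}{n_d + K\alpha}$$

These are conventional collapsed-Gibbs defaults; `k` is the only input a
user must choose, and choosing it is an intentionally manual, exploratory
step — no model-selection criterion is provided. The sampler draws from R's
RNG, so a seed makes the full assignment trajectory reproducible, and it
asserts token-count conservation (topic-word counts summing to the corpus
token total) after every sweep. Owning the sampler rather than delegating
it is what makes seeding, sampler state and the conservation invariant
directly testable; correctness is established against planted ground truth
(below) rather than against another implementation.

The word cloud is a table first: per topic the top-`n` words by
$\hat\phi$, and per word a unique `assigned_topic` — the argmax topic —
which becomes its colour. A word may rank highly in several topics but is
only ever coloured once.

## Examine: TF-IDF and negation-aware counting

The "table of important words" ranks, per document,

$$\mathrm{tfidf}(d, t) = \frac{n_{dt}}{n_d} \cdot \ln\frac{N}{n_t}$$

with raw counts normalised by filtered document length and a natural-log
inverse document frequency without smoothing — the plainest reading of
"frequency in this document against frequency across the corpus". Variant
weightings (sublinear tf, smoothed idf) are out of scope. Per document the
top `words_per_document` entries are kept (default forty; a smaller table
is easier to scan but less sensitive to rare variants), ties broken by term
order so the table is deterministic, and the per-document lists are
collated and sorted.

Counting proceeds from selected terms (exact-token matches, not
substrings — each spelling variant is selected explicitly, usually after a
substring search):

1. Every occurrence of the term is located with a keyword-in-context
   window of up to 10 word tokens on each side (`window`, exposed as a
   parameter; "each side" is the common KWIC convention).
2. The *phrase* is the span between the nearest punctuation token before
   and after the hit within that window, falling back to the window edge
   when no punctuation intervenes.
3. The hit is negated when any word in the phrase is a negation cue. The
   default lexicon is `no, not, without, absent, absence, free, negative,
   non, neither, nor, unremarkable` — covering the negation constructions
   of necropsy prose — and can be replaced from file; the lexicon in force
   is carried in every report.
4. A record is *positive* for a term when at least one of its hits is not
   negated; the unique-record count is the size of the union of per-term
   positive sets, so a record matching several terms counts once.

So "no evidence of pneumonia" does not count, while "severe pneumonia. No
nephritis." counts for pneumonia (the full stop bounds the phrase before
the cue) and not for nephritis. Phrase-level scoping is deliberately
simple: pseudo-negations ("not only") also negate, and uncertainty cues
("possible", "suspect") are not modelled. These imperfections are accepted;
the matched records can always be exported (`export_positive()`) for
manual review under a stricter case definition.

Reports are incremental: extending a report with new terms reuses the
already-computed per-term positive sets unchanged.

## The synthetic generator

Real register data cannot be redistributed, so validation rests on
`generate_necropsy_data()`: a seeded generator of register-shaped CSVs with
exact ground truth. It emulates the features of the real data that the
pipeline must survive — weighted species with planted typographic variants,
explicit missing-value rates in signalment, optional (sometimes empty)
free-text sections, theme vocabularies mixed into the text, and finding
terms planted as affirmed mentions, negated mentions (drawn from
grammar-conforming templates such as "no evidence of X"), or both. A
self-check at generation time runs the package's own phrase rule over every
planted term and aborts if any label would disagree, so truth and text are
consistent by construction.

Default rates (species weights, 2% missing signalment, 6% typographic
variants, finding prevalences of 5--20%) are fixed, round values chosen to
resemble an opportunistic wildlife caseload; they are conditions of the
validation experiments, not tuning knobs. For topic-recovery experiments
the generator runs in an *exclusive* mode — each record drawn from exactly
one theme with a disjoint vocabulary — because that is the setting in which
the true topic-word distributions are known (uniform over each theme's
vocabulary).

What the generator does **not** emulate, and what passing tests therefore
do not establish about real data: misspelled finding terms, negations
phrased outside the template grammar (e.g. cues beyond the lexicon, or cue
and term separated by punctuation), overlapping theme vocabularies, and
realistic epidemiological structure. On real records the negation rule's
accuracy is bounded by the lexicon and the phrase grammar; the exactness
results below are statements about rule-conforming text.

## Problem sizes and numerical choices

The validation experiments run at desk scale: 50 random document-term
matrices (up to 20 documents by 200 terms) for the TF-IDF oracle, 50
random binary matrices for the phi oracle, 200 documents of 50 tokens for
topic recovery at `k` of 2 and 3 (best-permutation mean cosine against the
planted distributions, threshold 0.9), and 500 records for negation-count
exactness. These sizes make the whole suite run in about a minute while
leaving the recovery thresholds comfortably non-trivial.

Numerical conventions: TF-IDF and phi are compared to brute-force oracles
at `1e-12`; probability rows of a fitted topic model must sum to 1 within
`1e-9`; cross-tab proportions within a bar sum to 1 within `1e-9`. Ties in
rankings are always broken lexicographically so outputs are reproducible.
Degenerate inputs have defined behaviour: an empty corpus raises an "empty
corpus" error rather than propagating NaNs; documents emptied by stop-word
removal are excluded from LDA with a warning; a search term absent from the
corpus yields a zero count, not an error; an unbounded KWIC window on
punctuation-free text takes the whole text as the phrase.

## Known limitations

* Negation detection is lexicon- and grammar-bound; no machine-learned
  scope resolution.
* Word correlations use presence/absence only; no weighting by frequency
  or proximity.
* The LDA estimate is a single final Gibbs state; no averaging, no
  convergence diagnostics — appropriate for exploration, not inference.
* Multi-token phrases cannot be searched or counted as units.
* `k`, `min_corr` and `words_per_document` are exploration dials; the
  package deliberately offers no automatic selection for them.
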