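---
title: "phenomine: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenomine: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomine)
```

`phenomine` re-implements, as tested reusable code, the computational
stages that surround transformer-based literature mining of bacterial
phenotypes: corpus preparation and BIO encoding, NER/RE evaluation,
strain normalization, phenotype-network analysis, triad-based trophic
inference, and gradient-boosted gene–phenotype association. The
transformers themselves (and their GPU fine-tuning) are out of scope;
predictions enter through defined record interfaces, and seeded
generators emulate every input so the pipeline is verifiable offline.
This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the tests do and do not
establish.

## Corpus model

A corpus record is a sentence or short paragraph with 0-based, half-open
character offsets throughout (a span `(start, end)` covers
`substr(text, start + 1, end)`). Filtering drops records from sections
unlikely to describe strains (acknowledgements, author declarations,
data availability, legends), records whose English-language confidence
is not strictly above 0.40 (the language identifier itself is pluggable;
the rule applies to a supplied confidence field), and duplicates.
Hyphens inside hyphenated words become spaces ("Gram-negative" →
"Gram negative") so that tokenizers do not split on them. Paragraphs
under 512 characters pass through whole — prediction context improves at
paragraph level — while longer ones are split into sentences by a
deterministic regular-expression splitter.

Two rules are under-determined by their one-line descriptions and were
fixed here as package decisions: duplicate detection is exact match
after case-folding and whitespace collapsing, and the journal filter is
a user-supplied allowlist rather than a built-in taxonomy.

The **reference tokenizer** splits on whitespace and detaches leading
and trailing punctuation as single-character tokens. Subword (model)
tokenizers are deliberately not reproduced: they are bound to particular
transformer checkpoints. Everything downstream (`bio_encode`,
`aggregate_spans`, the metrics) takes an explicit token table, so other
tokenizers can be plugged in.

**BIO encoding** is per entity category: the first token overlapping a
span is `B`, later overlapping tokens `I`, everything else `O`.
Overlapping same-category spans are an annotation defect and raise an
error rather than being silently resolved.

**Stratified splits** use the multi-hot entity-presence signature of a
sentence as the stratification key — the natural reading of "same
proportion of labeled sentences per set" when no key is stated — with
largest-remainder rounding of subset sizes (floors first, leftover items
to the largest fractional remainders, ties to the earlier subset) and a
pooled fallback stratum for strata smaller than 3. Under this rule 3979
sentences at (0.65, 0.175, 0.175) split as 2587/696/696: the single
leftover item follows the largest remainder (0.35) into the training
set.

**Augmentation** balances positives against negatives per NER category
(`N_aug = max(0, N_neg − N_pos)`) and at one fifth of the gap, rounded
up, per relation type. Synthetic positives are built by swapping every
`STRAIN` span's text for a random catalog term and recomputing all
offsets; augmented sentences are intended for training splits only,
since they are trivially correlated with their source sentences.

## Evaluation

The cross-entropy loss is the mean over sentences of the summed negative
log-probability of the true token classes, with a floor of `1e-12` on
probabilities (warned when triggered) so degenerate predictions yield a
finite, comparable loss. Span aggregation merges maximal runs of `B`/`I`
tokens and scores a span by the **maximum** token score over the run;
the retention threshold of 0.5 is inclusive ("0.5 or higher").

Strict matching counts exact-extent matches (`COR`); partial matching
additionally grants half credit to overlapping non-exact matches
(`PAR`): `P = (COR + 0.5·PAR) / n_pred`, `R = (COR + 0.5·PAR) / n_gold`,
`F1 = 2PR/(P+R)` with `F1 = 0` when `P + R = 0`.

The matcher is a deliberate deviation from the simplest design. A greedy
left-to-right matcher is provably suboptimal on some disjoint-span
configurations — a prediction overlapping two gold spans can consume the
only gold span available to a later prediction, understating `PAR` — and
therefore cannot agree exactly with an exhaustive one-to-one matcher.
`ner_metrics` instead computes an exact maximum-credit one-to-one
matching per sentence (memoised search over predictions × used-gold
subsets; candidates are restricted to overlapping spans, so the state
space is tiny for real sentences), with deterministic tie-breaks (prefer
exact matches, then larger overlap, then earlier gold start). One gold
span can match at most one prediction; whether a gold span may partially
match several predictions was left open by the formulas, and the
one-to-one reading is the conservative one. Partial-mode metrics
dominate strict-mode metrics on every instance because partial credit is
a superset of exact credit over the same denominators — this is asserted
property-style in the tests.

## Strain normalization

Terms are normalized (case-fold, whitespace collapse, hyphen rule),
optionally rewritten through a curated variant table, then matched in
two stages:

1. **Local stage** (`tau_local = 0.90` similarity): best approximate-
   substring Levenshtein match between the shorter and longer of
   term/alias. Because the local stage exists to handle *abbreviated*
   partial names, single-letter abbreviated tokens are first expanded
   against the alias token sharing their initial ("E. coli MG1655" →
   "escherichia coli mg1655" against the alias "Escherichia coli
   MG1655", distance 0). Without that expansion a plain partial distance
   for this canonical example is 2 on a 14-character pattern (similarity
   0.857) and no sensible threshold separates it from noise.
2. **Full stage** (`tau_full = 0.10`): best full Levenshtein distance
   normalized by the longer string.

Ties break by smaller distance, then lexicographic canonical id. The
thresholds are engineering defaults, exposed in the configuration; the
original values were never published. At `tau_full = 0.10`, one edit on
a name of ≥ 15 characters (distance ≤ 1/15 ≈ 0.067) is always
recoverable, which the acceptance suite checks at 100%.

Non-strain term variants (plurals, typos) are clustered by single
linkage under normalized Levenshtein ≤ `tau_cluster = 0.20` after
case-folding and plural-`s` stripping; the representative is the member
with the most literature occurrences. Input order never matters: terms
are canonically sorted before linkage.

## Phenotype network

`build_graph` makes one node per (term, category) and one directed edge
per (source, target, relation type), with a support count of distinct
supporting records; records below 0.5, self-loops and unknown relation
types are excluded. Exact duplicate records are collapsed first, so
support counts distinct sentences — the same duplicate-guard stance the
trophic module takes.

The degree-distribution fit is Clauset-style: for each candidate lower
cutoff `x_min`, the discrete power-law exponent is estimated by maximum
likelihood (normalization by the Hurwitz zeta function, computed by
direct summation with an Euler–Maclaurin tail), and the `x_min` with the
smallest Kolmogorov–Smirnov distance wins. The description "KS test
against log-normal fit" is statistically ambiguous, so both readings are
reported: KS distances for the power-law *and* a discrete log-normal fit
on the same tail, plus a Vuong-type normalized likelihood-ratio
statistic with a two-sided p-value. Degenerate (all-equal) sequences and
tails under 100 positive-degree nodes are errors, not silent fits.

The "main component" is the largest *weakly* connected component (the
direction-blind reading; the alternative was never specified).
Betweenness is exact Brandes on the directed graph with parallel typed
edges collapsed and no weights; vertex Jaccard similarity uses the union
of in- and out-neighbors excluding the paired nodes themselves, computed
only for pairs sharing at least one neighbor; communities come from
seeded Leiden (modularity objective) on the undirected projection.

## Trophic inference

Within an environment subnetwork (strains with an `INHABITS` edge to the
environment term, plus their compound edges), the four triad motifs are:
competition (two strains degrade the same compound, −), direct
inhibition (a strain produces a compound that inhibits another, −),
cross-feeding (one strain degrades what another produces, +) and
resistance development (a strain resists a compound another produces,
+). Each distinct (pair, compound, type) counts **once** regardless of
sentence multiplicity — literature popularity should not multiply
inferred ecology; support counts are exported separately. Interaction
weights net the counts per unordered pair, `w = n⁺ − n⁻`, with the
per-direction breakdown retained as an attribute for users who need
directional cross-feeding. Enumeration is verified against a brute-force
triple enumerator on random subnetworks.

## Gene–phenotype association

Assemblies are encoded by Pfam copy counts from InterProScan-dialect
tables (only `Pfam` analysis rows; malformed rows are skipped loudly).
The genus of a strain is the first whitespace token of its organism
name, overridable by a taxonomy table. A phenotype cluster is one
(relation type, entity term) pair with ≥ 3 occurrences, binarized
against the relation-type universe — negatives are the other assemblies
*within the same relation type*, the more conservative reading of an
ambiguous sentence, so that models discriminate terms rather than
relation participation. Modeling requires ≥ 10 positive assemblies from
≥ 5 genera with the top genus strictly under 30%, all as printed.

The classifier is a native Rcpp implementation of the standard
gradient-boosted tree configuration (no boosting library ships in this
environment): depth ≤ 6, learning rate 0.3, binary logistic objective,
second-order Newton leaf weights with L2 regularisation λ = 1, exact
greedy splits, no subsampling (hence deterministic given the split),
≤ 5000 rounds with early stopping after 10 rounds without validation
log-loss improvement. Early stopping uses an inner stratified 10% slice
of the training portion — using the 20% test set would leak — and
hold-out accuracy is computed on the untouched test set at threshold
0.5. Retention is strictly `accuracy > 0.8`. Gain importance is the
total split-gain per feature (with the per-split average also reported),
matching the conventional "average training-loss improvement" reading.

GO enrichment pools the annotated gene copies of all assemblies involved
in a relation against a background pool, one Fisher exact test (two-
sided) per GO term through a Pfam→GO mapping table, with
Benjamini–Hochberg q-values. The GO release is pinned by whichever
mapping file the user supplies.

## Synthetic generators: the stated world

Every generator draws from an isolated seeded stream, so outputs are
bit-reproducible and never perturb (or depend on) the caller's RNG.
Defaults mirror the documented composition of a realistic annotated set:
35.1% entity-free sentences, 64.2% strain-bearing sentences. The
relation-record generator plants a discrete power-law out-degree
sequence (default exponent 2.5, between the 2.1/2.6 in/out exponents a
real literature network exhibits) and wires strains to distinct entity
partners, so the out-degrees of degree-positive nodes *are* the planted
sequence; the compound→strain `INHIBITS` direction is available as an
option but defaults off so the fit is exercised on a clean sample. The
generator is bipartite (strain→entity) by construction, which is what
the real extraction schema produces — exactly one `STRAIN` endpoint per
record.

The genome generator uses Poisson(λ = 4) background copy counts and
labels from `logit P(y=1) = Σ β_f (x_f − (λ + 0.5))`. The half-integer
offset places the decision boundary *between* attainable copy numbers —
copy-number phenotypes are threshold-like (e.g. resistance conferred by
an extra copy) — making the planted signal Bayes-separable; with a
mid-integer boundary (offset λ) the mass at the boundary count caps
achievable accuracy near 0.83 and the > 0.8 recovery criterion would
hinge on noise. This choice was made a priori as part of the stated
world and is what the planted-recovery tests certify.

What a green test does **not** establish: the generators produce
template text, clean offsets, honest scores and independent Poisson
features. Real literature has nested and discontinuous entities,
OCR/encoding noise, correlated gene content along phylogeny, and
prediction scores that are miscalibrated in structured ways. Results on
synthetic fixtures certify the *algorithms*, not model quality on real
text.

## Numerical choices and degenerate inputs

* Probability floor `1e-12` in the loss; triggered floors warn.
* Threshold comparisons: score ≥ 0.5 (inclusive); accuracy > 0.8,
  genus share < 0.30, English confidence > 0.40 (all strict, as
  printed).
* Hurwitz zeta: 1000 direct terms plus a fourth-order Euler–Maclaurin
  tail (relative error ≲ 1e-10 over the exponents encountered).
* Exponent search interval (1.0001, 25); log-normal fit by Nelder–Mead
  on (μ, log σ) with the support truncated at 10× the maximum degree.
* Ties everywhere break deterministically (documented per function), so
  equal seeds give byte-identical outputs.
* Empty inputs return empty typed results; contractually impossible
  inputs (empty catalog, unknown environment term, single-class labels,
  degenerate degree sequences) raise errors with actionable messages.

## Limitations

* The transformers, their subword tokenizers, UMAP visualisations, PMC
  retrieval, live database access and positive-selection analyses are
  out of scope by design.
* Normalization thresholds are defaults chosen here, not recovered
  study parameters; treat mapped/unmapped rates as threshold-dependent.
* The Jaccard pair scan enumerates co-neighbor pairs; on hub-dominated
  million-edge networks this needs the usual top-k sparsification
  before use.
* The boosted-tree implementation covers the configuration the pipeline
  prescribes (exact splits, logistic objective); it is not a general
  replacement for a full boosting library.
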