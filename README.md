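# phenomine

Literature-mined microbial phenotype networks, trophic interaction
inference and gene–phenotype association — as a tested, offline R toolkit.

## The problem

Large language models fine-tuned for named-entity recognition (NER) and
relation extraction (RE) can mine millions of literature sentences for
bacterial phenotype statements: which strain grows on which medium,
produces or degrades which compound, inhabits which host. Around those
models sits a substantial computational pipeline that is just as important
for the final biology and — unlike the GPU-bound transformers — fully
reproducible at desk scale. `phenomine` implements that pipeline for
people who build or audit such literature-mining systems:

* **Corpus preparation** — section/language/duplicate filtering, the
  hyphen rule, the <512-character paragraph rule, a deterministic
  reference tokenizer, per-token Begin/Inside/Outside (BIO) encoding over
  9 entity categories (`STRAIN`, `SPECIES`, `ORGANISM`, `PHENOTYPE`,
  `EFFECT`, `DISEASE`, `MEDIUM`, `ISOLATE`, `COMPOUND`), stratified
  65/17.5/17.5 and 60/20/20 splits, and class-imbalance augmentation
  (`N_aug = max(0, N_neg − N_pos)` for NER, `⌈0.2 (N_neg − N_pos)⌉` for
  RE) by strain-term swapping.
* **Evaluation** — cross-entropy loss
  `L = −(1/N) Σᵢ Σₜ Σ_c δ(y_it, c) log p̂_itc`, max-aggregation of token
  scores into spans with the inclusive 0.5 threshold, strict
  (`P = COR/(TP+FP)`) and partial (`P = (COR + 0.5·PAR)/(TP+FP)`)
  span-matching metrics with an exact one-to-one matcher, and binary RE
  metrics (`F1 = 2PR/(P+R)`).
* **Strain normalization** — two-stage Levenshtein resolution against a
  StrainSelect-like catalog (abbreviation-aware local/partial match, then
  full normalized distance), plus single-linkage clustering of
  non-strain term variants with occurrence-count representatives.
* **Phenotype network** — typed directed graph `G = (V, E)` over entity
  terms; discrete power-law fit `P(k) ∼ k^(−α)` with Clauset-style
  maximum likelihood, `x_min` selection by Kolmogorov–Smirnov distance
  and a log-normal likelihood-ratio comparison; weak-component fractions,
  betweenness centrality, vertex Jaccard similarity and Leiden
  modularity.
* **Trophic inference** — environment-restricted subnetworks via
  `INHABITS`, enumeration of the four triad motifs (competition and
  direct inhibition, negative; cross-feeding and resistance development,
  positive) and per-pair interaction weights `w_ij = n⁺_ij − n⁻_ij`.
* **Gene–phenotype association** — Pfam copy-number feature matrices from
  InterProScan-dialect tables, binarized phenotype clusters (term ≥ 3
  occurrences; ≥ 10 assemblies, ≥ 5 genera, top genus < 30%),
  gradient-boosted trees (depth 6, learning rate 0.3, binary logistic,
  ≤ 5000 rounds, 10-round early stopping; implemented natively in Rcpp)
  with a strict > 80% accuracy retention gate and gain-based feature
  ranking, plus pooled Fisher/Benjamini–Hochberg GO enrichment.
* **Benchmarking** — accuracy against conflicting phenotypes for a
  curated reference snapshot matched by genome accession.
* **Synthetic generators** — seeded generators for every input above,
  with ground truth retained, so the whole pipeline runs and is verified
  with no downloads and no GPU.

## Worked example

```r
library(phenomine)

## a relation-record set whose strain degrees follow a power law
rr <- gen_relation_records(n_strains = 2000, alpha = 2.5, seed = 7)
g <- build_graph(rr$records)
g
#> <phenotype_graph> 2200 nodes, 3559 typed edges, 3559 records

fit_degree_distribution(g, direction = "out")
#> <degree_fit> alpha=2.493 xmin=1 n_tail=2000 KS=0.0067 (lognormal KS=0.0071) LR=-0.37 p=0.586

cs <- component_stats(g)
cm <- community_modularity(g, seed = 7)
cs$node_fraction   # 1.0 — the network is one weak component
cm$modularity      # 0.634 over 30 Leiden communities

## trophic triads: 3 planted cross-feeding + 1 competition = net weight 2
gt <- gen_trophic(data.frame(strain_i = "S1", strain_j = "S2",
                             type = c("cross_feeding", "competition"),
                             count = c(3, 1)), seed = 7)
interaction_weights(enumerate_triads(gt$subnetwork))
#>   strain_i strain_j n_pos n_neg w
#> 1       S1       S2     3     1 2
```

The estimated exponent (2.49 for a planted 2.5) is the discrete maximum
likelihood fit; `KS` vs `lognormal KS` and the likelihood ratio `LR`
report how the power law compares against a discrete log-normal on the
same tail. The interaction weight `w = 2` nets the three positive
cross-feeding triads against the one competition triad.

## Command line

```sh
Rscript inst/cli/phenomine.R simulate     --config pipeline.yaml
Rscript inst/cli/phenomine.R build-network --config pipeline.yaml
Rscript inst/cli/phenomine.R analyze-network --config pipeline.yaml
```

Stages (`simulate`, `prep-corpus`, `normalize`, `build-network`,
`analyze-network`, `infer-trophic`, `gene-pheno`, `benchmark`) compose
through a YAML config with CLI overrides; every stage writes atomically
and appends a manifest line (input hashes, seed, version, counts).

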