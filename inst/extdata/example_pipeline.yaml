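# Example pipeline configuration for the phenomine CLI.
# Run, from anywhere:
#   Rscript inst/cli/phenomine.R simulate --config inst/extdata/example_pipeline.yaml
#   Rscript inst/cli/phenomine.R build-network --config inst/extdata/example_pipeline.yaml
seed: 1
out_dir: phenomine_out
score_threshold: 0.5        # NER/RE retention (inclusive)
min_english_confidence: 0.4 # strict >
tau_local: 0.90             # local-stage similarity
tau_full: 0.10              # full-stage normalized distance
tau_cluster: 0.20           # term-variant single linkage
min_term_count: 3
min_assemblies: 10
min_genera: 5
max_genus_share: 0.30       # strict <
sim_n_sentences: 500
sim_n_strains: 500
sim_alpha: 2.5
environment: synthetic_env
paths:
  relation_records: phenomine_out/relation_records.tsv
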