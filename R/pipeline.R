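# Pipeline orchestration: stages as composable functions with a YAML/JSON
# config, structured per-stage logging and a manifest recording inputs,
# seeds and counts. Stage outputs are pure functions of (inputs, config,
# seed) and are written atomically.

#' Load a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration and merges it over the defaults
#' from [default_pipeline_config()].
#'
#' @param path YAML or JSON config file; `NULL` for pure defaults.
#' @param overrides Named list of keys overriding the file (CLI flags).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    loaded <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path) else
      yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, loaded)
  }
  cfg <- utils::modifyList(cfg, overrides)
  stopifnot(cfg$score_threshold >= 0, cfg$score_threshold <= 1,
            cfg$tau_local >= 0, cfg$tau_local <= 1,
            cfg$tau_full >= 0, cfg$tau_full <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Default pipeline configuration
#'
#' All thresholds at their documented defaults: NER/RE score threshold 0.5,
#' normalization thresholds `tau_local` 0.90 / `tau_full` 0.10 /
#' `tau_cluster` 0.20, cluster filters (>= 10 assemblies, >= 5 genera,
#' < 30% top-genus share), and the gradient-boosting configuration of
#' [model_config()].
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    out_dir = "phenomine_out",
    seed = 1L,
    score_threshold = 0.5,
    min_english_confidence = 0.4,
    tau_local = 0.90, tau_full = 0.10, tau_cluster = 0.20,
    min_term_count = 3L, min_assemblies = 10L, min_genera = 5L,
    max_genus_share = 0.30,
    sim_n_sentences = 500L, sim_n_strains = 500L, sim_alpha = 2.5,
    environment = "synthetic_env",
    paths = list())
}

# atomic write: write to tempfile in the same directory, then rename
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writer(tmp)
  file.rename(tmp, path)
  path
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

manifest_entry <- function(cfg, stage, inputs, outputs, counts) {
  list(stage = stage, seed = cfg$seed,
       version = as.character(utils::packageVersion("phenomine")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       inputs = lapply(inputs, function(p)
         list(path = p, md5 = unname(tools::md5sum(p)))),
       outputs = outputs, counts = counts)
}

append_manifest <- function(cfg, entry) {
  path <- file.path(cfg$out_dir, "manifest.jsonl")
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (generate every synthetic input), `prep-corpus`
#' (filter raw sentence records), `normalize` (strain-term resolution),
#' `build-network`, `analyze-network` (components, degree fit, centrality,
#' Jaccard, communities), `infer-trophic`, `gene-pheno` and `benchmark`.
#' Upstream artifact paths are taken from `config$paths`; each stage writes
#' its outputs atomically under `config$out_dir` and appends a manifest
#' record with input hashes, seed, package version and record counts.
#'
#' @param name Stage name.
#' @param config A `pipeline_config`.
#' @return Invisibly, the manifest entry of the stage.
#' @export
run_stage <- function(name, config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(key) {
    p <- config$paths[[key]]
    if (is.null(p) || !file.exists(p)) {
      stop("missing upstream artifact '", key, "' (",
           if (is.null(p)) "not configured" else p,
           ") required by stage ", name, call. = FALSE)
    }
    p
  }
  entry <- switch(
    name,
    "simulate" = {
      gc_ <- gen_corpus(config$sim_n_sentences, seed = config$seed)
      stem <- file.path(config$out_dir, "synthetic")
      write_corpus(gc_$sentences, stem)
      rr <- gen_relation_records(config$sim_n_strains,
                                 alpha = config$sim_alpha,
                                 seed = config$seed)
      rec_path <- file.path(config$out_dir, "relation_records.tsv")
      atomic_write(function(p) write_relation_records(rr$records, p),
                   rec_path)
      stage_log(name, "%d sentences, %d relation records",
                length(gc_$sentences), nrow(rr$records))
      manifest_entry(config, name, character(),
                     c(paste0(stem, ".sentences.jsonl"), rec_path),
                     list(sentences = length(gc_$sentences),
                          records = nrow(rr$records)))
    },
    "prep-corpus" = {
      raw <- read_sentence_records(need("raw_sentences"))
      fc <- filter_corpus(raw, config$min_english_confidence)
      stem <- file.path(config$out_dir, "corpus")
      write_corpus(fc$sentences, stem)
      drop_path <- file.path(config$out_dir, "corpus_dropped.tsv")
      atomic_write(function(p) write.table(fc$dropped, p, sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE), drop_path)
      stage_log(name, "%d in, %d kept, %d dropped", nrow(raw),
                length(fc$sentences), nrow(fc$dropped))
      manifest_entry(config, name, need("raw_sentences"),
                     paste0(stem, ".sentences.jsonl"),
                     list(records_in = nrow(raw),
                          kept = length(fc$sentences),
                          dropped = nrow(fc$dropped)))
    },
    "eval-ner" = {
      stem <- config$paths$gold_corpus_stem
      if (is.null(stem) ||
          !file.exists(paste0(stem, ".sentences.jsonl"))) {
        stop("missing upstream artifact 'gold_corpus_stem' required by ",
             "stage ", name, call. = FALSE)
      }
      sentences <- read_corpus(stem)
      preds <- read_span_predictions(need("ner_predictions"))
      rep_ <- evaluate_ner(preds, sentences,
                           threshold = config$score_threshold)
      out <- file.path(config$out_dir, "ner_metrics.tsv")
      atomic_write(function(p) write.table(rep_, p, sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE), out)
      stage_log(name, "%d category x mode rows", nrow(rep_))
      manifest_entry(config, name, need("ner_predictions"), out,
                     list(rows = nrow(rep_)))
    },
    "eval-re" = {
      stem <- config$paths$gold_corpus_stem
      if (is.null(stem) ||
          !file.exists(paste0(stem, ".sentences.jsonl"))) {
        stop("missing upstream artifact 'gold_corpus_stem' required by ",
             "stage ", name, call. = FALSE)
      }
      sentences <- read_corpus(stem)
      preds <- read.delim(need("re_predictions"))
      rep_ <- evaluate_re(preds, sentences)
      out <- file.path(config$out_dir, "re_metrics.tsv")
      atomic_write(function(p) write.table(rep_, p, sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE), out)
      stage_log(name, "%d relation rows", nrow(rep_))
      manifest_entry(config, name, need("re_predictions"), out,
                     list(rows = nrow(rep_)))
    },
    "normalize" = {
      records <- read_relation_records(need("relation_records"))
      catalog <- read_strain_catalog(need("strain_catalog"))
      strains <- unique(records$source_term[
        records$source_category == "STRAIN"])
      nm <- normalize_strains(strains, catalog, config$tau_local,
                              config$tau_full)
      out <- file.path(config$out_dir, "normalization.tsv")
      atomic_write(function(p) write.table(nm, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE), out)
      stage_log(name, "%d terms, %d mapped", nrow(nm),
                sum(!is.na(nm$canonical_id)))
      manifest_entry(config, name,
                     c(need("relation_records"), need("strain_catalog")),
                     out, list(terms = nrow(nm),
                               mapped = sum(!is.na(nm$canonical_id))))
    },
    "build-network" = {
      records <- read_relation_records(need("relation_records"))
      g <- build_graph(records, config$score_threshold)
      tsv <- file.path(config$out_dir, "network_edges.tsv")
      gml <- file.path(config$out_dir, "network.graphml")
      write_graph_files(g, tsv, gml)
      stage_log(name, "%d nodes, %d typed edges",
                igraph::vcount(g$graph), igraph::ecount(g$graph))
      manifest_entry(config, name, need("relation_records"), c(tsv, gml),
                     list(nodes = igraph::vcount(g$graph),
                          edges = igraph::ecount(g$graph),
                          records = g$n_records))
    },
    "analyze-network" = {
      records <- read_relation_records(need("relation_records"))
      g <- build_graph(records, config$score_threshold)
      comp <- component_stats(g)
      fit <- tryCatch(fit_degree_distribution(g, "out"),
                      error = function(e) NULL)
      cm <- community_modularity(g, seed = config$seed)
      cent <- centrality_table(g)
      jac <- jaccard_pairs(g, 10L)
      report <- list(
        components = comp,
        degree_fit = if (is.null(fit)) NULL else
          fit[c("alpha", "xmin", "ks", "ks_lognormal", "p_value",
                "n_tail")],
        modularity = cm$modularity,
        n_communities = length(unique(cm$membership)),
        top_betweenness = head(cent, 10L),
        top_jaccard = jac)
      out <- file.path(config$out_dir, "network_report.json")
      atomic_write(function(p) jsonlite::write_json(
        report, p, auto_unbox = TRUE, digits = NA, dataframe = "rows",
        pretty = TRUE, force = TRUE), out)
      stage_log(name, "main component %.1f%% nodes, modularity %.3f",
                100 * comp$node_fraction, cm$modularity)
      manifest_entry(config, name, need("relation_records"), out,
                     list(nodes = igraph::vcount(g$graph)))
    },
    "infer-trophic" = {
      records <- read_relation_records(need("relation_records"))
      g <- build_graph(records, config$score_threshold)
      sub <- extract_environment_subnetwork(g, config$environment)
      tri <- enumerate_triads(sub)
      w <- interaction_weights(tri)
      out <- file.path(config$out_dir, "interactions.tsv")
      atomic_write(function(p) write_interactions(w, p), out)
      stage_log(name, "%d strains, %d triads, %d weighted pairs",
                length(sub$strains), nrow(tri), nrow(w))
      manifest_entry(config, name, need("relation_records"), out,
                     list(strains = length(sub$strains),
                          triads = nrow(tri), pairs = nrow(w)))
    },
    "gene-pheno" = {
      records <- read.delim(need("normalized_records"))
      manifest <- read.delim(need("annotation_manifest"),
                             colClasses = "character")
      ann <- read_annotations(manifest)
      clusters <- define_clusters(records, ann, config$min_term_count)
      kept <- filter_clusters(clusters, ann, config$min_assemblies,
                              config$min_genera, config$max_genus_share)
      summaries <- lapply(kept, function(cl)
        train_and_rank(cl, ann, model_config(seed = config$seed)))
      res <- do.call(rbind, lapply(summaries, function(s)
        data.frame(cluster = s$cluster_id, accuracy = s$accuracy,
                   retained = s$retained,
                   top_feature = s$importance$feature[1])))
      out <- file.path(config$out_dir, "gene_pheno.tsv")
      atomic_write(function(p) write.table(
        if (is.null(res)) data.frame() else res, p, sep = "\t",
        quote = FALSE, row.names = FALSE), out)
      stage_log(name, "%d clusters, %d modeled, %d retained",
                length(clusters), length(kept),
                if (is.null(res)) 0L else sum(res$retained))
      manifest_entry(config, name,
                     c(need("normalized_records"),
                       need("annotation_manifest")), out,
                     list(clusters = length(clusters),
                          modeled = length(kept)))
    },
    "benchmark" = {
      preds <- read.delim(need("benchmark_predictions"))
      ref <- read.delim(need("benchmark_reference"))
      pats <- read.delim(need("benchmark_patterns"))
      res <- match_predictions(preds, ref, pats)
      out <- file.path(config$out_dir, "benchmark.tsv")
      atomic_write(function(p) write.table(res, p, sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE), out)
      stage_log(name, "%d phenotypes scored", nrow(res))
      manifest_entry(config, name,
                     c(need("benchmark_predictions"),
                       need("benchmark_reference")), out,
                     list(phenotypes = nrow(res)))
    },
    stop("unknown stage: ", name, call. = FALSE))
  append_manifest(config, entry)
  invisible(entry)
}

#' Run a sequence of pipeline stages
#'
#' @param config A `pipeline_config`.
#' @param stages Character vector of stage names, executed in order.
#' @return Invisibly, list of manifest entries.
#' @export
run_pipeline <- function(config, stages) {
  invisible(lapply(stages, run_stage, config = config))
}
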