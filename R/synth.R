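# Seeded synthetic-data generators emulating every input the pipeline
# consumes, with ground truth retained so downstream operations can be
# scored exactly: annotated corpora with planted spans/relations, relation
# record sets with power-law strain degrees, trophic subnetworks with
# planted triad motifs, Pfam copy-count feature matrices under a logistic
# label model, and strain catalogs with bounded edit-operation variants.

synth_vocab <- function() {
  list(
    genera = c("Bacillus", "Escherichia", "Pseudomonas", "Lactobacillus",
               "Streptomyces", "Klebsiella", "Acinetobacter", "Rhodococcus"),
    species = c("subtilis", "coli", "putida", "plantarum", "griseus",
                "pneumoniae", "baumannii", "erythropolis"),
    compounds = c("glucose", "lactate", "butyrate", "tetracycline",
                  "cellulose", "xylose", "acetate", "ethanol"),
    phenotypes = c("gram negative", "gram positive", "motile", "aerobic",
                   "anaerobic", "rod shaped", "spore forming",
                   "thermophilic"),
    media = c("LB medium", "TSB", "nutrient agar", "MRS broth", "R2A"),
    organisms = c("mouse", "human", "Arabidopsis thaliana", "maize",
                  "zebrafish"),
    isolates = c("soil", "marine sediment", "rhizosphere", "wastewater",
                 "feces"),
    diseases = c("pneumonia", "mastitis", "root rot", "sepsis"),
    effects = c("plant growth", "immune response", "biofilm formation"))
}

synth_strain_name <- function(rng, vocab = synth_vocab()) {
  paste0(vocab$genera[rng$draw_int(length(vocab$genera))], " ",
         vocab$species[rng$draw_int(length(vocab$species))], " STR ",
         sprintf("%04d", rng$draw_int(9999L)))
}

#' Generate an annotated corpus with planted spans and relations
#'
#' Template-based sentences with entity spans and binary relations planted
#' at configured frequencies: a configurable fraction of entity-free
#' sentences (default 0.351, mirroring the composition of a realistic
#' annotated set), a configurable fraction of STRAIN-bearing sentences
#' (default 0.642), the remainder carrying non-STRAIN entities only.
#'
#' @param n_sentences Number of sentences.
#' @param entity_free_fraction Fraction of sentences with no entities.
#' @param strain_fraction Fraction of sentences with a STRAIN span.
#' @param seed Integer seed; the same seed yields a byte-identical corpus.
#' @return List with `sentences` (list of [annotated_sentence()]) and
#'   `truth` (`data.frame`: per sentence, `id`, `kind`, `n_spans`,
#'   `n_relations`).
#' @export
gen_corpus <- function(n_sentences = 1000L, entity_free_fraction = 0.351,
                       strain_fraction = 0.642, seed = 1L) {
  stopifnot(n_sentences > 0,
            entity_free_fraction + strain_fraction <= 1 + 1e-9)
  vocab <- synth_vocab()
  rng <- local_rng(seed)
  empty_templates <- c(
    "The cultures were incubated overnight at 37 degrees .",
    "Statistical analyses were performed using standard methods .",
    "Samples were centrifuged and the supernatant was discarded .",
    "The results suggest a broad diversity of metabolic pathways .")
  sentences <- vector("list", n_sentences)
  truth <- data.frame(id = character(n_sentences),
                      kind = character(n_sentences),
                      n_spans = integer(n_sentences),
                      n_relations = integer(n_sentences))
  for (i in seq_len(n_sentences)) {
    u <- rng$runif(1)
    id <- sprintf("syn%05d", i)
    if (u < entity_free_fraction) {
      text <- empty_templates[rng$draw_int(length(empty_templates))]
      s <- annotated_sentence(id, text)
      kind <- "entity_free"
    } else if (u < entity_free_fraction + strain_fraction) {
      strain <- synth_strain_name(rng, vocab)
      tmpl <- rng$draw_int(4L)
      if (tmpl == 1L) {
        other <- vocab$compounds[rng$draw_int(length(vocab$compounds))]
        parts <- c("Strain ", strain, " produces ", other, " in culture .")
        cat2 <- "COMPOUND"; rel <- "PRODUCES"
      } else if (tmpl == 2L) {
        other <- vocab$media[rng$draw_int(length(vocab$media))]
        parts <- c("Strain ", strain, " grows on ", other, " .")
        cat2 <- "MEDIUM"; rel <- "GROWS_ON"
      } else if (tmpl == 3L) {
        other <- vocab$phenotypes[rng$draw_int(length(vocab$phenotypes))]
        parts <- c("Strain ", strain, " is ", other, " .")
        cat2 <- "PHENOTYPE"; rel <- "PRESENTS"
      } else {
        other <- vocab$isolates[rng$draw_int(length(vocab$isolates))]
        parts <- c("Strain ", strain, " was isolated from ", other, " .")
        cat2 <- "ISOLATE"; rel <- "INHABITS"
      }
      text <- paste(parts, collapse = "")
      off <- cumsum(c(0L, nchar(parts)))
      spans <- data.frame(
        category = c("STRAIN", cat2),
        start = c(off[2], off[4]), end = c(off[3], off[5]))
      relations <- data.frame(type = rel, source_idx = 1L, target_idx = 2L,
                              label = 1L)
      s <- annotated_sentence(id, text, spans = spans,
                              relations = relations)
      kind <- "strain"
    } else {
      other <- vocab$compounds[rng$draw_int(length(vocab$compounds))]
      parts <- c("High concentrations of ", other, " were detected .")
      text <- paste(parts, collapse = "")
      off <- cumsum(c(0L, nchar(parts)))
      spans <- data.frame(category = "COMPOUND", start = off[2],
                          end = off[3])
      s <- annotated_sentence(id, text, spans = spans)
      kind <- "other_entity"
    }
    sentences[[i]] <- s
    truth$id[i] <- id
    truth$kind[i] <- kind
    truth$n_spans[i] <- nrow(s$spans)
    truth$n_relations[i] <- nrow(s$relations)
  }
  list(sentences = sentences, truth = truth)
}

#' Generate relation records with a power-law strain degree sequence
#'
#' Samples per-strain out-degrees from a discrete power law with exponent
#' `alpha` and wires each strain to that many distinct entity partners
#' (configuration-model style), assigning entity categories and compatible
#' relation types per the annotation schema. All edges run STRAIN to entity
#' by default, so the out-degree sequence of degree-positive nodes is
#' exactly the planted sequence; an optional fraction of
#' `COMPOUND-STRAIN:INHIBITS` records (entity to strain) can be added.
#'
#' @param n_strains Number of strain nodes (>= 100).
#' @param alpha Power-law exponent (> 1).
#' @param n_entities Entity partner pool size; default scales with the
#'   maximum sampled degree.
#' @param inhibits_fraction Fraction of additional compound-to-strain
#'   `INHIBITS` records (default 0).
#' @param seed Integer seed.
#' @return List with `records` (`data.frame` ready for [build_graph()]) and
#'   `truth` (`degrees`, `n_edges`, `n_nodes`).
#' @export
gen_relation_records <- function(n_strains = 1000L, alpha = 2.5,
                                 n_entities = NULL, inhibits_fraction = 0,
                                 seed = 1L) {
  stopifnot(n_strains >= 100L, alpha > 1)
  rng <- local_rng(seed)
  degrees <- rpowerlaw(n_strains, alpha, xmin = 1L, seed = rng$child_seed())
  if (is.null(n_entities)) n_entities <- max(200L, 2L * max(degrees))
  if (max(degrees) > n_entities) stop("infeasible degree sequence")
  cats <- c("COMPOUND", "MEDIUM", "ORGANISM", "PHENOTYPE", "ISOLATE")
  rel_for <- list(COMPOUND = c("PRODUCES", "DEGRADES", "RESISTS"),
                  MEDIUM = "GROWS_ON", ORGANISM = "INHABITS",
                  PHENOTYPE = "PRESENTS", ISOLATE = "INHABITS")
  ent_cat <- cats[rng$draw(length(cats), n_entities, replace = TRUE)]
  ent_term <- paste0(tolower(ent_cat), "_", seq_len(n_entities))
  strains <- sprintf("strain_%05d", seq_len(n_strains))
  rows <- vector("list", n_strains)
  sid <- 0L
  for (i in seq_len(n_strains)) {
    d <- degrees[i]
    partners <- rng$draw(n_entities, d)
    rel <- vapply(partners, function(p) {
      opts <- rel_for[[ent_cat[p]]]
      opts[rng$draw_int(length(opts))]
    }, character(1))
    rows[[i]] <- data.frame(
      sentence_id = sprintf("s%07d", sid + seq_len(d)),
      source_term = strains[i], source_category = "STRAIN",
      target_term = ent_term[partners], target_category = ent_cat[partners],
      relation_type = rel,
      score = 0.5 + 0.5 * rng$runif(d))
    sid <- sid + d
  }
  records <- do.call(rbind, rows)
  if (inhibits_fraction > 0) {
    k <- ceiling(inhibits_fraction * nrow(records))
    comp <- which(ent_cat == "COMPOUND")
    extra <- data.frame(
      sentence_id = sprintf("s%07d", sid + seq_len(k)),
      source_term = ent_term[comp[rng$draw(length(comp), k,
                                           replace = TRUE)]],
      source_category = "COMPOUND",
      target_term = strains[rng$draw(n_strains, k, replace = TRUE)],
      target_category = "STRAIN", relation_type = "INHIBITS",
      score = 0.5 + 0.5 * rng$runif(k))
    extra <- extra[!duplicated(extra[, c("source_term", "target_term")]), ,
                   drop = FALSE]
    records <- rbind(records, extra)
  }
  used_entities <- unique(records$target_term[
    records$target_category != "STRAIN"])
  list(records = records,
       truth = list(degrees = degrees, n_edges = nrow(records),
                    n_nodes = n_strains + length(used_entities),
                    strains = strains))
}

#' Generate a trophic subnetwork with planted triad motifs
#'
#' Builds an environment subnetwork containing exactly the planted triads
#' (each on its own fresh mediating compound) plus decoy edges that complete
#' no motif (each decoy compound touches exactly one strain edge).
#'
#' @param plants `data.frame` with `strain_i`, `strain_j`, `type` (one of
#'   `competition`, `direct_inhibition`, `cross_feeding`, `resistance`) and
#'   `count` (how many such triads to plant, each via a distinct compound).
#' @param n_decoys Number of motif-free decoy edges (default 10).
#' @param environment Environment label (default `"synthetic_env"`).
#' @param seed Integer seed.
#' @return List with `subnetwork` (an [environment_subnetwork()]) and
#'   `truth` (expected per-pair `n_pos`/`n_neg`/`w` table).
#' @export
gen_trophic <- function(plants, n_decoys = 10L,
                        environment = "synthetic_env", seed = 1L) {
  plants <- as.data.frame(plants)
  sign_of <- c(competition = -1L, direct_inhibition = -1L,
               cross_feeding = +1L, resistance = +1L)
  if (nrow(plants)) {
    stopifnot(all(c("strain_i", "strain_j", "type", "count") %in%
                    names(plants)))
    if (any(!plants$type %in% names(sign_of)) ||
        any(plants$count < 1) ||
        any(plants$strain_i == plants$strain_j)) {
      stop("contradictory plant list")
    }
  }
  rng <- local_rng(seed)
  edges <- list()
  add_edge <- function(source, target, type) {
    edges[[length(edges) + 1L]] <<- data.frame(source = source,
                                               target = target, type = type)
  }
  comp_id <- 0L
  for (r in seq_len(nrow(plants))) {
    si <- plants$strain_i[r]; sj <- plants$strain_j[r]
    for (k in seq_len(plants$count[r])) {
      comp_id <- comp_id + 1L
      comp <- sprintf("compound_%03d", comp_id)
      switch(plants$type[r],
        competition = {
          add_edge(si, comp, "DEGRADES"); add_edge(sj, comp, "DEGRADES")
        },
        direct_inhibition = {
          add_edge(si, comp, "PRODUCES"); add_edge(comp, sj, "INHIBITS")
        },
        cross_feeding = {
          add_edge(si, comp, "PRODUCES"); add_edge(sj, comp, "DEGRADES")
        },
        resistance = {
          add_edge(si, comp, "PRODUCES"); add_edge(sj, comp, "RESISTS")
        })
    }
  }
  strains <- sort(unique(c(plants$strain_i, plants$strain_j)))
  if (!length(strains)) strains <- c("decoy_strain_1", "decoy_strain_2")
  for (k in seq_len(n_decoys)) {
    comp_id <- comp_id + 1L
    comp <- sprintf("compound_%03d", comp_id)
    s <- strains[rng$draw_int(length(strains))]
    type <- c("PRODUCES", "DEGRADES", "RESISTS")[rng$draw_int(3L)]
    add_edge(s, comp, type)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(),
               type = character())
  truth <- if (nrow(plants)) {
    a <- pmin(plants$strain_i, plants$strain_j)
    b <- pmax(plants$strain_i, plants$strain_j)
    sg <- sign_of[plants$type]
    agg <- aggregate(
      list(n_pos = plants$count * (sg > 0),
           n_neg = plants$count * (sg < 0)),
      by = list(strain_i = a, strain_j = b), FUN = sum)
    agg$w <- agg$n_pos - agg$n_neg
    agg[order(agg$strain_i, agg$strain_j), , drop = FALSE]
  } else {
    data.frame(strain_i = character(), strain_j = character(),
               n_pos = integer(), n_neg = integer(), w = integer())
  }
  list(subnetwork = environment_subnetwork(environment, strains, edges),
       truth = truth)
}

#' Generate assembly annotations under a logistic label model
#'
#' Poisson background copy counts over `n_features` Pfam-like features;
#' binary labels drawn from a logistic model on the planted features,
#' `logit P(y=1) = sum_f beta_f * (x_f - (lambda + 0.5))`. The half-integer
#' offset centres the decision boundary between attainable copy numbers
#' (threshold-like copy-number phenotypes). Genus is assigned from the
#' configured mixture.
#'
#' @param n_assemblies Number of assemblies.
#' @param n_features Total feature count (>= number of planted features).
#' @param planted_beta Named numeric vector: effect size per planted
#'   feature index (e.g. `c("1" = 4)` plants feature 1 with beta 4); empty
#'   for a null model.
#' @param lambda Poisson mean of copy counts (default 4).
#' @param genus_weights Named numeric mixture weights for genus assignment.
#' @param seed Integer seed.
#' @return List with `annotations` (an `assembly_annotations`), `labels`
#'   (named 0/1 vector by assembly) and `truth` (planted feature names,
#'   betas, linear predictor).
#' @export
gen_genomes <- function(n_assemblies = 200L, n_features = 51L,
                        planted_beta = c("1" = 4),
                        lambda = 4, genus_weights = NULL, seed = 1L) {
  planted_idx <- as.integer(names(planted_beta))
  stopifnot(n_features >= length(planted_idx),
            all(is.finite(planted_beta)))
  if (is.null(genus_weights)) {
    genus_weights <- setNames(c(0.2, 0.2, 0.15, 0.15, 0.1, 0.1, 0.05, 0.05),
                              synth_vocab()$genera)
  }
  if (any(genus_weights < 0) || sum(genus_weights) <= 0) {
    stop("degenerate genus mixture")
  }
  rng <- local_rng(seed)
  feats <- sprintf("PF%05d", seq_len(n_features))
  X <- matrix(rng$rpois(n_assemblies * n_features, lambda),
              n_assemblies, n_features, dimnames = list(NULL, feats))
  eta <- rep(0, n_assemblies)
  for (k in seq_along(planted_idx)) {
    eta <- eta + planted_beta[k] * (X[, planted_idx[k]] - (lambda + 0.5))
  }
  labels <- rng$rbinom(n_assemblies, 1L, plogis(eta))
  assembly_ids <- sprintf("GCF_SYN%06d.1", seq_len(n_assemblies))
  genus <- names(genus_weights)[
    rng$draw(length(genus_weights), n_assemblies, replace = TRUE,
             prob = genus_weights / sum(genus_weights))]
  meta <- data.frame(assembly_id = assembly_ids,
                     canonical_id = sprintf("syn_t%05d",
                                            seq_len(n_assemblies)),
                     genus = genus)
  nz <- which(X > 0, arr.ind = TRUE)
  counts <- data.frame(assembly_id = assembly_ids[nz[, 1]],
                       feature = feats[nz[, 2]],
                       count = X[nz])
  counts <- counts[order(counts$assembly_id, counts$feature), , drop = FALSE]
  list(annotations = assembly_annotations(meta, counts),
       labels = setNames(labels, assembly_ids),
       truth = list(planted = feats[planted_idx], beta = planted_beta,
                    eta = eta, lambda = lambda, X = X))
}

#' Write assembly annotations as InterProScan-dialect TSV tables
#'
#' One headerless 13-column TSV per assembly, one row per annotated protein
#' copy (analysis `Pfam`), plus a few non-Pfam rows to exercise the reader's
#' analysis filter.
#'
#' @param annotations An `assembly_annotations`.
#' @param dir Output directory.
#' @param organisms Optional named character vector (by assembly id) of
#'   organism names; defaults to `genus sp.`.
#' @return Invisibly, a manifest `data.frame` suitable for
#'   [read_annotations()].
#' @export
write_interproscan <- function(annotations, dir, organisms = NULL) {
  stopifnot(inherits(annotations, "assembly_annotations"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- annotations$meta
  paths <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    aid <- meta$assembly_id[i]
    cc <- annotations$counts[annotations$counts$assembly_id == aid, ,
                             drop = FALSE]
    rows <- character()
    prot <- 0L
    for (j in seq_len(nrow(cc))) {
      for (k in seq_len(cc$count[j])) {
        prot <- prot + 1L
        rows <- c(rows, paste(
          sprintf("%s_p%05d", aid, prot), "md5", "300", "Pfam",
          cc$feature[j], "synthetic family", "1", "250", "1e-10", "T",
          "2026-01-01", "-", "-", sep = "\t"))
      }
    }
    # non-Pfam decoy rows, ignored by the reader
    rows <- c(rows, paste(sprintf("%s_p%05d", aid, prot + 1L), "md5",
                          "200", "PANTHER", "PTHR00001", "decoy", "1",
                          "180", "1e-5", "T", "2026-01-01", "-", "-",
                          sep = "\t"))
    paths[i] <- file.path(dir, paste0(aid, ".tsv"))
    writeLines(rows, paths[i])
  }
  org <- if (is.null(organisms)) paste(meta$genus, "sp.") else
    organisms[meta$assembly_id]
  invisible(data.frame(assembly_id = meta$assembly_id,
                       canonical_id = meta$canonical_id,
                       organism = org, path = paths))
}

# apply k random single-character edits (substitute/insert/delete)
random_edits <- function(term, k, rng) {
  alphabet <- c(letters, as.character(0:9))
  for (e in seq_len(k)) {
    op <- rng$draw_int(3L)
    n <- nchar(term)
    pos <- rng$draw_int(n)
    ch <- alphabet[rng$draw_int(length(alphabet))]
    term <- switch(op,
      paste0(substr(term, 1, pos - 1), ch, substr(term, pos + 1, n)),
      paste0(substr(term, 1, pos), ch, substr(term, pos + 1, n)),
      if (n > 1) paste0(substr(term, 1, pos - 1),
                        substr(term, pos + 1, n)) else term)
  }
  term
}

#' Generate a strain catalog with corrupted and abbreviated variants
#'
#' Canonical strain names with alias entries, plus corrupted query terms
#' produced by at most `k` random single-character edit operations and
#' genus-abbreviation variants (`"Escherichia"` to `"E."`), with the true
#' canonical identity retained as ground truth.
#'
#' @param n_entries Number of catalog entries.
#' @param k Edit budget per corrupted variant (>= 0).
#' @param seed Integer seed.
#' @return List with `catalog` (`canonical_id`, `alias`), `variants`
#'   (`term`, `canonical_id`, `kind` among `edit`/`abbrev`) and `truth`
#'   (the canonical names).
#' @export
gen_catalog <- function(n_entries = 50L, k = 1L, seed = 1L) {
  stopifnot(k >= 0, n_entries >= 1)
  rng <- local_rng(seed)
  vocab <- synth_vocab()
  names_ <- character(n_entries)
  for (i in seq_len(n_entries)) {
    repeat {
      nm <- synth_strain_name(rng, vocab)
      if (!nm %in% names_) break
    }
    names_[i] <- nm
  }
  ids <- sprintf("t__%04d", seq_len(n_entries))
  catalog <- data.frame(canonical_id = ids, alias = names_)
  variants <- list()
  for (i in seq_len(n_entries)) {
    corrupted <- random_edits(names_[i], k, rng)
    variants[[length(variants) + 1L]] <- data.frame(
      term = corrupted, canonical_id = ids[i], kind = "edit")
    abbrev <- sub("^(\\w)\\w*", "\\1.", names_[i])
    variants[[length(variants) + 1L]] <- data.frame(
      term = abbrev, canonical_id = ids[i], kind = "abbrev")
  }
  list(catalog = catalog, variants = do.call(rbind, variants),
       truth = list(names = names_, ids = ids))
}
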