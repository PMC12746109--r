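# Gene-phenotype association: Pfam copy-count feature matrices from
# InterProScan-style annotation tables, phenotype cluster definition and
# filtering, gradient-boosted classification with gain ranking, and pooled
# GO enrichment.

# InterProScan TSV columns (no header). Only `analysis == "Pfam"` rows are
# counted; one row is one annotated protein hit.
ipr_columns <- function() {
  c("protein_accession", "md5", "length", "analysis",
    "signature_accession", "signature_description", "start", "stop",
    "score", "status", "date", "interpro_accession", "interpro_description")
}

#' Read per-assembly functional annotation tables
#'
#' Parses InterProScan-dialect TSV tables (13 headerless columns; protein
#' accession, analysis, signature accession, ...) for a set of assemblies
#' and counts Pfam signature copies per assembly. Rows from analyses other
#' than `Pfam` are ignored; malformed rows (too few columns) are skipped
#' with a warning. The genus of each assembly is the first whitespace token
#' of its organism name, unless overridden.
#'
#' @param manifest `data.frame` with one row per assembly: `assembly_id`,
#'   `canonical_id` (strain identity), `organism` (species name) and `path`
#'   to the annotation TSV.
#' @param genus_overrides Optional `data.frame` with `assembly_id`, `genus`.
#' @return An `assembly_annotations` list with `meta` (`assembly_id`,
#'   `canonical_id`, `genus`) and `counts` (long `data.frame`:
#'   `assembly_id`, `feature`, `count`).
#' @export
read_annotations <- function(manifest, genus_overrides = NULL) {
  manifest <- as.data.frame(manifest)
  stopifnot(all(c("assembly_id", "canonical_id", "organism", "path")
                %in% names(manifest)), nrow(manifest) >= 1L)
  counts <- list()
  for (i in seq_len(nrow(manifest))) {
    lines <- readLines(manifest$path[i])
    if (!length(lines)) stop("empty annotation table: ", manifest$path[i])
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(parts) >= 5L
    if (any(!ok)) warning(sum(!ok), " malformed row(s) skipped in ",
                          manifest$path[i])
    parts <- parts[ok]
    analysis <- vapply(parts, `[`, character(1), 4L)
    sig <- vapply(parts, `[`, character(1), 5L)
    sig <- sig[analysis == "Pfam"]
    if (length(sig)) {
      tb <- table(sig)
      counts[[i]] <- data.frame(assembly_id = manifest$assembly_id[i],
                                feature = names(tb),
                                count = as.integer(tb))
    }
  }
  genus <- vapply(strsplit(manifest$organism, "[[:space:]]+"),
                  `[`, character(1), 1L)
  if (!is.null(genus_overrides)) {
    hit <- match(manifest$assembly_id, genus_overrides$assembly_id)
    genus[!is.na(hit)] <- genus_overrides$genus[hit[!is.na(hit)]]
  }
  structure(list(meta = data.frame(assembly_id = manifest$assembly_id,
                                   canonical_id = manifest$canonical_id,
                                   genus = genus),
                 counts = do.call(rbind, counts)),
            class = "assembly_annotations")
}

#' Construct assembly annotations from in-memory counts
#'
#' @param meta `data.frame` with `assembly_id`, `canonical_id`, `genus`.
#' @param counts Long `data.frame` with `assembly_id`, `feature`, `count`.
#' @return An `assembly_annotations` object.
#' @export
assembly_annotations <- function(meta, counts) {
  stopifnot(all(c("assembly_id", "canonical_id", "genus") %in% names(meta)),
            all(c("assembly_id", "feature", "count") %in% names(counts)),
            all(counts$count >= 0))
  structure(list(meta = as.data.frame(meta),
                 counts = as.data.frame(counts)),
            class = "assembly_annotations")
}

#' Dense Pfam copy-count feature matrix
#'
#' @param annotations An `assembly_annotations` object.
#' @param assemblies Optional assembly ids (rows); defaults to all.
#' @return Integer matrix, assemblies x features, zero-filled.
#' @export
feature_matrix <- function(annotations, assemblies = NULL) {
  stopifnot(inherits(annotations, "assembly_annotations"))
  if (is.null(assemblies)) assemblies <- annotations$meta$assembly_id
  cc <- annotations$counts
  feats <- sort(unique(cc$feature))
  M <- matrix(0L, length(assemblies), length(feats),
              dimnames = list(assemblies, feats))
  cc <- cc[cc$assembly_id %in% assemblies, , drop = FALSE]
  M[cbind(match(cc$assembly_id, assemblies), match(cc$feature, feats))] <-
    as.integer(cc$count)
  M
}

#' Define binarized phenotype clusters from relation records
#'
#' A phenotype cluster is one (relation type, entity term) pair: strains
#' sharing that relation to that term. Entity terms appearing fewer than
#' `min_term_count` times within their relation type are discarded. Each
#' cluster is binarized against the relation-type universe (all assemblies
#' whose strain appears in any record of that relation type): label 1 when
#' the assembly's strain has the term, 0 otherwise.
#'
#' @param records Normalized relation records (`data.frame` with
#'   `canonical_id` of the strain, `relation_type`, `term`).
#' @param annotations An `assembly_annotations` (links `canonical_id` to
#'   assemblies and genus).
#' @param min_term_count Minimum term occurrence (default 3).
#' @return List of `phenotype_cluster` objects, each with `relation_type`,
#'   `term`, `assemblies` (universe), `labels` (named 0/1 vector),
#'   `positives`.
#' @export
define_clusters <- function(records, annotations, min_term_count = 3L) {
  records <- as.data.frame(records)
  stopifnot(all(c("canonical_id", "relation_type", "term") %in%
                  names(records)),
            inherits(annotations, "assembly_annotations"))
  meta <- annotations$meta
  clusters <- list()
  for (rt in sort(unique(records$relation_type))) {
    rr <- records[records$relation_type == rt, , drop = FALSE]
    universe_strains <- unique(rr$canonical_id)
    universe <- meta$assembly_id[meta$canonical_id %in% universe_strains]
    if (!length(universe)) next
    tab <- table(rr$term)
    for (term in sort(names(tab)[tab >= min_term_count])) {
      pos_strains <- unique(rr$canonical_id[rr$term == term])
      labels <- setNames(
        as.integer(meta$canonical_id[match(universe, meta$assembly_id)]
                   %in% pos_strains), universe)
      clusters[[length(clusters) + 1L]] <- structure(
        list(relation_type = rt, term = term, assemblies = universe,
             labels = labels, positives = universe[labels == 1L]),
        class = "phenotype_cluster")
    }
  }
  clusters
}

#' @export
print.phenotype_cluster <- function(x, ...) {
  cat(sprintf("<phenotype_cluster %s:%s> %d/%d positive assemblies\n",
              x$relation_type, x$term, length(x$positives),
              length(x$assemblies)))
  invisible(x)
}

#' Filter phenotype clusters for modelability
#'
#' Keeps clusters whose positives cover at least `min_assemblies` assemblies
#' from at least `min_genera` distinct genera, with the most abundant genus
#' strictly below `max_genus_share` of the positive strains.
#'
#' @param clusters List of `phenotype_cluster` objects.
#' @param annotations An `assembly_annotations` (genus lookup).
#' @param min_assemblies Minimum positive assemblies (default 10,
#'   inclusive).
#' @param min_genera Minimum distinct genera among positives (default 5,
#'   inclusive).
#' @param max_genus_share Maximum share of the most abundant genus (default
#'   0.30, strict).
#' @return Filtered list of clusters.
#' @export
filter_clusters <- function(clusters, annotations, min_assemblies = 10L,
                            min_genera = 5L, max_genus_share = 0.30) {
  stopifnot(inherits(annotations, "assembly_annotations"))
  meta <- annotations$meta
  keep <- vapply(clusters, function(cl) {
    pos <- cl$positives
    if (length(pos) < min_assemblies) return(FALSE)
    genera <- meta$genus[match(pos, meta$assembly_id)]
    if (length(unique(genera)) < min_genera) return(FALSE)
    max(table(genera)) / length(pos) < max_genus_share
  }, logical(1))
  clusters[keep]
}

# stratified index split preserving class balance
stratified_indices <- function(y, frac, rng) {
  pick <- integer()
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[rng$sample_idx(length(idx))]
    k <- round(frac * length(idx))
    pick <- c(pick, idx[seq_len(k)])
  }
  sort(pick)
}

#' Train a gradient-boosted model for one phenotype cluster and rank features
#'
#' Stratified 80/20 train/test split; an inner stratified 10% validation
#' slice is carved from the training portion for early stopping (the test
#' set is never used during training). Hold-out accuracy is computed at a
#' 0.5 probability threshold, the model is retained when accuracy is
#' strictly above `accuracy_gate`, and features are ranked by total gain.
#'
#' @param cluster A `phenotype_cluster`.
#' @param annotations An `assembly_annotations` providing the features.
#' @param config A [model_config()].
#' @param split Train/test fractions (default `c(0.8, 0.2)`).
#' @param accuracy_gate Retention threshold on hold-out accuracy (strict
#'   `>`, default 0.8).
#' @param seed Integer seed for the splits.
#' @return A `model_summary` list: `cluster_id`, `accuracy`, `retained`,
#'   `importance` (gain-ranked `data.frame`), `model`, `n_train`, `n_test`.
#' @export
train_and_rank <- function(cluster, annotations, config = model_config(),
                           split = c(0.8, 0.2), accuracy_gate = 0.8,
                           seed = config$seed) {
  stopifnot(inherits(cluster, "phenotype_cluster"),
            abs(sum(split) - 1) < 1e-9)
  y <- cluster$labels
  if (length(y) < 10L) stop("need at least 10 labeled assemblies")
  if (length(unique(y)) < 2L) stop("single-class cluster")
  X <- feature_matrix(annotations, names(y))
  rng <- local_rng(seed)
  train_idx <- stratified_indices(y, split[1], rng)
  test_idx <- setdiff(seq_along(y), train_idx)
  # inner validation slice for early stopping: 10% of training
  val_of_train <- stratified_indices(y[train_idx], 0.1, rng)
  val_idx <- train_idx[val_of_train]
  fit_idx <- setdiff(train_idx, val_idx)
  if (length(unique(y[fit_idx])) < 2L || !length(val_idx)) {
    fit_idx <- train_idx
    val_idx <- train_idx
  }
  model <- gboost(X[fit_idx, , drop = FALSE], y[fit_idx], config,
                  X_val = X[val_idx, , drop = FALSE], y_val = y[val_idx])
  pred <- predict(model, X[test_idx, , drop = FALSE])
  accuracy <- mean(as.integer(pred >= 0.5) == y[test_idx])
  structure(list(cluster_id = paste0(cluster$relation_type, ":",
                                     cluster$term),
                 accuracy = accuracy,
                 retained = accuracy > accuracy_gate,
                 importance = model$importance,
                 model = model,
                 n_train = length(train_idx), n_test = length(test_idx)),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("<model_summary %s> accuracy=%.3f retained=%s top=%s\n",
              x$cluster_id, x$accuracy, x$retained,
              x$importance$feature[1]))
  invisible(x)
}

#' Pooled GO-term enrichment for one relation type
#'
#' Pools the annotated gene copies of all foreground assemblies (all strains
#' involved in any instance of the relation) and tests each GO term for
#' enrichment against the background assemblies' gene pool with Fisher's
#' exact test (two-sided), correcting p-values by Benjamini-Hochberg FDR.
#' Pfam copies are mapped to GO terms through the supplied `pfam2go` table;
#' copies of unmapped families count toward the totals only.
#'
#' @param annotations An `assembly_annotations`.
#' @param foreground_assemblies Assembly ids involved in the relation.
#' @param pfam2go `data.frame` with columns `pfam`, `go`.
#' @param background_assemblies Background pool (default: all assemblies).
#' @return `data.frame` with `go`, the 2x2 counts (`fg_in`, `fg_out`,
#'   `bg_in`, `bg_out`), `p` and BH-adjusted `q`, sorted by `p`.
#' @export
go_enrichment <- function(annotations, foreground_assemblies, pfam2go,
                          background_assemblies = NULL) {
  stopifnot(inherits(annotations, "assembly_annotations"))
  pfam2go <- as.data.frame(pfam2go)
  if (!nrow(pfam2go)) stop("empty Pfam-to-GO mapping")
  stopifnot(all(c("pfam", "go") %in% names(pfam2go)))
  if (is.null(background_assemblies)) {
    background_assemblies <- annotations$meta$assembly_id
  }
  cc <- annotations$counts
  fg <- cc[cc$assembly_id %in% foreground_assemblies, , drop = FALSE]
  bg <- cc[cc$assembly_id %in% background_assemblies, , drop = FALSE]
  fg_total <- sum(fg$count)
  bg_total <- sum(bg$count)
  if (fg_total == 0L || bg_total == 0L) stop("no annotated genes in pool")
  gos <- sort(unique(pfam2go$go))
  rows <- lapply(gos, function(go) {
    fams <- pfam2go$pfam[pfam2go$go == go]
    fg_in <- sum(fg$count[fg$feature %in% fams])
    bg_in <- sum(bg$count[bg$feature %in% fams])
    tab <- matrix(c(fg_in, fg_total - fg_in, bg_in, bg_total - bg_in), 2L)
    data.frame(go = go, fg_in = fg_in, fg_out = fg_total - fg_in,
               bg_in = bg_in, bg_out = bg_total - bg_in,
               p = fisher.test(tab)$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$go), , drop = FALSE]
}
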