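# Strain-term normalization against a reference catalog via two-stage
# Levenshtein matching (local/partial first, then full-distance), and
# single-linkage clustering of non-strain term variants.

#' Read a strain reference catalog
#'
#' @param path TSV file with columns `canonical_id` and `alias` (one alias
#'   per row; a canonical id may have many aliases).
#' @return `data.frame` with `canonical_id`, `alias`.
#' @export
read_strain_catalog <- function(path) {
  cat_ <- read.delim(path, colClasses = "character")
  stopifnot(all(c("canonical_id", "alias") %in% names(cat_)))
  cat_[nzchar(cat_$alias), c("canonical_id", "alias")]
}

# Text normalization applied before any distance computation: case-fold,
# collapse whitespace, and apply the corpus hyphen rule.
normalize_term <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(dehyphenate(x))))
}

# Expand single-letter abbreviated tokens of `term` (e.g. "e.") against the
# alias token sharing the initial ("escherichia"), to let abbreviated strain
# names reach their full-name alias at the local stage.
expand_abbreviations <- function(term, alias) {
  tt <- strsplit(term, " ", fixed = TRUE)[[1]]
  at <- strsplit(alias, " ", fixed = TRUE)[[1]]
  for (i in seq_along(tt)) {
    if (grepl("^[a-z]\\.$", tt[i])) {
      hit <- at[substr(at, 1L, 1L) == substr(tt[i], 1L, 1L) & nchar(at) > 2L]
      if (length(hit)) tt[i] <- hit[1L]
    }
  }
  paste(tt, collapse = " ")
}

# Local (partial) similarity: best approximate-substring match of the
# shorter string within the longer, after abbreviation expansion.
# Returns 1 - d_partial / nchar(shorter).
local_similarity <- function(term, alias) {
  term2 <- expand_abbreviations(term, alias)
  shorter <- if (nchar(term2) <= nchar(alias)) term2 else alias
  longer <- if (nchar(term2) <= nchar(alias)) alias else term2
  if (!nchar(shorter)) return(0)
  d <- adist(shorter, longer, partial = TRUE)[1, 1]
  1 - d / nchar(shorter)
}

# Full normalized Levenshtein distance in [0, 1].
full_distance <- function(a, b) {
  if (!nchar(a) && !nchar(b)) return(0)
  adist(a, b)[1, 1] / max(nchar(a), nchar(b))
}

#' Normalize strain terms against a reference catalog
#'
#' Two-stage matching per term, after text normalization (case-folding,
#' whitespace collapsing, hyphen rule) and optional curated rewrites:
#'
#' 1. *Local stage* — best partial (approximate-substring) Levenshtein match
#'    against every alias, with single-letter genus abbreviations (`"e."`)
#'    expanded against the alias first; accepted when the local similarity is
#'    at least `tau_local`.
#' 2. *Full stage* — best full normalized Levenshtein distance; accepted when
#'    at most `tau_full`.
#'
#' Ties are broken by smaller distance, then lexicographic canonical id.
#' Unmatched terms are returned with stage `"none"`.
#'
#' @param terms Character vector of strain terms to resolve.
#' @param catalog `data.frame` with `canonical_id`, `alias` columns (see
#'   [read_strain_catalog()]).
#' @param tau_local Minimum local-stage similarity (default `0.90`).
#' @param tau_full Maximum full-stage normalized distance (default `0.10`).
#' @param overrides Optional `data.frame` of curated rewrites with columns
#'   `variant`, `canonical_term`, applied to terms before matching.
#' @return `data.frame` with one row per input term: `term`, `canonical_id`
#'   (`NA` when unmapped), `distance` (normalized; `1 - similarity` for the
#'   local stage) and `stage` (`"local"`, `"full"` or `"none"`).
#' @export
normalize_strains <- function(terms, catalog, tau_local = 0.90,
                              tau_full = 0.10, overrides = NULL) {
  catalog <- as.data.frame(catalog)
  if (!nrow(catalog)) stop("empty catalog")
  stopifnot(all(c("canonical_id", "alias") %in% names(catalog)))
  aliases_norm <- normalize_term(catalog$alias)
  res <- data.frame(term = as.character(terms),
                    canonical_id = NA_character_,
                    distance = NA_real_, stage = "none",
                    stringsAsFactors = FALSE)
  for (k in seq_along(terms)) {
    term <- as.character(terms[k])
    if (!nzchar(term)) next
    if (!is.null(overrides)) {
      hit <- match(term, overrides$variant)
      if (!is.na(hit)) term <- overrides$canonical_term[hit]
    }
    tn <- normalize_term(term)
    # stage 1: local
    sims <- vapply(aliases_norm, function(a) local_similarity(tn, a),
                   numeric(1), USE.NAMES = FALSE)
    best <- order(-sims, catalog$canonical_id)[1L]
    if (sims[best] >= tau_local) {
      res$canonical_id[k] <- catalog$canonical_id[best]
      res$distance[k] <- 1 - sims[best]
      res$stage[k] <- "local"
      next
    }
    # stage 2: full
    dists <- vapply(aliases_norm, function(a) full_distance(tn, a),
                    numeric(1), USE.NAMES = FALSE)
    best <- order(dists, catalog$canonical_id)[1L]
    if (dists[best] <= tau_full) {
      res$canonical_id[k] <- catalog$canonical_id[best]
      res$distance[k] <- dists[best]
      res$stage[k] <- "full"
    }
  }
  res
}

#' Cluster term variants and pick representatives
#'
#' Groups variations of the same entity term (plural forms, typos) by
#' single-linkage under normalized Levenshtein distance, after case-folding
#' and plural-`s` stripping. The representative of each cluster is the member
#' with the largest occurrence count (ties broken lexicographically).
#'
#' @param terms Character vector of distinct terms.
#' @param counts Occurrence counts (>= 1), same length as `terms`.
#' @param tau_cluster Maximum normalized distance joining two terms
#'   (default `0.20`).
#' @return `data.frame` with `term`, `count`, `cluster` (integer id) and
#'   `representative`.
#' @export
cluster_terms <- function(terms, counts, tau_cluster = 0.20) {
  stopifnot(length(terms) == length(counts), all(counts >= 1))
  n <- length(terms)
  if (!n) {
    return(data.frame(term = character(), count = integer(),
                      cluster = integer(), representative = character()))
  }
  # canonical ordering makes clustering permutation-invariant
  ord <- order(terms)
  terms_o <- terms[ord]; counts_o <- counts[ord]
  key <- sub("s$", "", normalize_term(terms_o))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    d <- adist(key)
    den <- outer(nchar(key), nchar(key), pmax)
    den[den == 0] <- 1L
    nd <- d / den
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (nd[i, j] <= tau_cluster) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  cluster <- match(root, sort(unique(root)))
  rep_ <- vapply(seq_len(max(cluster)), function(cl) {
    m <- which(cluster == cl)
    m <- m[order(-counts_o[m], terms_o[m])]
    terms_o[m[1L]]
  }, character(1))
  out <- data.frame(term = terms_o, count = counts_o, cluster = cluster,
                    representative = rep_[cluster])
  out[match(terms, out$term), , drop = FALSE]
}
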