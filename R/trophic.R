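# Triad-based inference of strain-strain trophic interactions inside
# environment-restricted subnetworks: competition and direct inhibition
# (negative), cross-feeding and resistance development (positive), weighted
# per strain pair as w = n_pos - n_neg.

#' Extract the subnetwork of strains inhabiting one environment
#'
#' Members are all STRAIN nodes with an `INHABITS` edge towards the
#' environment term; the returned edge set is the induced `PRODUCES`,
#' `DEGRADES`, `RESISTS` and `INHIBITS` edges between members and their
#' compounds (strain-to-compound, plus the `INHIBITS` compound-to-strain
#' direction).
#'
#' @param graph A `phenotype_graph` from [build_graph()].
#' @param environment_term The environment/host term (node term, any
#'   category) strains inhabit.
#' @return An `environment_subnetwork` list with `environment`, `strains`
#'   (character vector of member strain terms) and `edges`
#'   (`data.frame` `source`, `target`, `type` on terms).
#' @export
extract_environment_subnetwork <- function(graph, environment_term) {
  stopifnot(inherits(graph, "phenotype_graph"))
  g <- graph$graph
  names_ <- igraph::V(g)$name
  terms <- igraph::V(g)$term
  env_idx <- which(terms == environment_term)
  if (!length(env_idx)) stop("unknown environment term: ", environment_term)
  e <- graph$edges
  src_term <- sub("^[^|]*\\|", "", e$source)
  src_cat <- sub("\\|.*$", "", e$source)
  tgt_term <- sub("^[^|]*\\|", "", e$target)
  tgt_cat <- sub("\\|.*$", "", e$target)
  members <- sort(unique(src_term[
    e$relation_type == "INHABITS" & src_cat == "STRAIN" &
      tgt_term == environment_term]))
  keep_types <- c("PRODUCES", "DEGRADES", "RESISTS", "INHIBITS")
  keep <- e$relation_type %in% keep_types &
    ((src_cat == "STRAIN" & src_term %in% members &
        tgt_cat == "COMPOUND") |
       (src_cat == "COMPOUND" & e$relation_type == "INHIBITS" &
          tgt_cat == "STRAIN" & tgt_term %in% members))
  structure(list(environment = environment_term, strains = members,
                 edges = data.frame(source = src_term[keep],
                                    target = tgt_term[keep],
                                    type = e$relation_type[keep],
                                    support = e$support[keep])),
            class = "environment_subnetwork")
}

#' Construct an environment subnetwork directly from edges
#'
#' Convenience constructor used by the generators and for testing: wraps a
#' member list and typed edge set without requiring a full phenotype graph.
#'
#' @param environment Environment term label.
#' @param strains Character vector of member strains.
#' @param edges `data.frame` with `source`, `target`, `type` (terms; types
#'   among `PRODUCES`, `DEGRADES`, `RESISTS`, `INHIBITS`).
#' @return An `environment_subnetwork`.
#' @export
environment_subnetwork <- function(environment, strains, edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    stopifnot(all(c("source", "target", "type") %in% names(edges)),
              all(edges$type %in%
                    c("PRODUCES", "DEGRADES", "RESISTS", "INHIBITS")))
  }
  structure(list(environment = environment,
                 strains = sort(unique(as.character(strains))),
                 edges = edges),
            class = "environment_subnetwork")
}

#' @export
print.environment_subnetwork <- function(x, ...) {
  cat(sprintf("<environment_subnetwork %s> %d strains, %d edges\n",
              x$environment, length(x$strains), nrow(x$edges)))
  invisible(x)
}

#' Enumerate trophic triads in an environment subnetwork
#'
#' Finds every triad (two member strains contiguously connected through a
#' mediating compound) of the four motif types:
#'
#' * `competition` (sign `-`, symmetric): both strains `DEGRADES` the same
#'   compound — resource competition.
#' * `direct_inhibition` (sign `-`, directed i -> j): strain i `PRODUCES` a
#'   compound that `INHIBITS` strain j.
#' * `cross_feeding` (sign `+`, directed i -> j): strain j `DEGRADES` a
#'   compound `PRODUCES`-ed by strain i.
#' * `resistance` (sign `+`, symmetric roles producer/resister): strain j
#'   `RESISTS` a compound `PRODUCES`-ed by strain i.
#'
#' Each distinct (strain pair, compound, type) combination is counted once,
#' regardless of how many sentences support the underlying edges; the two
#' strains are always distinct.
#'
#' @param sub An `environment_subnetwork`.
#' @return `data.frame` with columns `type`, `strain_i`, `strain_j`,
#'   `compound`, `sign` (+1/-1). For symmetric types `strain_i < strain_j`;
#'   for directed types `strain_i` is the producer.
#' @export
enumerate_triads <- function(sub) {
  stopifnot(inherits(sub, "environment_subnetwork"))
  e <- unique(sub$edges[, c("source", "target", "type")])
  strains <- sub$strains
  out <- list()
  add <- function(type, i, j, comp, sign) {
    out[[length(out) + 1L]] <<- data.frame(
      type = type, strain_i = i, strain_j = j, compound = comp, sign = sign)
  }
  compounds <- unique(c(e$target[e$type %in%
                                   c("PRODUCES", "DEGRADES", "RESISTS")],
                        e$source[e$type == "INHIBITS"]))
  for (comp in compounds) {
    producers <- sort(unique(e$source[
      e$type == "PRODUCES" & e$target == comp & e$source %in% strains]))
    degraders <- sort(unique(e$source[
      e$type == "DEGRADES" & e$target == comp & e$source %in% strains]))
    resisters <- sort(unique(e$source[
      e$type == "RESISTS" & e$target == comp & e$source %in% strains]))
    inhibited <- sort(unique(e$target[
      e$type == "INHIBITS" & e$source == comp & e$target %in% strains]))
    # competition: unordered degrader pairs
    if (length(degraders) >= 2L) {
      for (a in seq_len(length(degraders) - 1L))
        for (b in (a + 1L):length(degraders))
          add("competition", degraders[a], degraders[b], comp, -1L)
    }
    for (i in producers) {
      for (j in inhibited) if (i != j)
        add("direct_inhibition", i, j, comp, -1L)
      for (j in degraders) if (i != j)
        add("cross_feeding", i, j, comp, +1L)
      for (j in resisters) if (i != j)
        add("resistance", i, j, comp, +1L)
    }
  }
  if (!length(out)) {
    return(data.frame(type = character(), strain_i = character(),
                      strain_j = character(), compound = character(),
                      sign = integer()))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res[order(res$type, res$strain_i, res$strain_j, res$compound), ,
      drop = FALSE]
}

#' Net interaction weights per strain pair
#'
#' Aggregates triads over unordered strain pairs: `n_pos` and `n_neg` count
#' positive and negative triads over both directions and all mediating
#' compounds, and the interaction weight is `w = n_pos - n_neg` (positive:
#' net positive interaction). Pairs with no triads are omitted. Per-direction
#' counts are retained in the attribute `"by_direction"`.
#'
#' @param triads Triad table from [enumerate_triads()].
#' @return `data.frame` with `strain_i`, `strain_j` (`strain_i < strain_j`),
#'   `n_pos`, `n_neg`, `w`.
#' @export
interaction_weights <- function(triads) {
  triads <- as.data.frame(triads)
  if (!nrow(triads)) {
    return(data.frame(strain_i = character(), strain_j = character(),
                      n_pos = integer(), n_neg = integer(), w = integer()))
  }
  a <- pmin(triads$strain_i, triads$strain_j)
  b <- pmax(triads$strain_i, triads$strain_j)
  key <- paste(a, b, sep = "\r")
  pos <- tapply(triads$sign > 0, key, sum)
  neg <- tapply(triads$sign < 0, key, sum)
  ks <- sort(unique(key))
  parts <- strsplit(ks, "\r", fixed = TRUE)
  out <- data.frame(
    strain_i = vapply(parts, `[`, character(1), 1L),
    strain_j = vapply(parts, `[`, character(1), 2L),
    n_pos = as.integer(pos[ks]), n_neg = as.integer(neg[ks]))
  out$w <- out$n_pos - out$n_neg
  dir_ <- aggregate(list(n = rep(1L, nrow(triads))),
                    by = list(strain_i = triads$strain_i,
                              strain_j = triads$strain_j,
                              type = triads$type),
                    FUN = sum)
  attr(out, "by_direction") <- dir_
  rownames(out) <- NULL
  out
}

#' Export an interaction network
#'
#' @param weights Interaction table from [interaction_weights()].
#' @param tsv_path TSV output path (`NULL` to skip).
#' @param graphml_path GraphML output path with signed `w` edge weights
#'   (`NULL` to skip).
#' @return Invisibly, `weights`.
#' @export
write_interactions <- function(weights, tsv_path = NULL,
                               graphml_path = NULL) {
  if (!is.null(tsv_path)) {
    write.table(weights, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(graphml_path) && nrow(weights)) {
    g <- igraph::graph_from_data_frame(
      weights[, c("strain_i", "strain_j", "w")], directed = FALSE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(weights)
}
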