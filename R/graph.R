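# The typed directed phenotype network: construction from relation records
# and structural summaries (components, centrality, Jaccard similarity,
# Leiden communities).

#' Build the phenotype network from relation records
#'
#' One node per unique (term, category); one directed typed edge per
#' (source, target, relation type) with a support count of distinct
#' supporting records. Records scoring below the threshold, self-loop
#' records and records with unknown relation types are excluded (the latter
#' with a warning). Exact duplicate records (same sentence and triple) are
#' collapsed before counting, so support counts distinct supporting
#' sentences per triple.
#'
#' @param records `data.frame` of relation records with columns
#'   `sentence_id`, `source_term`, `source_category`, `target_term`,
#'   `target_category`, `relation_type`, `score`.
#' @param threshold Minimum score retained (inclusive); default `0.5`.
#' @return A `phenotype_graph`: list with the underlying `igraph` object
#'   (`graph`), the collapsed `edges` data.frame, and `n_records` retained.
#' @export
build_graph <- function(records, threshold = 0.5) {
  records <- as.data.frame(records)
  need <- c("sentence_id", "source_term", "source_category", "target_term",
            "target_category", "relation_type", "score")
  if (nrow(records)) stopifnot(all(need %in% names(records)))
  if (!nrow(records)) {
    g <- igraph::make_empty_graph(directed = TRUE)
    return(structure(list(graph = g,
                          edges = data.frame(), n_records = 0L),
                     class = "phenotype_graph"))
  }
  bad <- !records$relation_type %in% relation_types()
  if (any(bad)) {
    warning(sum(bad), " record(s) with unknown relation type rejected: ",
            paste(unique(records$relation_type[bad]), collapse = ", "))
    records <- records[!bad, , drop = FALSE]
  }
  records <- records[records$score >= threshold, , drop = FALSE]
  src <- paste0(records$source_category, "|", records$source_term)
  tgt <- paste0(records$target_category, "|", records$target_term)
  loop <- src == tgt
  if (any(loop)) records <- records[!loop, , drop = FALSE]
  src <- src[!loop]; tgt <- tgt[!loop]
  key <- paste(records$sentence_id, src, tgt, records$relation_type,
               sep = "\r")
  dup <- duplicated(key)
  records <- records[!dup, , drop = FALSE]
  src <- src[!dup]; tgt <- tgt[!dup]
  agg <- aggregate(list(support = rep(1L, nrow(records))),
                   by = list(source = src, target = tgt,
                             relation_type = records$relation_type),
                   FUN = sum)
  agg <- agg[order(agg$source, agg$target, agg$relation_type), , drop = FALSE]
  nodes <- sort(unique(c(src, tgt)))
  g <- igraph::graph_from_data_frame(
    agg[, c("source", "target", "relation_type", "support")],
    directed = TRUE,
    vertices = data.frame(
      name = nodes,
      category = sub("\\|.*$", "", nodes),
      term = sub("^[^|]*\\|", "", nodes)))
  structure(list(graph = g, edges = agg, n_records = nrow(records)),
            class = "phenotype_graph")
}

as_igraph <- function(x) {
  if (inherits(x, "phenotype_graph")) x$graph else
    if (inherits(x, "igraph")) x else
      stop("not a graph")
}

#' @export
print.phenotype_graph <- function(x, ...) {
  cat(sprintf("<phenotype_graph> %d nodes, %d typed edges, %d records\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$n_records))
  invisible(x)
}

#' Largest weakly connected component fractions
#'
#' @param graph A `phenotype_graph` or `igraph` object (non-empty).
#' @return List with `node_fraction` and `edge_fraction` of the largest
#'   weakly connected component, and its absolute `nodes`/`edges` counts.
#' @export
component_stats <- function(graph) {
  g <- as_igraph(graph)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  comp <- igraph::components(g, mode = "weak")
  main <- which.max(comp$csize)
  keep <- which(comp$membership == main)
  sub <- igraph::induced_subgraph(g, keep)
  list(node_fraction = length(keep) / igraph::vcount(g),
       edge_fraction = if (igraph::ecount(g) > 0)
         igraph::ecount(sub) / igraph::ecount(g) else 1,
       nodes = length(keep), edges = igraph::ecount(sub))
}

#' Per-node degree and betweenness centrality table
#'
#' Degrees are counted over the typed (collapsed) edges; betweenness is exact
#' (Brandes) on the directed graph with unweighted edges, ignoring type
#' multiplicity (parallel typed edges between the same ordered pair count
#' once for shortest paths).
#'
#' @param graph A `phenotype_graph` or `igraph` object.
#' @return `data.frame` with `node`, `category`, `indegree`, `outdegree`,
#'   `betweenness`, sorted by decreasing betweenness.
#' @export
centrality_table <- function(graph) {
  g <- as_igraph(graph)
  simple <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  btw <- igraph::betweenness(simple, directed = TRUE, weights = NA)
  cat_ <- if ("category" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$category else NA_character_
  out <- data.frame(node = igraph::V(g)$name,
                    category = cat_,
                    indegree = as.integer(igraph::degree(g, mode = "in")),
                    outdegree = as.integer(igraph::degree(g, mode = "out")),
                    betweenness = as.numeric(btw))
  out[order(-out$betweenness, out$node), , drop = FALSE]
}

#' Top vertex pairs by Jaccard neighborhood similarity
#'
#' For every node pair sharing at least one neighbor, the Jaccard index of
#' their neighborhoods, where a node's neighborhood is the union of its in-
#' and out-neighbors excluding the two paired nodes themselves.
#'
#' @param graph A `phenotype_graph` or `igraph` object.
#' @param top_n Number of pairs returned (by decreasing index, ties broken
#'   lexicographically by node names). Default `10`.
#' @return `data.frame` with `node_a`, `node_b`, `jaccard`.
#' @export
jaccard_pairs <- function(graph, top_n = 10L) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  empty <- data.frame(node_a = character(), node_b = character(),
                      jaccard = numeric())
  if (n < 2L) return(empty)
  nbrs <- lapply(seq_len(n), function(v)
    setdiff(unique(c(
      igraph::neighbors(g, v, mode = "in"),
      igraph::neighbors(g, v, mode = "out"))), v))
  # candidate pairs: co-neighbors of some node
  cand <- new.env(parent = emptyenv())
  for (w in seq_len(n)) {
    adj <- nbrs[[w]]
    if (length(adj) < 2L) next
    adj <- sort(adj)
    for (i in seq_len(length(adj) - 1L)) for (j in (i + 1L):length(adj)) {
      assign(paste0(adj[i], "_", adj[j]), TRUE, envir = cand)
    }
  }
  keys <- ls(cand)
  if (!length(keys)) return(empty)
  names_ <- igraph::V(g)$name
  rows <- lapply(keys, function(k) {
    uv <- as.integer(strsplit(k, "_", fixed = TRUE)[[1]])
    u <- uv[1]; v <- uv[2]
    nu <- setdiff(nbrs[[u]], c(u, v))
    nv <- setdiff(nbrs[[v]], c(u, v))
    un <- length(union(nu, nv))
    if (un == 0L) return(NULL)
    jac <- length(intersect(nu, nv)) / un
    if (jac == 0) return(NULL)
    ab <- sort(c(names_[u], names_[v]))
    data.frame(node_a = ab[1], node_b = ab[2], jaccard = jac)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty)
  rows <- rows[order(-rows$jaccard, rows$node_a, rows$node_b), , drop = FALSE]
  head(rows, top_n)
}

#' Leiden community partition and modularity
#'
#' Runs the Leiden algorithm (modularity objective) on the undirected
#' projection of the graph, seeded for reproducibility.
#'
#' @param graph A `phenotype_graph` or `igraph` object with >= 2 nodes.
#' @param seed Integer seed.
#' @param n_iterations Leiden refinement iterations (default `10`).
#' @return List with `membership` (named integer vector) and `modularity`.
#' @export
community_modularity <- function(graph, seed = 1L, n_iterations = 10L) {
  g <- as_igraph(graph)
  if (igraph::vcount(g) < 2L) stop("need at least 2 nodes")
  und <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
  cl <- with_seed(seed, igraph::cluster_leiden(
    und, objective_function = "modularity", n_iterations = n_iterations))
  memb <- igraph::membership(cl)
  list(membership = memb,
       modularity = igraph::modularity(und, memb))
}

#' Seeded random edge subsample (export utility)
#'
#' @param graph A `phenotype_graph` or `igraph` object.
#' @param n_edges Number of edges kept.
#' @param seed Integer seed.
#' @return An `igraph` subgraph on the sampled edges.
#' @export
subsample_edges <- function(graph, n_edges, seed = 1L) {
  g <- as_igraph(graph)
  m <- igraph::ecount(g)
  keep <- local_rng(seed)$draw(m, min(n_edges, m))
  igraph::subgraph_from_edges(g, sort(keep), delete.vertices = TRUE)
}

#' Export a phenotype graph
#'
#' Writes the collapsed typed edge list as TSV (columns `source`,
#' `source_category`, `target`, `target_category`, `relation_type`,
#' `support`) and optionally GraphML.
#'
#' @param graph A `phenotype_graph`.
#' @param tsv_path Path for the TSV edge list (`NULL` to skip).
#' @param graphml_path Path for GraphML output (`NULL` to skip).
#' @return Invisibly, the exported edge `data.frame`.
#' @export
write_graph_files <- function(graph, tsv_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(graph, "phenotype_graph"))
  e <- graph$edges
  out <- data.frame(source = sub("^[^|]*\\|", "", e$source),
                    source_category = sub("\\|.*$", "", e$source),
                    target = sub("^[^|]*\\|", "", e$target),
                    target_category = sub("\\|.*$", "", e$target),
                    relation_type = e$relation_type,
                    support = e$support)
  if (!is.null(tsv_path)) {
    write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph$graph, graphml_path, format = "graphml")
  }
  invisible(out)
}
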