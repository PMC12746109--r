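# phenotype network construction and structural summaries

rec_row <- function(sid, s, t, type = "PRODUCES", score = 0.9,
                    scat = "STRAIN", tcat = "COMPOUND") {
  data.frame(sentence_id = sid, source_term = s, source_category = scat,
             target_term = t, target_category = tcat,
             relation_type = type, score = score)
}

test_that("build_graph collapses typed edges with support counts", {
  recs <- rbind(rec_row("s1", "a", "x"), rec_row("s2", "a", "x"),
                rec_row("s3", "a", "x", type = "DEGRADES"),
                rec_row("s4", "b", "x", score = 0.4))     # below threshold
  g <- build_graph(recs)
  expect_equal(igraph::vcount(g$graph), 2L)
  expect_equal(nrow(g$edges), 2L)
  e <- g$edges[g$edges$relation_type == "PRODUCES", ]
  expect_equal(e$support, 2L)
  expect_equal(g$n_records, 3L)
  expect_equal(sum(g$edges$support), g$n_records)
  # empty stream
  g0 <- build_graph(data.frame())
  expect_equal(igraph::vcount(g0$graph), 0L)
  # unknown relation type rejected with a warning
  bad <- rbind(recs, rec_row("s5", "a", "x", type = "EATS"))
  expect_warning(g2 <- build_graph(bad), "unknown relation type")
  expect_equal(g2$n_records, 3L)
})

test_that("graph construction is order-invariant and matches generator truth", {
  rr <- gen_relation_records(150, alpha = 2.3, seed = 42)
  g <- build_graph(rr$records)
  expect_equal(igraph::vcount(g$graph), rr$truth$n_nodes)
  expect_equal(sum(g$edges$support), rr$truth$n_edges)
  perm <- rr$records[sample(nrow(rr$records)), ]
  g2 <- build_graph(perm)
  expect_equal(g2$edges, g$edges)
  # strain out-degrees equal the planted degree sequence
  outdeg <- igraph::degree(g$graph, mode = "out")
  strain_deg <- sort(as.integer(
    outdeg[igraph::V(g$graph)$category == "STRAIN"]))
  expect_equal(strain_deg, sort(rr$truth$degrees))
})

test_that("component_stats reports largest weak-component fractions", {
  g <- build_graph(rbind(rec_row("s1", "a", "x"), rec_row("s2", "b", "x")))
  cs <- component_stats(g)
  expect_equal(cs$node_fraction, 1)
  expect_equal(cs$edge_fraction, 1)
  two <- rbind(rec_row("s1", "a", "x"), rec_row("s2", "b", "x"),
               rec_row("s3", "c", "y"), rec_row("s4", "d", "y"))
  # components: {a,b,x} (2 edges) and {c,d,y} (2 edges): equal, main = first
  cs2 <- component_stats(build_graph(two))
  expect_equal(cs2$node_fraction, 0.5)
  expect_equal(cs2$edge_fraction, 0.5)
  expect_error(component_stats(build_graph(data.frame())), "empty")
})

test_that("centrality_table matches a naive all-pairs betweenness oracle", {
  # directed path a -> b -> c
  path_ <- rbind(rec_row("s1", "a", "b", tcat = "STRAIN"),
                 rec_row("s2", "b", "c", tcat = "STRAIN"))
  ct <- centrality_table(build_graph(path_))
  expect_equal(ct$betweenness[ct$node == "STRAIN|b"], 1)
  expect_equal(sum(ct$betweenness), 1)
  # star hub: hub has maximal betweenness
  star <- rbind(rec_row("s1", "h", "a", tcat = "STRAIN"),
                rec_row("s2", "h", "b", tcat = "STRAIN"),
                rec_row("s3", "x", "h", scat = "COMPOUND", tcat = "STRAIN",
                        type = "INHIBITS"),
                rec_row("s4", "y", "h", scat = "COMPOUND", tcat = "STRAIN",
                        type = "INHIBITS"))
  ct2 <- centrality_table(build_graph(star))
  expect_equal(ct2$node[1], "STRAIN|h")
  # random 30-node digraph vs oracle
  set.seed(77)
  n <- 30
  adj <- matrix(rbinom(n * n, 1, 0.12), n, n)
  diag(adj) <- 0
  el <- which(adj > 0, arr.ind = TRUE)
  recs <- rec_row(paste0("s", seq_len(nrow(el))),
                  paste0("n", el[, 1]), paste0("n", el[, 2]),
                  tcat = "STRAIN")
  g <- build_graph(recs)
  ct3 <- centrality_table(g)
  ids <- as.integer(sub("STRAIN\\|n", "", ct3$node))
  expect_equal(ct3$betweenness[order(ids)][sort(unique(c(el)))],
               oracle_betweenness(adj)[sort(unique(c(el)))],
               tolerance = 1e-10)
})

test_that("jaccard_pairs computes neighborhood similarity over shared neighbors", {
  # a -> {x, y}; b -> {y, z}: J(a,b) = 1/3
  recs <- rbind(rec_row("s1", "a", "x"), rec_row("s2", "a", "y"),
                rec_row("s3", "b", "y"), rec_row("s4", "b", "z"))
  jp <- jaccard_pairs(build_graph(recs), 100)
  ab <- jp[jp$node_a == "STRAIN|a" & jp$node_b == "STRAIN|b", ]
  expect_equal(ab$jaccard, 1 / 3)
  # identical neighborhoods give 1
  recs2 <- rbind(rec_row("s1", "a", "x"), rec_row("s2", "a", "y"),
                 rec_row("s3", "b", "x"), rec_row("s4", "b", "y"))
  jp2 <- jaccard_pairs(build_graph(recs2), 100)
  ab2 <- jp2[jp2$node_a == "STRAIN|a" & jp2$node_b == "STRAIN|b", ]
  expect_equal(ab2$jaccard, 1)
  # disjoint neighborhoods are absent
  recs3 <- rbind(rec_row("s1", "a", "x"), rec_row("s2", "b", "y"))
  jp3 <- jaccard_pairs(build_graph(recs3), 100)
  expect_equal(nrow(jp3[jp3$node_a == "STRAIN|a" &
                          jp3$node_b == "STRAIN|b", ]), 0L)
})

test_that("community_modularity finds planted cliques and is seed-deterministic", {
  # two disjoint 5-cliques: planted partition modularity is exactly 0.5
  mk_clique <- function(prefix, members) {
    do.call(rbind, lapply(seq_along(members), function(i)
      do.call(rbind, lapply(seq_along(members), function(j)
        if (i < j) rec_row(paste0(prefix, i, "_", j),
                           members[i], members[j], tcat = "STRAIN")))))
  }
  recs <- rbind(mk_clique("c1", paste0("a", 1:5)),
                mk_clique("c2", paste0("b", 1:5)))
  g <- build_graph(recs)
  cm <- community_modularity(g, seed = 5)
  expect_equal(cm$modularity, 0.5, tolerance = 1e-9)
  expect_equal(length(unique(cm$membership)), 2L)
  # all members of one clique share a community
  memb <- cm$membership
  expect_equal(length(unique(memb[startsWith(names(memb), "STRAIN|a")])), 1L)
  # complete graph has no community structure
  kg <- mk_clique("k", paste0("n", 1:6))
  cmk <- community_modularity(build_graph(kg), seed = 5)
  expect_lte(cmk$modularity, 1e-9)
  # determinism
  cm2 <- community_modularity(g, seed = 5)
  expect_identical(cm$membership, cm2$membership)
})

test_that("graph export writes a readable edge list and GraphML", {
  recs <- rbind(rec_row("s1", "a", "x"), rec_row("s2", "a", "y"))
  g <- build_graph(recs)
  tsv <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  out <- write_graph_files(g, tsv, gml)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 2L)
  expect_equal(sort(back$target), c("x", "y"))
  expect_true(all(back$source_category == "STRAIN"))
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), 3L)
})
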