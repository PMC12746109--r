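# annotation reading, cluster definition/filtering, boosted models,
# GO enrichment

test_that("read_annotations counts Pfam copies and parses genus", {
  dir <- tempfile()
  gg <- gen_genomes(3, n_features = 5, planted_beta = c("1" = 0), seed = 2)
  manifest <- write_interproscan(gg$annotations, dir)
  ann <- read_annotations(manifest)
  # round trip: counts identical to the generator's
  orig <- gg$annotations$counts
  got <- ann$counts
  key <- function(d) paste(d$assembly_id, d$feature)
  expect_setequal(key(got), key(orig))
  expect_equal(got$count[order(key(got))], orig$count[order(key(orig))])
  # the non-Pfam decoy row was ignored
  expect_false(any(grepl("PTHR", ann$counts$feature)))
  # genus = first token of organism, override honored
  expect_equal(ann$meta$genus,
               vapply(strsplit(manifest$organism, " "), `[`, character(1),
                      1))
  ov <- data.frame(assembly_id = manifest$assembly_id[1],
                   genus = "Override")
  ann2 <- read_annotations(manifest, genus_overrides = ov)
  expect_equal(ann2$meta$genus[1], "Override")
})

test_that("malformed rows are skipped with a warning; empty tables error", {
  f <- tempfile()
  writeLines(c("p1\tmd5\t100\tPfam\tPF00005\tABC\t1\t90\t1e-5\tT\td\t-\t-",
               "broken row"), f)
  manifest <- data.frame(assembly_id = "A1", canonical_id = "t1",
                         organism = "Bacillus sp.", path = f)
  expect_warning(ann <- read_annotations(manifest), "malformed")
  expect_equal(ann$counts$count, 1L)
  writeLines(character(), f)
  expect_error(suppressWarnings(read_annotations(manifest)), "empty")
})

mk_records <- function(ids, term, type = "PRESENTS") {
  data.frame(canonical_id = ids, relation_type = type, term = term)
}

test_that("define_clusters applies the min-count threshold and binarizes", {
  gg <- gen_genomes(20, n_features = 5, planted_beta = c("1" = 0), seed = 3)
  meta <- gg$annotations$meta
  recs <- rbind(
    mk_records(meta$canonical_id[1:5], "motile"),
    mk_records(meta$canonical_id[6:20], "rod shaped"),
    mk_records(meta$canonical_id[1:2], "rare")) # only 2 occurrences
  cl <- define_clusters(recs, gg$annotations)
  expect_equal(vapply(cl, `[[`, character(1), "term"),
               c("motile", "rod shaped"))
  motile <- cl[[1]]
  # universe = all 20 assemblies of the relation type; 5 positives
  expect_equal(length(motile$labels), 20L)
  expect_equal(sum(motile$labels), 5L)
  expect_setequal(motile$positives, meta$assembly_id[1:5])
  # permuting record order changes nothing
  cl2 <- define_clusters(recs[sample(nrow(recs)), ], gg$annotations)
  expect_equal(cl, cl2)
})

test_that("filter_clusters enforces assembly, genus and share thresholds", {
  mk_cluster <- function(pos, universe) {
    structure(list(relation_type = "PRESENTS", term = "t",
                   assemblies = universe,
                   labels = setNames(as.integer(universe %in% pos),
                                     universe),
                   positives = pos), class = "phenotype_cluster")
  }
  mk_ann <- function(genera) {
    ids <- paste0("A", seq_along(genera))
    assembly_annotations(
      data.frame(assembly_id = ids, canonical_id = ids, genus = genera),
      data.frame(assembly_id = ids[1], feature = "PF1", count = 1L))
  }
  # 9 positives: dropped by the >= 10 rule
  ann9 <- mk_ann(rep(paste0("G", 1:9)))
  expect_length(filter_clusters(list(mk_cluster(paste0("A", 1:9),
                                                paste0("A", 1:9))), ann9),
                0L)
  # 12 positives, 6 genera, largest 4/12 (33%): dropped (not < 30%)
  gen12 <- c(rep("G1", 4), "G2", "G3", "G4", "G5", rep("G6", 4))
  ann12 <- mk_ann(gen12)
  expect_length(filter_clusters(list(mk_cluster(paste0("A", 1:12),
                                                paste0("A", 1:12))),
                                ann12), 0L)
  # 20 positives, 5 genera, largest 5/20 = 25%: kept
  gen20 <- rep(paste0("G", 1:5), 4)
  ann20 <- mk_ann(gen20)
  expect_length(filter_clusters(list(mk_cluster(paste0("A", 1:20),
                                                paste0("A", 1:20))),
                                ann20), 1L)
  # exactly 30% is dropped, just under is kept (strictness)
  gen10 <- c(rep("G1", 3), "G2", "G3", "G4", "G5", "G6", "G7", "G8")
  expect_length(filter_clusters(list(mk_cluster(paste0("A", 1:10),
                                                paste0("A", 1:10))),
                                mk_ann(gen10)), 0L)
})

test_that("gboost separates a planted feature and ranks it first by gain", {
  gg <- gen_genomes(200, n_features = 51, planted_beta = c("1" = 4),
                    seed = 11)
  cl <- structure(list(relation_type = "PRESENTS", term = "planted",
                       assemblies = names(gg$labels), labels = gg$labels,
                       positives = names(gg$labels)[gg$labels == 1]),
                  class = "phenotype_cluster")
  ts <- train_and_rank(cl, gg$annotations, model_config(seed = 13))
  expect_gt(ts$accuracy, 0.8)
  expect_true(ts$retained)
  expect_equal(ts$importance$feature[1], "PF00001")
  expect_equal(ts$n_train + ts$n_test, 200L)
  expect_equal(ts$n_test, 40L)
})

test_that("label-independent features give chance accuracy and fail the gate", {
  gg <- gen_genomes(200, n_features = 30, planted_beta = c("1" = 0),
                    seed = 17)
  cl <- structure(list(relation_type = "PRESENTS", term = "null",
                       assemblies = names(gg$labels), labels = gg$labels,
                       positives = names(gg$labels)[gg$labels == 1]),
                  class = "phenotype_cluster")
  ts <- train_and_rank(cl, gg$annotations, model_config(seed = 19))
  expect_gte(ts$accuracy, 0.3)
  expect_lte(ts$accuracy, 0.7)
  expect_false(ts$retained)
})

test_that("the accuracy gate is strictly greater-than", {
  gg <- gen_genomes(60, n_features = 10, planted_beta = c("1" = 4),
                    seed = 23)
  cl <- structure(list(relation_type = "PRESENTS", term = "gate",
                       assemblies = names(gg$labels), labels = gg$labels,
                       positives = names(gg$labels)[gg$labels == 1]),
                  class = "phenotype_cluster")
  ts <- train_and_rank(cl, gg$annotations, model_config(seed = 29))
  # retention must equal acc > gate; at gate == acc it must be FALSE
  ts_at <- train_and_rank(cl, gg$annotations, model_config(seed = 29),
                          accuracy_gate = ts$accuracy)
  expect_false(ts_at$retained)
  expect_identical(ts$retained, ts$accuracy > 0.8)
  # error paths
  cl1 <- cl; cl1$labels[] <- 1L
  expect_error(train_and_rank(cl1, gg$annotations), "single-class")
  cl2 <- cl; cl2$labels <- cl2$labels[1:5]
  expect_error(train_and_rank(cl2, gg$annotations), "at least 10")
})

test_that("gboost learns separable data and early-stops", {
  set.seed(5)
  X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- as.integer(X[, 1] > 0)
  fit <- gboost(X[1:150, ], y[1:150], model_config(nrounds = 200),
                X_val = X[151:200, ], y_val = y[151:200])
  expect_lt(length(fit$eval_log), 200L) # early stopping fired
  expect_equal(as.numeric(predict(fit, X[151:200, ]) >= 0.5), y[151:200])
  imp <- fit$importance
  expect_gt(imp$gain[imp$feature == "f1"],
            imp$gain[imp$feature == "f2"])
  expect_error(gboost(X, rep(1, 200)), "single-class")
  expect_error(gboost(X, y[1:10]))
})

test_that("go_enrichment matches hypergeometric enumeration and BH reference", {
  ids <- c("F1", "B1")
  meta <- data.frame(assembly_id = ids, canonical_id = ids,
                     genus = c("G1", "G2"))
  # foreground: 10 copies of PF1; background extra: 10 copies of PF2
  counts <- data.frame(assembly_id = c("F1", "B1"),
                       feature = c("PF1", "PF2"), count = c(10L, 10L))
  ann <- assembly_annotations(meta, counts)
  p2g <- data.frame(pfam = c("PF1", "PF2"), go = c("GO:1", "GO:2"))
  res <- go_enrichment(ann, "F1", p2g, background_assemblies = "B1")
  # table for GO:1 is [[10,0],[0,10]]: two-sided p = 2/choose(20,10)
  p_expect <- 2 / choose(20, 10)
  expect_equal(res$p[res$go == "GO:1"], p_expect, tolerance = 1e-10)
  expect_equal(oracle_fisher_p(matrix(c(10, 0, 0, 10), 2)), p_expect,
               tolerance = 1e-12)
  # identical proportions give p = 1
  counts2 <- data.frame(assembly_id = c("F1", "F1", "B1", "B1"),
                        feature = c("PF1", "PF2", "PF1", "PF2"),
                        count = c(5L, 5L, 5L, 5L))
  ann2 <- assembly_annotations(meta, counts2)
  res2 <- go_enrichment(ann2, "F1", p2g, background_assemblies = "B1")
  expect_true(all(res2$p == 1))
  expect_error(go_enrichment(ann, "F1", p2g[0, ]), "empty")
})

test_that("BH q-values are monotone and match the reference on random p", {
  set.seed(8)
  p <- runif(40)
  expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  # equal p-values share their q
  expect_equal(p.adjust(rep(0.01, 7), "BH"), rep(0.01, 7))
  # q monotone non-decreasing in p-rank
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})
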