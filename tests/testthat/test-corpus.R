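# corpus filtering, tokenization, BIO encoding, splits, augmentation

test_that("filter_corpus applies section, language, hyphen, dedup and length rules", {
  records <- data.frame(
    id = c("a", "b", "c", "d", "e", "f", "g"),
    text = c("Strains were isolated.",            # kept
             "We thank the funders.",             # excluded section
             "Gram-negative rod morphology.",     # hyphen rule
             "Strains were isolated.",            # duplicate of a
             "Ein Satz auf Deutsch.",             # low english
             NA,                                  # no text
             "Une phrase au seuil."),             # confidence exactly 0.4
    section = c("results", "acknowledgements", "results", "methods",
                "results", "results", "results"),
    english_confidence = c(0.99, 0.99, 0.95, 0.99, 0.2, 0.9, 0.4))
  out <- filter_corpus(records)
  ids <- vapply(out$sentences, `[[`, character(1), "id")
  expect_equal(ids, c("a", "c"))
  expect_equal(out$sentences[[2]]$text, "Gram negative rod morphology.")
  expect_setequal(out$dropped$reason[out$dropped$id == "b"],
                  "excluded_section")
  expect_setequal(out$dropped$reason[out$dropped$id == "d"], "duplicate")
  expect_setequal(out$dropped$reason[out$dropped$id == "e"], "low_english")
  expect_setequal(out$dropped$reason[out$dropped$id == "f"], "no_text")
  # threshold is strict: confidence == 0.4 is dropped
  expect_setequal(out$dropped$reason[out$dropped$id == "g"], "low_english")
})

test_that("long paragraphs are emitted sentence by sentence, short ones whole", {
  short <- paste(rep("a", 100), collapse = "")
  long_ <- paste(rep("This is a sentence about strains.", 20),
                 collapse = " ")
  stopifnot(nchar(long_) >= 512)
  records <- data.frame(id = c("s", "l"), text = c(short, long_),
                        section = "results", english_confidence = 1)
  out <- filter_corpus(records)
  ids <- vapply(out$sentences, `[[`, character(1), "id")
  expect_equal(sum(ids == "s"), 1L)
  # identical sentences inside the paragraph deduplicate to one
  expect_equal(sum(startsWith(ids, "l.")), 1L)
  dedup_drops <- out$dropped[out$dropped$id == "l", ]
  expect_equal(nrow(dedup_drops), 19L)
})

test_that("tokenize detaches punctuation and reconstructs the text", {
  tk <- tokenize("E. coli grows.")
  expect_equal(tk$text, c("E", ".", "coli", "grows", "."))
  expect_equal(tk$start, c(0L, 1L, 3L, 8L, 13L))
  expect_equal(tk$end, c(1L, 2L, 7L, 13L, 14L))
  expect_equal(nrow(tokenize("")), 0L)
  # round-trip property: token slices + gaps reproduce the text
  texts <- c("Strain X33 (ATCC 700-2) grows, e.g., on LB.",
             "pH 7.0; 37C.", "  leading and trailing  ",
             "a-b c--d e.f.g !?", "one")
  for (tx in texts) {
    tk <- tokenize(tx)
    for (i in seq_len(nrow(tk))) {
      expect_identical(substr(tx, tk$start[i] + 1L, tk$end[i]), tk$text[i])
    }
    # tokens tile non-whitespace in order
    covered <- unlist(lapply(seq_len(nrow(tk)), function(i)
      seq(tk$start[i] + 1L, tk$end[i])))
    nonws <- which(strsplit(tx, "")[[1]] != " ")
    expect_identical(covered, as.integer(nonws))
  }
})

test_that("bio_encode marks B/I/O per the span extents", {
  s <- annotated_sentence(
    "s1", "Strain X33 grows",
    spans = data.frame(category = "STRAIN", start = 7L, end = 10L))
  expect_equal(bio_encode(s, "STRAIN"), c("O", "B", "O"))
  expect_equal(bio_encode(s, "MEDIUM"), c("O", "O", "O"))
  s2 <- annotated_sentence(
    "s2", "Bacillus subtilis 168 grows here",
    spans = data.frame(category = "STRAIN", start = 0L, end = 21L))
  expect_equal(bio_encode(s2, "STRAIN"), c("B", "I", "I", "O", "O"))
  s3 <- annotated_sentence(
    "s3", "aa bb cc",
    spans = data.frame(category = c("STRAIN", "STRAIN"),
                       start = c(0L, 3L), end = c(5L, 8L)))
  expect_error(bio_encode(s3, "STRAIN"), "overlapping")
})

test_that("bio_decode inverts bio_encode on non-overlapping spans", {
  set.seed(42)
  words <- c("Strain", "X33", "grows", "on", "LB", "medium", "fast", "now")
  for (rep_ in 1:50) {
    text <- paste(sample(words, 6, replace = TRUE), collapse = " ")
    tk <- tokenize(text)
    i <- sort(sample.int(nrow(tk), 2))
    spans <- data.frame(category = "STRAIN",
                        start = tk$start[i[1]], end = tk$end[i[2]])
    s <- annotated_sentence("r", text, spans = spans)
    dec <- bio_decode(tk, bio_encode(s, "STRAIN"))
    expect_equal(dec$start, spans$start)
    expect_equal(dec$end, spans$end)
  }
})

test_that("stratified_split partitions deterministically with largest-remainder sizes", {
  mk <- function(n) lapply(seq_len(n), function(i)
    annotated_sentence(paste0("s", i), "text here"))
  # 3979 at (0.65, 0.175, 0.175): floors (2586,696,696), remainders
  # (.35,.325,.325) -> leftover to the largest remainder (train)
  sp <- stratified_split(mk(3979), c(0.65, 0.175, 0.175), seed = 7)
  expect_equal(lengths(sp), c(train = 2587L, eval = 696L, test = 696L))
  sp10 <- stratified_split(mk(10), c(0.6, 0.2, 0.2), seed = 7)
  expect_equal(lengths(sp10), c(train = 6L, eval = 2L, test = 2L))
  # disjoint + exhaustive + deterministic
  all_idx <- sort(unname(unlist(sp)))
  expect_equal(all_idx, 1:3979)
  sp2 <- stratified_split(mk(3979), c(0.65, 0.175, 0.175), seed = 7)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(mk(3979), c(0.65, 0.175, 0.175), seed = 8)
  expect_false(identical(sp, sp3))
})

test_that("stratified_split keeps per-stratum proportions within one item", {
  set.seed(11)
  sents <- lapply(1:200, function(i) {
    spans <- if (i %% 3 == 0)
      data.frame(category = "STRAIN", start = 0L, end = 6L) else
        if (i %% 3 == 1)
          data.frame(category = "COMPOUND", start = 0L, end = 6L) else NULL
    annotated_sentence(paste0("s", i), "glucose strain terms", spans = spans)
  })
  sp <- stratified_split(sents, c(0.6, 0.2, 0.2), seed = 3)
  sig <- vapply(sents, function(s)
    paste(sort(unique(s$spans$category)), collapse = "+"), character(1))
  for (key in unique(sig)) {
    n_k <- sum(sig == key)
    for (p in 1:3) {
      got <- sum(sig[sp[[p]]] == key)
      expect_lte(abs(got - n_k * c(0.6, 0.2, 0.2)[p]), 1)
    }
  }
})

test_that("plan_augmentation follows the NER and RE formulas", {
  expect_equal(plan_augmentation(100, 300, "NER")$n_aug, 200L)
  expect_equal(plan_augmentation(300, 100, "NER")$n_aug, 0L)
  expect_equal(plan_augmentation(100, 300, "RE")$n_aug, 40L)
  expect_equal(plan_augmentation(100, 301, "RE")$n_aug, 41L) # ceil
  expect_equal(plan_augmentation(300, 100, "RE")$n_aug, 0L)
  expect_error(plan_augmentation(-1, 5, "NER"), "non-negative")
  # after NER augmentation the classes balance exactly
  p <- plan_augmentation(120, 345, "NER")
  expect_equal(p$n_pos + p$n_aug, p$n_neg)
})

test_that("augment_by_strain_swap replaces only STRAIN text and keeps offsets valid", {
  s <- annotated_sentence(
    "s1", "Strain Bacillus subtilis 168 produces glucose today",
    spans = data.frame(category = c("STRAIN", "COMPOUND"),
                       start = c(7L, 38L), end = c(28L, 45L)),
    relations = data.frame(type = "PRODUCES", source_idx = 1L,
                           target_idx = 2L, label = 1L))
  plan0 <- plan_augmentation(5, 5, "NER")
  expect_equal(augment_by_strain_swap(list(s), c("X"), plan0), list())
  plan <- plan_augmentation(0, 5, "NER", seed = 9)
  catalog <- paste("Escherichia coli STR", 1:10)
  out <- augment_by_strain_swap(list(s), catalog, plan)
  expect_length(out, 5L)
  for (a in out) {
    strain <- a$spans[a$spans$category == "STRAIN", ]
    expect_true(strain$term %in% catalog)
    comp <- a$spans[a$spans$category == "COMPOUND", ]
    expect_identical(comp$term, "glucose")
    # non-strain text unchanged
    expect_identical(sub(strain$term, "<S>", a$text, fixed = TRUE),
                     "Strain <S> produces glucose today")
    expect_equal(nrow(a$relations), 1L)
  }
  # no eligible sentence
  bare <- annotated_sentence("b", "no entities at all")
  expect_error(augment_by_strain_swap(list(bare), catalog, plan),
               "eligible")
  # reproducible under the plan's seed
  out2 <- augment_by_strain_swap(list(s), catalog, plan)
  expect_identical(vapply(out, `[[`, character(1), "text"),
                   vapply(out2, `[[`, character(1), "text"))
})

test_that("synthetic swaps always yield valid BIO sequences", {
  base <- gen_corpus(50, entity_free_fraction = 0, strain_fraction = 1,
                     seed = 21)$sentences
  catalog <- vapply(1:30, function(i)
    paste("Rhodococcus erythropolis STR", i), character(1))
  plan <- plan_augmentation(0, 1000, "NER", seed = 33)
  out <- augment_by_strain_swap(base, catalog, plan)
  expect_length(out, 1000L)
  ok <- vapply(out, function(a) {
    lab <- bio_encode(a, "STRAIN")
    # I never follows O; at least one B
    !any(lab == "I" & c("O", head(lab, -1)) == "O") && any(lab == "B")
  }, logical(1))
  expect_true(all(ok))
})
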