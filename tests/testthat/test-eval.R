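# token-score aggregation, cross-entropy loss, strict/partial NER metrics,
# binary RE metrics

mk_batch <- function(p_true_by_sentence) {
  lapply(p_true_by_sentence, function(ps) {
    probs <- t(vapply(ps, function(p)
      c(B = p, I = (1 - p) / 2, O = (1 - p) / 2), numeric(3)))
    list(labels = rep("B", length(ps)), probs = probs)
  })
}

test_that("cross_entropy_loss matches hand-computed values", {
  expect_equal(cross_entropy_loss(mk_batch(list(1))), 0)
  # one sentence, two tokens with true-class probabilities 0.5 and 0.25
  expect_equal(cross_entropy_loss(mk_batch(list(c(0.5, 0.25)))),
               -(log(0.5) + log(0.25)))
  # duplicating sentences leaves the mean unchanged
  one <- mk_batch(list(c(0.5, 0.25)))
  expect_equal(cross_entropy_loss(c(one, one)), cross_entropy_loss(one))
  # zero probability floored with a warning, loss stays finite
  expect_warning(l0 <- cross_entropy_loss(mk_batch(list(0))), "floored")
  expect_true(is.finite(l0) && l0 > 0)
  # invalid probability rows rejected
  bad <- list(list(labels = "B",
                   probs = matrix(c(0.5, 0.2, 0.2), 1,
                                  dimnames = list(NULL, c("B", "I", "O")))))
  expect_error(cross_entropy_loss(bad), "sum to 1")
})

test_that("aggregate_spans merges runs, max-aggregates and thresholds at >= 0.5", {
  toks <- data.frame(class = c("B", "I", "O", "B"),
                     score = c(0.4, 0.7, 0.9, 0.49),
                     start = 0:3, end = 1:4)
  sp <- aggregate_spans(toks)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$score, 0.7)         # max over the run
  expect_equal(sp$start, 0L)
  expect_equal(sp$end, 2L)            # the 0.49 B-token span is dropped
  # exactly 0.5 is retained (inclusive threshold)
  sp2 <- aggregate_spans(data.frame(class = "B", score = 0.5,
                                    start = 0L, end = 1L))
  expect_equal(nrow(sp2), 1L)
  expect_equal(nrow(aggregate_spans(data.frame(class = character(),
                                               score = numeric(),
                                               start = integer(),
                                               end = integer()))), 0L)
  all_o <- data.frame(class = "O", score = 0.99, start = 0L, end = 1L)
  expect_equal(nrow(aggregate_spans(all_o)), 0L)
})

test_that("ner_metrics reproduces the worked strict and partial examples", {
  one <- list(data.frame(start = 0L, end = 3L))
  for (mode in c("strict", "partial")) {
    m <- ner_metrics(one, one, mode)
    expect_equal(c(m$P, m$R, m$F1), c(1, 1, 1))
  }
  # 3 predicted, 2 exact among 4 gold, strict: P=2/3 R=0.5 F1=4/7
  pred <- list(data.frame(start = c(0L, 5L, 20L), end = c(3L, 8L, 25L)))
  gold <- list(data.frame(start = c(0L, 5L, 10L, 15L),
                          end = c(3L, 8L, 12L, 18L)))
  m <- ner_metrics(pred, gold, "strict")
  expect_equal(m$COR, 2L)
  expect_equal(m$P, 2 / 3)
  expect_equal(m$R, 0.5)
  expect_equal(m$F1, 4 / 7)
  # COR=1, PAR=1 in partial mode: P = (1 + 0.5)/3
  pred2 <- list(data.frame(start = c(0L, 5L, 20L), end = c(3L, 9L, 25L)))
  m2 <- ner_metrics(pred2, gold, "partial")
  expect_equal(m2$COR, 1L)
  expect_equal(m2$PAR, 1L)
  expect_equal(m2$P, 0.5)
  expect_error(ner_metrics(pred, gold, "bogus"))
})

test_that("metric values stay in [0,1] and F1 is 0 when P + R = 0", {
  m <- ner_metrics(list(data.frame(start = 0L, end = 2L)),
                   list(data.frame(start = 5L, end = 7L)), "partial")
  expect_equal(m$F1, 0)
  set.seed(99)
  for (rep_ in 1:100) {
    pred <- list(random_span_set())
    gold <- list(random_span_set())
    for (mode in c("strict", "partial")) {
      m <- ner_metrics(pred, gold, mode)
      expect_true(all(c(m$P, m$R, m$F1) >= 0 & c(m$P, m$R, m$F1) <= 1))
    }
  }
})

test_that("re_metrics computes binary precision/recall/F1", {
  expect_equal(re_metrics(c(1, 0, 1), c(1, 0, 1))$F1, 1)
  m0 <- re_metrics(c(0, 0, 0), c(1, 0, 0))
  expect_equal(m0$R, 0)
  expect_equal(m0$F1, 0)
  # TP=8 FP=2 FN=2
  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), 0, 0, rep(0, 8), 1, 1)
  m <- re_metrics(pred, truth)
  expect_equal(c(m$P, m$R, m$F1), c(0.8, 0.8, 0.8))
  # numeric scores threshold at >= 0.5
  expect_equal(re_metrics(c(0.5, 0.49), c(1, 0))$F1, 1)
  expect_error(re_metrics(c(1, 0), c(1)), "length")
})

test_that("evaluate_ner scores span predictions per category against a corpus", {
  s1 <- annotated_sentence(
    "s1", "Strain X33 produces glucose",
    spans = data.frame(category = c("STRAIN", "COMPOUND"),
                       start = c(7L, 20L), end = c(10L, 27L)))
  s2 <- annotated_sentence("s2", "no entities here")
  pred <- data.frame(
    sentence_id = c("s1", "s1", "s2"),
    category = c("STRAIN", "COMPOUND", "STRAIN"),
    start = c(7L, 20L, 0L), end = c(10L, 25L, 2L),
    score = c(0.9, 0.8, 0.7))
  rep_ <- evaluate_ner(pred, list(s1, s2))
  strain_strict <- rep_[rep_$target == "STRAIN" & rep_$mode == "strict", ]
  expect_equal(strain_strict$COR, 1L)
  expect_equal(strain_strict$P, 0.5)   # the s2 false positive
  expect_equal(strain_strict$R, 1)
  comp_partial <- rep_[rep_$target == "COMPOUND" & rep_$mode == "partial", ]
  expect_equal(comp_partial$PAR, 1L)
  expect_equal(comp_partial$P, 0.5)
  # low-score predictions drop before matching
  rep2 <- evaluate_ner(transform(pred, score = 0.4), list(s1, s2))
  expect_true(all(rep2$n_pred == 0))
})

test_that("evaluate_re scores per relation type with gold from annotations", {
  s1 <- annotated_sentence(
    "s1", "Strain X produces glucose",
    spans = data.frame(category = c("STRAIN", "COMPOUND"),
                       start = c(0L, 18L), end = c(8L, 25L)),
    relations = data.frame(type = "PRODUCES", source_idx = 1L,
                           target_idx = 2L, label = 1L))
  s2 <- annotated_sentence("s2", "nothing to see")
  preds <- data.frame(sentence_id = c("s1", "s2"),
                      relation_type = "PRODUCES", score = c(0.9, 0.8))
  rep_ <- evaluate_re(preds, list(s1, s2))
  expect_equal(rep_$P, 0.5)  # s2 is a false positive
  expect_equal(rep_$R, 1)
  expect_equal(rep_$F1, 2 / 3)
})
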