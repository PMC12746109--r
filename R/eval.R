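# Evaluation of token-classification and relation predictions: cross-entropy
# loss, max-aggregation of token scores into entity spans, strict/partial
# span-matching precision/recall/F1, and binary relation metrics.

#' Mean cross-entropy loss of a token-prediction batch
#'
#' `L = -(1/N) * sum_i sum_t sum_c delta(y_it, c) * log p_itc`, the mean (over
#' sentences) summed negative log-likelihood of the true token classes under
#' the predicted `B`/`I`/`O` probabilities.
#'
#' @param batch List of sentences, each a list with `labels` (character
#'   vector over `B`,`I`,`O`) and `probs` (numeric matrix, tokens x 3 with
#'   columns named `B`,`I`,`O`, rows summing to 1).
#' @param eps Probability floor applied before taking logs; a triggered floor
#'   is reported with a warning. Default `1e-12`.
#' @return Non-negative loss value; `0` iff every true-class probability is 1.
#' @export
cross_entropy_loss <- function(batch, eps = 1e-12) {
  stopifnot(length(batch) >= 1L)
  total <- 0
  floored <- FALSE
  for (s in batch) {
    probs <- as.matrix(s$probs)
    labels <- as.character(s$labels)
    stopifnot(nrow(probs) == length(labels),
              all(labels %in% c("B", "I", "O")),
              all(c("B", "I", "O") %in% colnames(probs)))
    if (any(abs(rowSums(probs) - 1) > 1e-6)) {
      stop("per-token probabilities must sum to 1")
    }
    p_true <- probs[cbind(seq_along(labels), match(labels, colnames(probs)))]
    if (any(p_true < eps)) {
      floored <- TRUE
      p_true <- pmax(p_true, eps)
    }
    total <- total - sum(log(p_true))
  }
  if (floored) warning("zero/near-zero true-class probability floored at ",
                       eps)
  total / length(batch)
}

#' Aggregate token-level scores into entity span predictions
#'
#' Maximal runs of consecutive tokens predicted `B` or `I` are merged into
#' one span; the span score is the maximum token score over the run
#' (max aggregation). Spans scoring below the threshold are dropped; the
#' comparison is inclusive (a score of exactly `threshold` is a positive
#' hit).
#'
#' @param tokens `data.frame` with one row per token: `class` (predicted
#'   class among `B`,`I`,`O`), `score` (probability of that class) and
#'   token extents `start`, `end` (any consistent coordinate, e.g. character
#'   offsets from [tokenize()] or token indices).
#' @param threshold Minimum span score retained; default `0.5`.
#' @return `data.frame` of spans with `start`, `end` (the run's outer
#'   extents), `score`, `first_token`, `last_token`.
#' @export
aggregate_spans <- function(tokens, threshold = 0.5) {
  tokens <- as.data.frame(tokens)
  if (!nrow(tokens)) {
    return(data.frame(start = integer(), end = integer(), score = numeric(),
                      first_token = integer(), last_token = integer()))
  }
  stopifnot(all(c("class", "score", "start", "end") %in% names(tokens)))
  inside <- tokens$class %in% c("B", "I")
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- data.frame(start = tokens$start[starts[keep]],
                    end = tokens$end[ends[keep]],
                    score = vapply(keep, function(r)
                      max(tokens$score[starts[r]:ends[r]]), numeric(1)),
                    first_token = starts[keep], last_token = ends[keep])
  out[out$score >= threshold, , drop = FALSE]
}

# Exact maximum-credit one-to-one matching between predicted and gold spans
# of one sentence. Credit: 1 for an exact-extent match; `partial_credit` for
# a non-exact overlap. Ties between equal-credit assignments are broken
# deterministically (prefer exact, then larger overlap, then earlier gold
# start). Memoised search over (prediction index, set of used golds);
# span sets within a sentence are small, and candidate golds are only those
# overlapping a prediction, so the state space stays tiny in practice.
match_spans <- function(pred, gold, partial_credit = 0.5) {
  np <- nrow(pred); ng <- nrow(gold)
  if (!np || !ng) return(list(cor = 0L, par = 0L))
  if (ng > 30L) stop("too many gold spans in one sentence for exact matching")
  overlap <- function(i, j) {
    max(0, min(pred$end[i], gold$end[j]) - max(pred$start[i], gold$start[j]))
  }
  cand <- lapply(seq_len(np), function(i) {
    js <- which(gold$start < pred$end[i] & gold$end > pred$start[i])
    if (!length(js)) return(NULL)
    ex <- gold$start[js] == pred$start[i] & gold$end[js] == pred$end[i]
    ov <- vapply(js, function(j) overlap(i, j), numeric(1))
    # deterministic preference order for equal total credit
    ord <- order(-ex, -ov, gold$start[js])
    js <- js[ord]; ex <- ex[ord]
    data.frame(j = js, exact = ex, credit = ifelse(ex, 1, partial_credit))
  })
  memo <- new.env(parent = emptyenv())
  best <- function(i, used) {
    if (i > np) return(c(0, 0, 0))            # credit, cor, par
    key <- paste0(i, "|", paste(used, collapse = ","))
    hit <- get0(key, envir = memo)
    if (!is.null(hit)) return(hit)
    res <- best(i + 1L, used)                 # leave prediction i unmatched
    ci <- cand[[i]]
    if (!is.null(ci)) {
      for (r in seq_len(nrow(ci))) {
        j <- ci$j[r]
        if (ci$credit[r] == 0 || j %in% used) next
        sub <- best(i + 1L, sort(c(used, j)))
        tot <- c(sub[1] + ci$credit[r],
                 sub[2] + as.integer(ci$exact[r]),
                 sub[3] + as.integer(!ci$exact[r]))
        # maximise credit, then exact-match count
        if (tot[1] > res[1] + 1e-12 ||
            (abs(tot[1] - res[1]) <= 1e-12 && tot[2] > res[2])) res <- tot
      }
    }
    assign(key, res, envir = memo)
    res
  }
  r <- best(1L, integer())
  list(cor = as.integer(r[2]), par = as.integer(r[3]))
}

#' Strict and partial span-matching metrics for entity predictions
#'
#' Counts exact-extent matches (`COR`) and non-exact overlaps (`PAR`) under
#' one-to-one matching between predicted and gold spans, per sentence, then
#' computes precision and recall. Strict mode: `P = COR/(TP+FP)`,
#' `R = COR/(TP+FN)`; partial mode grants half credit to overlaps:
#' `P = (COR + 0.5*PAR)/(TP+FP)`, `R = (COR + 0.5*PAR)/(TP+FN)`, where
#' `TP+FP` is the number of predicted spans and `TP+FN` the number of gold
#' spans. `F1 = 2PR/(P+R)` (0 when `P + R = 0`).
#'
#' The matcher maximises total matching credit exactly (1 per exact match,
#' 0.5 per overlap in partial mode; exact matches only in strict mode), with
#' each gold span matched at most once.
#'
#' @param pred,gold Lists (one element per sentence) of span `data.frame`s
#'   with `start`, `end` columns; extents must be in the same coordinate
#'   system on both sides.
#' @param mode `"strict"` or `"partial"`.
#' @return A `metric_result` list with `mode`, `COR`, `PAR`, `n_pred`,
#'   `n_gold`, `P`, `R`, `F1`.
#' @export
ner_metrics <- function(pred, gold, mode = c("strict", "partial")) {
  mode <- match.arg(mode)
  stopifnot(length(pred) == length(gold))
  cor <- 0L; par <- 0L; n_pred <- 0L; n_gold <- 0L
  for (i in seq_along(pred)) {
    p <- as.data.frame(pred[[i]]); g <- as.data.frame(gold[[i]])
    n_pred <- n_pred + nrow(p); n_gold <- n_gold + nrow(g)
    if (!nrow(p) || !nrow(g)) next
    m <- if (mode == "strict") {
      # only exact matches earn credit; overlaps are not counted as PAR
      ex <- match_spans(p, g, partial_credit = 0)
      list(cor = ex$cor, par = 0L)
    } else match_spans(p, g, partial_credit = 0.5)
    cor <- cor + m$cor; par <- par + m$par
  }
  credit <- if (mode == "strict") cor else cor + 0.5 * par
  P <- if (n_pred > 0) credit / n_pred else 0
  R <- if (n_gold > 0) credit / n_gold else 0
  metric_result(mode, cor, par, n_pred, n_gold, P, R)
}

metric_result <- function(mode, cor, par, n_pred, n_gold, P, R) {
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(list(mode = mode, COR = cor, PAR = par,
                 n_pred = n_pred, n_gold = n_gold,
                 P = P, R = R, F1 = F1), class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<%s metrics> COR=%d PAR=%d pred=%d gold=%d P=%.4f R=%.4f F1=%.4f\n",
              x$mode, x$COR, x$PAR, x$n_pred, x$n_gold, x$P, x$R, x$F1))
  invisible(x)
}

#' Binary relation-extraction metrics
#'
#' Standard binary precision/recall/F1 with the positive class being
#' "relation present". Numeric predictions are thresholded at `>= 0.5`.
#'
#' @param pred Predicted labels: logical/0-1 vector, or numeric scores in
#'   `[0, 1]`.
#' @param truth True binary labels, same length.
#' @return A `metric_result` (mode `"binary"`; `COR` holds TP).
#' @export
re_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  pred <- as.numeric(pred) >= 0.5
  truth <- as.numeric(truth) >= 0.5
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  P <- if (tp + fp > 0) tp / (tp + fp) else 0
  R <- if (tp + fn > 0) tp / (tp + fn) else 0
  metric_result("binary", as.integer(tp), 0L, as.integer(tp + fp),
                as.integer(tp + fn), P, R)
}

#' Read span predictions from JSONL
#'
#' One record per sentence and category:
#' `{sentence_id, category, spans: [{start, end, score}]}`.
#'
#' @param path JSONL file path.
#' @return `data.frame` with `sentence_id`, `category`, `start`, `end`,
#'   `score`.
#' @export
read_span_predictions <- function(path) {
  recs <- read_jsonl(path)
  rows <- lapply(recs, function(r) {
    sp <- as.data.frame(r$spans)
    if (!nrow(sp)) return(NULL)
    data.frame(sentence_id = as.character(r$sentence_id),
               category = as.character(r$category),
               start = sp$start, end = sp$end,
               score = if ("score" %in% names(sp)) sp$score else 1)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sentence_id = character(), category = character(),
                      start = integer(), end = integer(),
                      score = numeric())
  }
  out
}

#' Evaluate span predictions against an annotated corpus
#'
#' Computes strict and partial metrics per entity category, using character
#' extents. Predictions scoring below the threshold are dropped first.
#'
#' @param predictions `data.frame` from [read_span_predictions()].
#' @param sentences List of [annotated_sentence()] gold sentences.
#' @param categories Categories to evaluate (default: all with gold or
#'   predicted spans).
#' @param threshold Score threshold (inclusive), default 0.5.
#' @return `data.frame`: one row per (category, mode) with `COR`, `PAR`,
#'   `n_pred`, `n_gold`, `P`, `R`, `F1`.
#' @export
evaluate_ner <- function(predictions, sentences, categories = NULL,
                         threshold = 0.5) {
  predictions <- predictions[predictions$score >= threshold, , drop = FALSE]
  gold_by_id <- setNames(sentences, vapply(sentences, `[[`, character(1),
                                           "id"))
  if (is.null(categories)) {
    categories <- sort(unique(c(
      predictions$category,
      unlist(lapply(sentences, function(s) s$spans$category)))))
  }
  rows <- list()
  for (cat_ in categories) {
    pred <- lapply(names(gold_by_id), function(id) {
      p <- predictions[predictions$sentence_id == id &
                         predictions$category == cat_, , drop = FALSE]
      p[, c("start", "end"), drop = FALSE]
    })
    gold <- lapply(gold_by_id, function(s) {
      g <- s$spans[s$spans$category == cat_, , drop = FALSE]
      g[, c("start", "end"), drop = FALSE]
    })
    for (mode in c("strict", "partial")) {
      m <- ner_metrics(pred, gold, mode)
      rows[[length(rows) + 1L]] <- data.frame(
        target = cat_, mode = mode, COR = m$COR, PAR = m$PAR,
        n_pred = m$n_pred, n_gold = m$n_gold, P = m$P, R = m$R, F1 = m$F1)
    }
  }
  do.call(rbind, rows)
}

#' Evaluate binary relation predictions against an annotated corpus
#'
#' Gold labels come from the sentences' relation annotations (a relation
#' type is positive for a sentence when any annotated instance of it has
#' label 1); predictions carry a score per (sentence, relation type).
#'
#' @param predictions `data.frame` with `sentence_id`, `relation_type`,
#'   `score`.
#' @param sentences List of [annotated_sentence()] gold sentences.
#' @return `data.frame`: one row per relation type with TP-based counts
#'   and `P`, `R`, `F1`.
#' @export
evaluate_re <- function(predictions, sentences) {
  ids <- vapply(sentences, `[[`, character(1), "id")
  rows <- list()
  for (rt in sort(unique(predictions$relation_type))) {
    gold <- vapply(sentences, function(s)
      as.integer(nrow(s$relations) > 0 &&
                   any(s$relations$type == rt & s$relations$label == 1)),
      integer(1))
    p <- predictions[predictions$relation_type == rt, , drop = FALSE]
    score <- setNames(rep(0, length(ids)), ids)
    score[p$sentence_id[p$sentence_id %in% ids]] <-
      p$score[p$sentence_id %in% ids]
    m <- re_metrics(score, gold)
    rows[[length(rows) + 1L]] <- data.frame(
      target = rt, mode = "binary", COR = m$COR, PAR = 0L,
      n_pred = m$n_pred, n_gold = m$n_gold, P = m$P, R = m$R, F1 = m$F1)
  }
  do.call(rbind, rows)
}
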