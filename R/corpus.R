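# Sentence/annotation data model, corpus filtering, reference tokenizer,
# BIO encoding, stratified splits and class-imbalance augmentation.
#
# All character offsets are 0-based, half-open: a span (start, end) covers
# text substring [start+1, end] in R's 1-based substr() terms.

#' Construct an annotated sentence
#'
#' The unit record of the corpus: a sentence (or short paragraph) with
#' optional entity spans and binary relation annotations. Character offsets
#' are 0-based and half-open.
#'
#' @param id Sentence identifier.
#' @param text Sentence text.
#' @param section Section label of the originating article (e.g.
#'   `"results"`), used by corpus filtering.
#' @param english_confidence Language-identification confidence that the
#'   text is English, in `[0, 1]`.
#' @param spans `data.frame` with columns `category`, `start`, `end` (and
#'   optionally `term`; recomputed from `text` when absent). One row per
#'   entity span.
#' @param relations `data.frame` with columns `type`, `source_idx`,
#'   `target_idx` (1-based row indices into `spans`) and binary `label`.
#' @return An object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(id, text, section = "body",
                               english_confidence = 1,
                               spans = NULL, relations = NULL) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (is.null(spans)) {
    spans <- data.frame(category = character(), start = integer(),
                        end = integer(), term = character())
  }
  spans <- as.data.frame(spans)
  if (nrow(spans)) {
    stopifnot(all(c("category", "start", "end") %in% names(spans)))
    bad <- !spans$category %in% entity_categories()
    if (any(bad)) {
      stop("unknown entity category: ", paste(unique(spans$category[bad]),
                                              collapse = ", "))
    }
    if (any(spans$start >= spans$end) || any(spans$start < 0) ||
        any(spans$end > nchar(text))) {
      stop("span offsets out of range for sentence ", id)
    }
    spans$term <- substr(rep(text, nrow(spans)), spans$start + 1L, spans$end)
  }
  if (is.null(relations)) {
    relations <- data.frame(type = character(), source_idx = integer(),
                            target_idx = integer(), label = integer())
  }
  relations <- as.data.frame(relations)
  if (nrow(relations)) {
    stopifnot(all(c("type", "source_idx", "target_idx", "label")
                  %in% names(relations)))
    if (!all(relations$type %in% relation_types())) {
      stop("unknown relation type in sentence ", id)
    }
    idx <- c(relations$source_idx, relations$target_idx)
    if (any(idx < 1L | idx > nrow(spans))) {
      stop("relation span index out of range in sentence ", id)
    }
  }
  structure(list(id = as.character(id), text = text,
                 section = as.character(section),
                 english_confidence = as.numeric(english_confidence),
                 spans = spans, relations = relations),
            class = "annotated_sentence")
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat(sprintf("<annotated_sentence %s: %d spans, %d relations>\n  %s\n",
              x$id, nrow(x$spans), nrow(x$relations), x$text))
  invisible(x)
}

# Sections unlikely to contain strain descriptions, dropped by default.
default_excluded_sections <- function() {
  c("acknowledgements", "acknowledgments", "author declarations",
    "data availability", "legends")
}

# Replace the hyphen in hyphenated words with a space ("Gram-negative" ->
# "Gram negative"); hyphens not flanked by word characters are untouched.
dehyphenate <- function(text) {
  gsub("(?<=[[:alnum:]])-(?=[[:alnum:]])", " ", text, perl = TRUE)
}

# Normalization used for duplicate detection: case-fold + collapse whitespace.
normalize_for_dedup <- function(text) {
  tolower(gsub("[[:space:]]+", " ", trimws(text)))
}

# Deterministic sentence splitter for long paragraphs: break after
# [.!?] followed by whitespace and an upper-case/digit start.
split_sentences <- function(text) {
  parts <- strsplit(text, "(?<=[.!?])[[:space:]]+(?=[A-Z0-9])",
                    perl = TRUE)[[1]]
  parts[nzchar(trimws(parts))]
}

#' Filter and normalize raw text records into a corpus
#'
#' Applies the corpus preparation rules: records from excluded sections are
#' dropped; records whose English-language confidence is not strictly above
#' the threshold are dropped; hyphens inside hyphenated words are replaced by
#' spaces; exact duplicates (after case-folding and whitespace collapsing)
#' are dropped; paragraphs shorter than 512 characters are emitted whole
#' while longer ones are emitted sentence by sentence. An optional journal
#' allowlist restricts records to biology-related journals.
#'
#' @param records `data.frame` with columns `id`, `text`, `section` and
#'   `english_confidence` (optionally `journal`).
#' @param min_english_confidence Records are kept only when
#'   `english_confidence > min_english_confidence` (strict). Default `0.4`.
#' @param excluded_sections Character vector of section labels to drop
#'   (case-insensitive).
#' @param journal_allowlist Optional character vector; when supplied, records
#'   whose `journal` is not listed are dropped.
#' @param max_paragraph_chars Paragraphs with fewer characters than this are
#'   emitted in full; longer ones are split into sentences. Default `512`.
#' @return A list with `sentences` (list of [annotated_sentence()]) and
#'   `dropped` (`data.frame` of record ids with reason codes among
#'   `no_text`, `excluded_section`, `not_allowlisted`, `low_english`,
#'   `duplicate`).
#' @export
filter_corpus <- function(records, min_english_confidence = 0.4,
                          excluded_sections = default_excluded_sections(),
                          journal_allowlist = NULL,
                          max_paragraph_chars = 512L) {
  records <- as.data.frame(records)
  stopifnot(all(c("id", "section", "english_confidence") %in% names(records)))
  if (!"text" %in% names(records)) records$text <- NA_character_
  dropped <- data.frame(id = character(), reason = character())
  drop <- function(id, reason) {
    dropped <<- rbind(dropped, data.frame(id = as.character(id),
                                          reason = reason))
  }
  out <- list()
  seen <- character()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (is.na(rec$text) || !nzchar(trimws(rec$text))) {
      drop(rec$id, "no_text"); next
    }
    if (tolower(trimws(rec$section)) %in% tolower(excluded_sections)) {
      drop(rec$id, "excluded_section"); next
    }
    if (!is.null(journal_allowlist) &&
        (!"journal" %in% names(rec) || !rec$journal %in% journal_allowlist)) {
      drop(rec$id, "not_allowlisted"); next
    }
    if (!(rec$english_confidence > min_english_confidence)) {
      drop(rec$id, "low_english"); next
    }
    text <- dehyphenate(rec$text)
    pieces <- if (nchar(text) < max_paragraph_chars) text else
      split_sentences(text)
    for (j in seq_along(pieces)) {
      key <- normalize_for_dedup(pieces[j])
      if (key %in% seen) {
        drop(rec$id, "duplicate"); next
      }
      seen <- c(seen, key)
      id <- if (length(pieces) > 1L) paste0(rec$id, ".", j) else
        as.character(rec$id)
      out[[length(out) + 1L]] <- annotated_sentence(
        id = id, text = pieces[j], section = rec$section,
        english_confidence = rec$english_confidence)
    }
  }
  list(sentences = out, dropped = dropped)
}

#' Reference whitespace tokenizer
#'
#' Deterministic tokenizer used for BIO encoding and span evaluation: text is
#' split on whitespace and leading/trailing punctuation characters are
#' detached as separate single-character tokens. Offsets are 0-based,
#' half-open, and token slices reconstruct the original text.
#'
#' @param text Character scalar.
#' @return `data.frame` with columns `text`, `start`, `end`; zero rows for
#'   empty input.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(text = character(), start = integer(), end = integer())
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[^[:space:]]+", text)[[1]]
  if (m[1] == -1L) return(empty)
  toks <- list()
  push <- function(s, e) { # 0-based half-open
    toks[[length(toks) + 1L]] <<- c(s, e)
  }
  for (i in seq_along(m)) {
    s <- as.integer(m[i]) - 1L                       # 0-based start
    e <- s + attr(m, "match.length")[i]              # 0-based end (exclusive)
    chunk <- substr(text, s + 1L, e)
    # peel leading punctuation
    while (nchar(chunk) > 1L && grepl("^[[:punct:]]", chunk)) {
      push(s, s + 1L)
      s <- s + 1L
      chunk <- substr(text, s + 1L, e)
    }
    # peel trailing punctuation (collect, emit after the core)
    tail_ <- integer()
    while (nchar(chunk) > 1L && grepl("[[:punct:]]$", chunk)) {
      tail_ <- c(e - 1L, tail_)
      e <- e - 1L
      chunk <- substr(text, s + 1L, e)
    }
    push(s, e)
    for (ts in tail_) push(ts, ts + 1L)
  }
  starts <- vapply(toks, `[`, numeric(1), 1L)
  ends <- vapply(toks, `[`, numeric(1), 2L)
  data.frame(text = substring(text, starts + 1L, ends),
             start = as.integer(starts), end = as.integer(ends))
}

#' BIO-encode one entity category of a sentence
#'
#' Per-token Begin/Inside/Outside labels for the spans of one category: the
#' first token overlapping a span is `B`, subsequent overlapping tokens are
#' `I`, all others `O`.
#'
#' @param sentence An [annotated_sentence()].
#' @param category One of [entity_categories()].
#' @param tokens Optional tokenization (as returned by [tokenize()]); the
#'   reference tokenizer is used when omitted.
#' @return Character vector of labels `B`/`I`/`O`, one per token.
#' @export
bio_encode <- function(sentence, category, tokens = NULL) {
  stopifnot(inherits(sentence, "annotated_sentence"),
            category %in% entity_categories())
  if (is.null(tokens)) tokens <- tokenize(sentence$text)
  labels <- rep("O", nrow(tokens))
  spans <- sentence$spans[sentence$spans$category == category, , drop = FALSE]
  if (!nrow(spans)) return(labels)
  spans <- spans[order(spans$start), , drop = FALSE]
  if (nrow(spans) > 1L && any(spans$start[-1L] < spans$end[-nrow(spans)])) {
    stop("overlapping ", category, " spans in sentence ", sentence$id,
         " (annotation defect)")
  }
  for (k in seq_len(nrow(spans))) {
    ov <- which(tokens$start < spans$end[k] & tokens$end > spans$start[k])
    if (!length(ov)) next
    labels[ov[1L]] <- "B"
    if (length(ov) > 1L) labels[ov[-1L]] <- "I"
  }
  labels
}

#' Reconstruct spans from a BIO label sequence
#'
#' Inverse of [bio_encode()] on non-overlapping span sets: each maximal
#' `B`/`I` run becomes one span covering its tokens.
#'
#' @param tokens Tokenization as returned by [tokenize()].
#' @param labels Character vector of `B`/`I`/`O`, one per token.
#' @return `data.frame` with 0-based half-open `start`, `end` columns.
#' @export
bio_decode <- function(tokens, labels) {
  stopifnot(nrow(tokens) == length(labels))
  inside <- labels %in% c("B", "I")
  runs <- rle(inside)
  idx <- cumsum(c(1L, runs$lengths))
  out <- data.frame(start = integer(), end = integer())
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    first <- idx[r]; last <- idx[r + 1L] - 1L
    # a fresh B inside a run starts a new span
    b_at <- first + which(labels[first:last] == "B") - 1L
    if (!length(b_at) || b_at[1L] != first) b_at <- c(first, b_at)
    bounds <- c(b_at, last + 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      out <- rbind(out, data.frame(start = tokens$start[bounds[k]],
                                   end = tokens$end[bounds[k + 1L] - 1L]))
    }
  }
  out
}

#' Stratified three-way split
#'
#' Partitions sentences into training/evaluation/test subsets with the same
#' per-stratum proportions, deterministically under a seed. Subset sizes
#' within each stratum use largest-remainder rounding (floors first, leftover
#' items to the largest fractional remainders, ties to the earlier subset).
#' Strata smaller than 3 items are pooled into one fallback stratum.
#'
#' @param sentences List of [annotated_sentence()] objects.
#' @param fractions Ordered numeric triple summing to 1, e.g.
#'   `c(0.65, 0.175, 0.175)` for NER or `c(0.6, 0.2, 0.2)` for relations.
#' @param seed Integer seed; the same seed always yields the same partition.
#' @param strata Optional character vector of stratum keys, one per sentence.
#'   Default: the multi-hot entity-presence signature of each sentence.
#' @return List with elements `train`, `eval`, `test` (integer index vectors
#'   into `sentences`, disjoint and exhaustive).
#' @export
stratified_split <- function(sentences, fractions = c(0.65, 0.175, 0.175),
                             seed = 1L, strata = NULL) {
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-9, length(sentences) >= 3L)
  n <- length(sentences)
  if (is.null(strata)) {
    strata <- vapply(sentences, function(s) {
      paste(as.integer(entity_categories() %in% s$spans$category),
            collapse = "")
    }, character(1))
  }
  stopifnot(length(strata) == n)
  tab <- table(strata)
  small <- names(tab)[tab < 3L]
  if (length(small)) {
    message("pooling ", length(small), " strata with <3 items")
    strata[strata %in% small] <- ".pooled"
  }
  rng <- local_rng(seed)
  parts <- list(integer(), integer(), integer())
  for (key in sort(unique(strata))) {
    idx <- which(strata == key)
    idx <- idx[rng$sample_idx(length(idx))]
    sizes <- largest_remainder(length(idx), fractions)
    cuts <- cumsum(c(0L, sizes))
    for (p in 1:3) {
      parts[[p]] <- c(parts[[p]], idx[seq_len(sizes[p]) + cuts[p]])
    }
  }
  list(train = sort(parts[[1]]), eval = sort(parts[[2]]),
       test = sort(parts[[3]]))
}

# Hamilton/largest-remainder apportionment of n items to fractions.
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  sizes <- floor(exact)
  rem <- exact - sizes
  left <- n - sum(sizes)
  if (left > 0) {
    give <- order(-rem, seq_along(rem))[seq_len(left)]
    sizes[give] <- sizes[give] + 1L
  }
  as.integer(sizes)
}

#' Plan class-imbalance augmentation
#'
#' Number of synthetic positive sentences to add for one entity category or
#' relation type: for NER, the full positive/negative gap
#' `max(0, n_neg - n_pos)`; for RE, one-fifth of the gap, rounded up,
#' `ceiling(0.2 * (n_neg - n_pos))` when the gap is positive.
#'
#' @param n_pos,n_neg Non-negative counts of positive and negative sentences.
#' @param mode `"NER"` or `"RE"`.
#' @param target Label of the entity category or relation type (metadata).
#' @param seed Integer seed carried into the plan.
#' @return An `augmentation_plan` list with `n_aug` and the inputs.
#' @export
plan_augmentation <- function(n_pos, n_neg, mode = c("NER", "RE"),
                              target = NA_character_, seed = 1L) {
  mode <- match.arg(mode)
  if (n_pos < 0 || n_neg < 0) stop("counts must be non-negative")
  gap <- n_neg - n_pos
  n_aug <- if (mode == "NER") max(0L, gap) else
    if (gap > 0) ceiling(0.2 * gap) else 0L
  structure(list(target = target, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), mode = mode,
                 n_aug = as.integer(n_aug), seed = as.integer(seed)),
            class = "augmentation_plan")
}

#' Generate synthetic positives by swapping strain terms
#'
#' Creates `plan$n_aug` synthetic sentences by sampling eligible sentences
#' (those containing at least one `STRAIN` span) and replacing each `STRAIN`
#' span's text with a randomly drawn catalog term, leaving the rest of the
#' sentence unchanged. All span offsets, including downstream non-strain
#' spans, are recomputed; relation annotations are carried over.
#'
#' @param sentences List of [annotated_sentence()] objects.
#' @param catalog_terms Character vector of curated strain names to draw
#'   replacements from.
#' @param plan An `augmentation_plan` from [plan_augmentation()].
#' @return List of synthetic [annotated_sentence()] objects of length
#'   `plan$n_aug` (ids suffixed `_augK`).
#' @export
augment_by_strain_swap <- function(sentences, catalog_terms, plan) {
  stopifnot(inherits(plan, "augmentation_plan"))
  if (plan$n_aug == 0L) return(list())
  if (!length(catalog_terms)) stop("empty catalog")
  eligible <- which(vapply(sentences, function(s)
    any(s$spans$category == "STRAIN"), logical(1)))
  if (!length(eligible)) stop("no eligible sentence with a STRAIN span")
  rng <- local_rng(plan$seed)
  out <- vector("list", plan$n_aug)
  for (k in seq_len(plan$n_aug)) {
    s <- sentences[[eligible[rng$draw_int(length(eligible))]]]
    spans <- s$spans[order(s$spans$start), , drop = FALSE]
    text <- s$text
    shift <- 0L
    new_spans <- spans
    ord <- order(spans$start)
    for (i in ord) {
      st <- spans$start[i] + shift
      en <- spans$end[i] + shift
      if (spans$category[i] == "STRAIN") {
        repl <- catalog_terms[rng$draw_int(length(catalog_terms))]
        text <- paste0(substr(text, 1L, st),
                       repl,
                       substr(text, en + 1L, nchar(text)))
        delta <- nchar(repl) - (en - st)
        new_spans$start[i] <- st
        new_spans$end[i] <- st + nchar(repl)
        shift <- shift + delta
      } else {
        new_spans$start[i] <- st
        new_spans$end[i] <- en
      }
    }
    out[[k]] <- annotated_sentence(
      id = paste0(s$id, "_aug", k), text = text, section = s$section,
      english_confidence = s$english_confidence,
      spans = new_spans, relations = s$relations)
  }
  out
}
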