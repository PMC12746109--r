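# File interfaces: JSONL sentence/annotation/prediction records and TSV
# relation records. One JSON object per line; character offsets 0-based,
# half-open throughout.

#' Read a JSONL file
#'
#' @param path File with one JSON object per line.
#' @return List of parsed records.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

#' Write records to a JSONL file
#'
#' @param records List of records (each serialisable by
#'   [jsonlite::toJSON()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Read raw sentence records (JSONL) into a data frame
#'
#' Expected fields per record: `id`, `text`, `section`, `journal`
#' (optional), `english_confidence`.
#'
#' @param path JSONL file path.
#' @return `data.frame` ready for [filter_corpus()].
#' @export
read_sentence_records <- function(path) {
  recs <- read_jsonl(path)
  data.frame(
    id = vapply(recs, function(r) as.character(r$id %||% NA), character(1)),
    text = vapply(recs, function(r) as.character(r$text %||% NA),
                  character(1)),
    section = vapply(recs, function(r) as.character(r$section %||% "body"),
                     character(1)),
    journal = vapply(recs, function(r) as.character(r$journal %||% NA),
                     character(1)),
    english_confidence = vapply(recs, function(r)
      as.numeric(r$english_confidence %||% 1), numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an annotated corpus as paired JSONL files
#'
#' Sentences go to `<stem>.sentences.jsonl` (`id`, `text`, `section`,
#' `english_confidence`); annotations to `<stem>.annotations.jsonl`
#' (`sentence_id`, `spans`, `relations`).
#'
#' @param sentences List of [annotated_sentence()] objects.
#' @param stem Output path stem.
#' @return Invisibly, the two paths.
#' @export
write_corpus <- function(sentences, stem) {
  sent_recs <- lapply(sentences, function(s)
    list(id = s$id, text = s$text, section = s$section,
         english_confidence = s$english_confidence))
  ann_recs <- lapply(sentences, function(s) {
    list(sentence_id = s$id,
         spans = s$spans[, c("category", "start", "end"), drop = FALSE],
         relations = s$relations)
  })
  p1 <- paste0(stem, ".sentences.jsonl")
  p2 <- paste0(stem, ".annotations.jsonl")
  write_jsonl(sent_recs, p1)
  write_jsonl(ann_recs, p2)
  invisible(c(p1, p2))
}

#' Read an annotated corpus written by [write_corpus()]
#'
#' @param stem Path stem used by [write_corpus()].
#' @return List of [annotated_sentence()] objects.
#' @export
read_corpus <- function(stem) {
  sents <- read_jsonl(paste0(stem, ".sentences.jsonl"))
  anns <- read_jsonl(paste0(stem, ".annotations.jsonl"))
  ann_by_id <- setNames(anns, vapply(anns, function(a)
    as.character(a$sentence_id), character(1)))
  lapply(sents, function(s) {
    a <- ann_by_id[[as.character(s$id)]]
    spans <- if (!is.null(a) && length(a$spans)) as.data.frame(a$spans) else
      NULL
    rels <- if (!is.null(a) && length(a$relations))
      as.data.frame(a$relations) else NULL
    annotated_sentence(s$id, s$text, s$section %||% "body",
                       s$english_confidence %||% 1, spans, rels)
  })
}

#' Read relation records from TSV
#'
#' @param path TSV with columns `sentence_id`, `source_term`,
#'   `source_category`, `target_term`, `target_category`, `relation_type`,
#'   `score`.
#' @return `data.frame` of relation records.
#' @export
read_relation_records <- function(path) {
  read.delim(path, colClasses = c(score = "numeric"))
}

#' Write relation records to TSV
#'
#' @param records Relation record `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_relation_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
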