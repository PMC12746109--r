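# Benchmark predicted phenotypes against a curated reference snapshot
# (BacDive-like TSV) by exact genome-accession matching, scoring accuracy
# against conflicting phenotypes.

#' Default conflict table for common phenotype patterns
#'
#' Symmetric pattern pairs that contradict each other (Gram stain, oxygen
#' requirement, shape, motility, temperature preference). User-supplied
#' tables follow the same two-column layout.
#'
#' @return `data.frame` with `pattern`, `conflict_pattern`.
#' @export
default_conflicts <- function() {
  data.frame(
    pattern = c("gram negative", "aerobic", "anaerobic", "rod", "motile",
                "thermophilic", "spore"),
    conflict_pattern = c("gram positive", "anaerobic", "aerobic", "cocci",
                         "non motile", "psychrophilic", "non spore"))
}

# symmetric closure of a conflict table
symmetrize_conflicts <- function(conflicts) {
  conflicts <- as.data.frame(conflicts)
  rbind(conflicts,
        data.frame(pattern = conflicts$conflict_pattern,
                   conflict_pattern = conflicts$pattern))
}

matches_pattern <- function(terms, pattern) {
  any(grepl(pattern, terms, fixed = TRUE))
}

#' Benchmark predictions against a curated phenotype reference
#'
#' For each reference phenotype, strains (matched by exact genome accession)
#' are scored: *concordant* when any predicted term contains the searched
#' pattern (case-insensitive substring, so truncated patterns like
#' `"anaerob"` act as prefixes), *conflicting* when no predicted term
#' matches but one matches a conflict pattern. Strains matching neither are
#' excluded from the denominator. Accuracy is
#' `concordant / (concordant + conflicting)`.
#'
#' Phenotypes with no conflict entry are scored on overlap only (denominator
#' = strains with any prediction) and flagged.
#'
#' @param predictions `data.frame` with `accession`, `term` (predicted
#'   phenotype terms per genome accession).
#' @param reference `data.frame` with `accession`, `category`, `value`
#'   (curated reference snapshot).
#' @param patterns `data.frame` with `reference_value`, `searched_pattern`
#'   (which reference phenotypes to score, and the substring searched in
#'   predicted terms).
#' @param conflicts `data.frame` with `pattern`, `conflict_pattern`
#'   (treated symmetrically); default [default_conflicts()].
#' @return `data.frame` with `reference_phenotype`, `searched_pattern`,
#'   `accuracy`, `n` (strains scored), `category`, `overlap_only` flag.
#'   Rows with `n == 0` are dropped.
#' @export
match_predictions <- function(predictions, reference, patterns,
                              conflicts = default_conflicts()) {
  predictions <- as.data.frame(predictions)
  reference <- as.data.frame(reference)
  patterns <- as.data.frame(patterns)
  stopifnot(all(c("accession", "term") %in% names(predictions)),
            all(c("accession", "category", "value") %in% names(reference)),
            all(c("reference_value", "searched_pattern") %in%
                  names(patterns)))
  conflicts <- symmetrize_conflicts(conflicts)
  conflicts$pattern <- tolower(conflicts$pattern)
  conflicts$conflict_pattern <- tolower(conflicts$conflict_pattern)
  pred_terms <- split(tolower(predictions$term), predictions$accession)
  rows <- list()
  for (k in seq_len(nrow(patterns))) {
    ref_val <- patterns$reference_value[k]
    pat <- tolower(patterns$searched_pattern[k])
    ref_rows <- reference[reference$value == ref_val, , drop = FALSE]
    if (!nrow(ref_rows)) next
    conf_pats <- conflicts$conflict_pattern[conflicts$pattern == pat]
    overlap_only <- !length(conf_pats)
    concordant <- 0L; conflicting <- 0L; with_pred <- 0L
    for (acc in unique(ref_rows$accession)) {
      terms <- pred_terms[[acc]]
      if (is.null(terms)) next
      with_pred <- with_pred + 1L
      if (matches_pattern(terms, pat)) {
        concordant <- concordant + 1L
      } else if (!overlap_only &&
                 any(vapply(conf_pats, function(cp)
                   matches_pattern(terms, cp), logical(1)))) {
        conflicting <- conflicting + 1L
      }
    }
    n <- if (overlap_only) with_pred else concordant + conflicting
    if (n == 0L) next
    if (overlap_only) {
      warning("no conflict entry for pattern '", pat,
              "'; scored on overlap only")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      reference_phenotype = ref_val, searched_pattern = pat,
      accuracy = concordant / n, n = n,
      category = ref_rows$category[1L], overlap_only = overlap_only)
  }
  if (!length(rows)) {
    return(data.frame(reference_phenotype = character(),
                      searched_pattern = character(), accuracy = numeric(),
                      n = integer(), category = character(),
                      overlap_only = logical()))
  }
  do.call(rbind, rows)
}
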