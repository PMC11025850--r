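# Vocabulary handling: a toy OMOP-style standard-vocabulary bundle, term
# normalisation, direct and fuzzy matching, frequency-threshold term
# selection and record-coverage statistics.

#' Normalise a free-text clinical term
#'
#' Lowercases, replaces punctuation with spaces, collapses runs of
#' whitespace and trims.  Idempotent: `normalise_term(normalise_term(x))`
#' equals `normalise_term(x)`.  Empty input yields empty output.
#'
#' @param x character vector of raw terms.
#' @return character vector of normalised terms.
#' @export
#' @examples
#' normalise_term("Amoxycillin  500mg, CAP")  # "amoxycillin 500mg cap"
normalise_term <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Strip a trailing pack-size token from a normalised drug term
#'
#' Medication strings in primary-care EMRs are typically
#' "brand + strength + form + pack size"; the pack size harms text
#' matching against drug vocabularies, so it is removed before lookup.
#' Removed patterns, anchored at the end of the string: `"x N"`,
#' `"N pack"`, or a final bare integer following a form word
#' (cap/tab/ml and friends).  Strength tokens carrying a unit
#' (500mg, 10ml, 100iu/ml) are never touched.
#'
#' @param x character vector of normalised drug terms.
#' @return character vector with pack sizes removed.
#' @export
#' @examples
#' strip_pack_size("amoxycillin 500mg cap 20")     # "amoxycillin 500mg cap"
#' strip_pack_size("insulin 100iu ml 10ml x 5")    # "insulin 100iu ml 10ml"
#' strip_pack_size("metformin 850mg")              # unchanged
strip_pack_size <- function(x) {
  # "x N" or "N pack" at the end is always a pack count
  x <- sub(" x \\d+$", "", x)
  x <- sub(" \\d+ pack$", "", x)
  # a final bare integer is a pack count only after a form word or a
  # unit-bearing token; a lone "drug 850mg" style strength is protected
  # because the digits are attached to their unit
  x <- sub("(?<=[a-z]) (\\d+)$", "", x, perl = TRUE)
  x
}

#' Load an OMOP-style vocabulary bundle
#'
#' Reads a CONCEPT table (columns `concept_id`, `concept_name`,
#' `domain_id`, `vocabulary_id`, `standard_concept`) and an optional
#' ingredient-relationship table (`concept_id`, `ingredient_concept_id`)
#' linking multi-ingredient drug concepts to their ingredients.
#'
#' @param concept_csv path to the concept CSV.
#' @param ingredient_csv optional path to the ingredient-relationship CSV.
#' @return an object of class `omop_vocabulary`.
#' @export
read_vocabulary <- function(concept_csv, ingredient_csv = NULL) {
  con <- read_csv_raw(concept_csv)
  need <- c("concept_id", "concept_name", "domain_id", "vocabulary_id",
            "standard_concept")
  if (!all(need %in% names(con)))
    stopf("concept table missing columns: %s",
          paste(setdiff(need, names(con)), collapse = ", "))
  con$concept_id <- as.integer(con$concept_id)
  ing <- if (!is.null(ingredient_csv) && file.exists(ingredient_csv)) {
    x <- read_csv_raw(ingredient_csv)
    x$concept_id <- as.integer(x$concept_id)
    x$ingredient_concept_id <- as.integer(x$ingredient_concept_id)
    x
  } else {
    data.frame(concept_id = integer(), ingredient_concept_id = integer())
  }
  new_vocabulary(con, ing)
}

new_vocabulary <- function(concept, ingredient) {
  stopifnot(!anyDuplicated(concept$concept_id))
  concept$name_norm <- normalise_term(concept$concept_name)
  concept$standard <- concept$standard_concept %in% c("S", "TRUE", "true")
  structure(list(concept = concept, ingredient = ingredient),
            class = "omop_vocabulary")
}

#' @export
print.omop_vocabulary <- function(x, ...) {
  cat(sprintf("<omop_vocabulary> %d concepts (%d standard), %d ingredient links\n",
              nrow(x$concept), sum(x$concept$standard), nrow(x$ingredient)))
  print(table(x$concept$domain_id))
  invisible(x)
}

#' Write a vocabulary bundle to CSV files
#' @param vocab an `omop_vocabulary`.
#' @param dir output directory; `CONCEPT.csv` and `CONCEPT_INGREDIENT.csv`
#'   are written inside it.
#' @return the directory, invisibly.
#' @export
write_vocabulary <- function(vocab, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- vocab$concept[c("concept_id", "concept_name", "domain_id",
                         "vocabulary_id", "standard_concept")]
  write_csv_plain(con, file.path(dir, "CONCEPT.csv"))
  write_csv_plain(vocab$ingredient, file.path(dir, "CONCEPT_INGREDIENT.csv"))
  invisible(dir)
}

#' Exact lookup of a normalised term against concept names
#'
#' Matches `term_norm` against normalised concept names.  Standard
#' concepts are preferred over non-standard; ties break to the lowest
#' `concept_id` so the result is deterministic.
#'
#' @param term_norm a single normalised term.
#' @param vocab an `omop_vocabulary`.
#' @return one row of the concept table, or `NULL` when nothing matches.
#' @export
direct_match <- function(term_norm, vocab) {
  hits <- vocab$concept[vocab$concept$name_norm == term_norm, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[order(-hits$standard, hits$concept_id), , drop = FALSE]
  hits[1L, ]
}

# Similarity between two normalised terms in [0, 1]: a blend of
# character-level normalised Levenshtein similarity (robust to
# misspellings) and token-set overlap (robust to token reordering).
# Exact matches score exactly 1.
term_similarity <- function(term, names_norm) {
  if (length(names_norm) == 0L) return(numeric(0))
  dmat <- utils::adist(term, names_norm)[1L, ]
  maxlen <- pmax(nchar(term), nchar(names_norm), 1L)
  char_sim <- 1 - dmat / maxlen
  tok_a <- strsplit(term, " ", fixed = TRUE)[[1]]
  tok_sim <- vapply(strsplit(names_norm, " ", fixed = TRUE), function(tb) {
    u <- union(tok_a, tb)
    if (length(u) == 0L) return(1)
    length(intersect(tok_a, tb)) / length(u)
  }, numeric(1))
  sim <- 0.7 * char_sim + 0.3 * tok_sim
  sim[names_norm == term] <- 1
  sim
}

#' Rank candidate concepts for a term
#'
#' Review support for manual mapping: returns the `k` most similar
#' concepts with similarity scores in `[0, 1]`.  Exact name matches score
#' 1.0.  Ordering is deterministic: score descending, then `concept_id`
#' ascending.
#'
#' @param term_norm a single normalised term.
#' @param vocab an `omop_vocabulary`.
#' @param k maximum number of candidates (>= 1).
#' @return data.frame of candidate concept rows with a `score` column.
#' @export
suggest_candidates <- function(term_norm, vocab, k = 5) {
  stopifnot(k >= 1)
  con <- vocab$concept
  if (nrow(con) == 0L)
    return(cbind(con, score = numeric(0)))
  score <- term_similarity(term_norm, con$name_norm)
  ord <- order(-score, con$concept_id)
  out <- con[ord[seq_len(min(k, nrow(con)))], , drop = FALSE]
  out$score <- score[ord[seq_len(nrow(out))]]
  rownames(out) <- NULL
  out
}

#' Select terms for the mapping review queue by frequency threshold
#'
#' Free-text EMRs carry far too many distinct terms to map by hand, but
#' term frequency is heavily skewed, so mapping only terms at or above a
#' per-table frequency threshold covers most records.  The threshold is
#' inclusive ("n times or more").
#'
#' @param freqs data.frame with columns `term_norm` and `frequency`
#'   (one row per distinct term).
#' @param threshold minimum record frequency (>= 1), inclusive.
#' @return the qualifying rows, sorted by frequency descending then term
#'   ascending.
#' @export
select_terms_for_mapping <- function(freqs, threshold) {
  stopifnot(threshold >= 1)
  sel <- freqs[freqs$frequency >= threshold, , drop = FALSE]
  sel <- sel[order(-sel$frequency, sel$term_norm), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Largest frequency threshold achieving a target record coverage
#'
#' Returns the largest threshold `t` such that terms with frequency `>= t`
#' jointly account for at least `target_fraction` of all records; returns
#' 1 when even mapping every term is needed.
#'
#' @param freqs data.frame with columns `term_norm` and `frequency`.
#' @param target_fraction fraction of records to cover, in `(0, 1]`.
#' @return integer threshold.
#' @export
threshold_for_target_coverage <- function(freqs, target_fraction) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  if (nrow(freqs) == 0L) stopf("empty frequency list")
  total <- sum(freqs$frequency)
  if (total < 1) stopf("no records behind the frequency list")
  f <- sort(freqs$frequency, decreasing = TRUE)
  cum <- cumsum(f)
  # candidate thresholds are the distinct frequencies; coverage of
  # "map all terms with frequency >= t" is non-increasing in t
  cand <- unique(f)
  for (t in cand) {
    if (cum[max(which(f >= t))] / total >= target_fraction) return(as.integer(t))
  }
  1L
}

#' Build mapping entries for a term-frequency table
#'
#' Emulates the frequency-threshold mapping workflow: terms at or above
#' `threshold` enter the review queue; each is first tried by direct text
#' match against the vocabulary (`matched_auto`); failing that, the best
#' fuzzy candidate at or above `fuzzy_cutoff` stands in for a human
#' mapper's decision (`mapped_manual`); otherwise the term stays
#' `unmapped`.  Terms below the threshold are retained as `unmapped` so
#' no record is ever dropped.
#'
#' @param freqs data.frame with columns `term_norm`, `frequency` (and
#'   optionally `source_table`).
#' @param vocab an `omop_vocabulary`.
#' @param threshold inclusive frequency threshold.
#' @param fuzzy_cutoff minimum similarity for an automatic manual-style
#'   assignment; set to `Inf` to disable fuzzy assignment.
#' @param strip_pack whether to strip pack sizes before matching (used
#'   for medication tables).
#' @return data.frame of mapping entries: `term_norm`, `concept_ids`
#'   (semicolon-separated), `status`, `frequency`.
#' @export
map_terms <- function(freqs, vocab, threshold, fuzzy_cutoff = 0.85,
                      strip_pack = FALSE) {
  queue <- select_terms_for_mapping(freqs, threshold)
  below <- freqs[!(freqs$term_norm %in% queue$term_norm), , drop = FALSE]
  map_one <- function(term) {
    lookup <- if (strip_pack) strip_pack_size(term) else term
    hit <- direct_match(lookup, vocab)
    if (!is.null(hit))
      return(list(ids = hit$concept_id, status = "matched_auto"))
    if (is.finite(fuzzy_cutoff)) {
      cand <- suggest_candidates(lookup, vocab, k = 1)
      if (nrow(cand) == 1L && cand$score >= fuzzy_cutoff)
        return(list(ids = cand$concept_id, status = "mapped_manual"))
    }
    list(ids = integer(0), status = "unmapped")
  }
  res <- lapply(queue$term_norm, map_one)
  entries <- data.frame(
    term_norm = c(queue$term_norm, below$term_norm),
    concept_ids = c(vapply(res, function(r) paste(r$ids, collapse = ";"),
                           character(1)),
                    rep("", nrow(below))),
    status = c(vapply(res, function(r) r$status, character(1)),
               rep("unmapped", nrow(below))),
    frequency = c(queue$frequency, below$frequency),
    stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  entries
}

#' Record-level coverage of a mapping
#'
#' How many source records carry a term whose mapping status is anything
#' other than `unmapped`.  Percentages are rounded half-up to one
#' decimal, each independently, so mapped and unmapped percentages can
#' differ from 100 by up to 0.1.
#'
#' @param mapping data.frame of mapping entries (`term_norm`, `status`).
#' @param freqs data.frame with `term_norm` and `frequency`; every
#'   mapping term must appear here at most once.
#' @return an object of class `coverage_report`.
#' @export
record_coverage <- function(mapping, freqs) {
  if (anyDuplicated(freqs$term_norm))
    stopf("duplicate terms in frequency table")
  unknown <- setdiff(mapping$term_norm, freqs$term_norm)
  if (length(unknown) > 0L)
    stopf("mapping references unknown term(s): %s",
          paste(utils::head(unknown, 3), collapse = ", "))
  total <- sum(freqs$frequency)
  mapped_terms <- mapping$term_norm[mapping$status != "unmapped"]
  mapped <- sum(freqs$frequency[freqs$term_norm %in% mapped_terms])
  unmapped <- total - mapped
  structure(list(
    total_records = total,
    mapped_records = mapped,
    unmapped_records = unmapped,
    pct_mapped = if (total > 0) pct_of(mapped, total) else 0.0,
    pct_unmapped = if (total > 0) pct_of(unmapped, total) else 0.0,
    n_terms_total = nrow(freqs),
    n_terms_mapped = length(unique(mapped_terms))
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "<coverage_report> %s of %s records mapped (%.1f%%); %s unmapped (%.1f%%)\n",
    format(x$mapped_records, big.mark = ","),
    format(x$total_records, big.mark = ","), x$pct_mapped,
    format(x$unmapped_records, big.mark = ","), x$pct_unmapped))
  cat(sprintf("  terms: %d mapped of %d distinct\n",
              x$n_terms_mapped, x$n_terms_total))
  invisible(x)
}

#' Expand a drug concept into its ingredient concepts
#'
#' Combination medicines cannot carry a single ingredient-level drug
#' code; they are represented by one code per constituent ingredient.
#' Looks the term up in the vocabulary and follows ingredient links
#' transitively.  A single-ingredient drug returns itself resolved to
#' one ingredient (or itself when it has no link and is itself an
#' ingredient-domain concept).
#'
#' @param term_norm a normalised drug term (matched directly), or an
#'   integer concept id.
#' @param vocab an `omop_vocabulary`.
#' @return list with `concept_ids` (integer vector, possibly empty) and
#'   `status` (`"ok"` or `"flagged"` when no ingredient data exists).
#' @export
split_ingredients <- function(term_norm, vocab) {
  id <- if (is.numeric(term_norm)) {
    as.integer(term_norm)
  } else {
    hit <- direct_match(term_norm, vocab)
    if (is.null(hit)) return(list(concept_ids = integer(0), status = "flagged"))
    hit$concept_id
  }
  ing <- vocab$ingredient
  seen <- integer(0)
  frontier <- id
  leaves <- integer(0)
  while (length(frontier) > 0L) {
    cur <- frontier[1L]
    frontier <- frontier[-1L]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    kids <- ing$ingredient_concept_id[ing$concept_id == cur]
    if (length(kids) == 0L) leaves <- c(leaves, cur)
    else frontier <- c(frontier, kids)
  }
  leaves <- sort(unique(leaves))
  if (identical(leaves, id)) {
    # no links at all: acceptable only if the concept is ingredient-like
    row <- vocab$concept[vocab$concept$concept_id == id, , drop = FALSE]
    if (nrow(row) == 1L && row$domain_id == "Drug" &&
        !id %in% ing$concept_id && id %in% ing$ingredient_concept_id)
      return(list(concept_ids = id, status = "ok"))
    if (nrow(row) == 1L && !id %in% ing$concept_id &&
        nrow(ing) > 0L && !id %in% ing$ingredient_concept_id)
      return(list(concept_ids = integer(0), status = "flagged"))
  }
  list(concept_ids = leaves, status = "ok")
}

#' Read / write mapping interchange CSV
#'
#' Columns: `term`, `frequency`, `concept_ids` (semicolon-separated),
#' `status`.  `write_mapping_csv` followed by `read_mapping_csv` is the
#' identity on valid entries.  Rows violating the status/concept
#' invariant (`unmapped` iff no concept ids) are rejected with the row
#' number.
#'
#' @param path CSV file path.
#' @return data.frame of mapping entries (as produced by [map_terms()]).
#' @export
read_mapping_csv <- function(path) {
  df <- read_csv_raw(path)
  need <- c("term", "frequency", "concept_ids", "status")
  if (!all(need %in% names(df)))
    stopf("mapping file missing columns: %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  valid_status <- c("matched_auto", "mapped_manual", "unmapped", "flagged")
  for (i in seq_len(nrow(df))) {
    st <- df$status[i]
    has_ids <- nzchar(trimws(df$concept_ids[i]))
    if (!st %in% valid_status)
      stopf("row %d: unknown status '%s'", i, st)
    if ((st == "unmapped") == has_ids)
      stopf("row %d: status '%s' inconsistent with concept_ids '%s'",
            i, st, df$concept_ids[i])
    if (is.na(suppressWarnings(as.integer(df$frequency[i]))))
      stopf("row %d: non-integer frequency '%s'", i, df$frequency[i])
  }
  data.frame(term_norm = df$term,
             concept_ids = df$concept_ids,
             status = df$status,
             frequency = as.integer(df$frequency),
             stringsAsFactors = FALSE)
}

#' @rdname read_mapping_csv
#' @param entries data.frame of mapping entries.
#' @export
write_mapping_csv <- function(entries, path) {
  out <- data.frame(term = entries$term_norm,
                    frequency = entries$frequency,
                    concept_ids = entries$concept_ids,
                    status = entries$status)
  write_csv_plain(out, path)
}

#' Distinct-term frequencies from staging records
#'
#' Counts, per logical source table, how many records carry each
#' normalised term.  Medication terms are counted on the pack-stripped
#' form so the mapping operates on match-ready text.
#'
#' @param records staging records data.frame (columns `source_table`,
#'   `term_text`).
#' @param strip_pack_tables source tables whose terms get pack-size
#'   stripping (default `"medications"`).
#' @return data.frame with `source_table`, `term_norm`, `frequency`,
#'   sorted by table then frequency descending then term.
#' @export
term_frequencies <- function(records, strip_pack_tables = "medications") {
  tn <- normalise_term(records$term_text)
  strip <- records$source_table %in% strip_pack_tables
  tn[strip] <- strip_pack_size(tn[strip])
  agg <- stats::aggregate(list(frequency = tn),
                          by = list(source_table = records$source_table,
                                    term_norm = tn),
                          FUN = length)
  agg <- agg[order(agg$source_table, -agg$frequency, agg$term_norm), ]
  rownames(agg) <- NULL
  agg
}
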