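# Kahn-framework data-quality engine over the CDM subset: declarative
# checks in {plausibility, conformance, completeness} x {verification,
# validation}, strict-exceed threshold semantics, and a category-by-
# context summary table.

.categories <- c("plausibility", "conformance", "completeness")
.contexts <- c("verification", "validation")

#' Define a data-quality check
#'
#' A check counts rows of one CDM table violating a predicate and fails
#' when the violation percentage strictly exceeds `threshold_pct`.
#' Built-in predicate kinds:
#' \describe{
#'   \item{range}{`field` numeric within `params$min`..`params$max`
#'     (inclusive); `NA` counts as violating when `params$required`.}
#'   \item{date_max}{`field` date on or before `params$max_date`.}
#'   \item{date_after_birth}{event year of `field` at or after the
#'     person's `year_of_birth`.}
#'   \item{fk_person}{`person_id` present in PERSON.}
#'   \item{value_in}{`field` value among `params$allowed`.}
#'   \item{concept_known}{`field` concept id is 0 or present in the
#'     vocabulary bundle (`params$concept_ids`).}
#'   \item{non_null}{`field` present and non-empty.}
#'   \item{person_has_row}{denominator is persons; a person violates
#'     when they have no row in `table`.}
#'   \item{share_in}{validation: the share of rows with `field` in
#'     `params$values` lies within `params$min_share`..`params$max_share`;
#'     violation is all-or-nothing on the table.}
#'   \item{rows_per_person}{validation: mean rows per person within
#'     `params$min`..`params$max`; all-or-nothing.}
#' }
#'
#' @param check_id unique identifier.
#' @param category one of plausibility, conformance, completeness.
#' @param context verification (internal consistency) or validation
#'   (against external expectations).
#' @param table CDM table name.
#' @param predicate_kind one of the built-ins above.
#' @param field column examined (when applicable).
#' @param params named list of predicate parameters.
#' @param threshold_pct maximum tolerated violation percentage.
#' @return an object of class `check_definition`.
#' @export
check_definition <- function(check_id, category, context, table,
                             predicate_kind, field = NULL,
                             params = list(), threshold_pct = 0) {
  stopifnot(category %in% .categories, context %in% .contexts,
            threshold_pct >= 0, threshold_pct <= 100)
  kinds <- c("range", "date_max", "date_after_birth", "fk_person",
             "value_in", "concept_known", "non_null", "person_has_row",
             "share_in", "rows_per_person")
  if (!predicate_kind %in% kinds)
    stopf("unknown predicate kind: %s", predicate_kind)
  structure(list(check_id = check_id, category = category,
                 context = context, table = table, field = field,
                 predicate_kind = predicate_kind, params = params,
                 threshold_pct = threshold_pct),
            class = "check_definition")
}

#' Run one quality check against a CDM
#'
#' Status semantics: `FAIL` iff the violation percentage strictly
#' exceeds the threshold; a violation rate exactly at the threshold
#' passes.  An empty denominator yields `NOT_APPLICABLE`, as does a
#' missing column (with a warning).
#'
#' @param cdm named list of CDM data.frames.
#' @param def a [check_definition()].
#' @return one-row data.frame: `check_id`, `category`, `context`,
#'   `table`, `denominator`, `violating`, `pct_violated`,
#'   `threshold_pct`, `status`.
#' @export
run_check <- function(cdm, def) {
  stopifnot(inherits(def, "check_definition"))
  tab <- cdm[[def$table]]
  if (is.null(tab)) stopf("CDM table not found: %s", def$table)
  need_field <- !def$predicate_kind %in% c("fk_person", "person_has_row",
                                           "rows_per_person")
  if (need_field && (is.null(def$field) || !def$field %in% names(tab))) {
    warning(sprintf("check %s: column %s missing in %s; not applicable",
                    def$check_id, def$field %||% "<unset>", def$table),
            call. = FALSE)
    return(check_row(def, 0L, 0L))
  }
  p <- def$params
  counts <- switch(def$predicate_kind,
    range = {
      v <- suppressWarnings(as.numeric(tab[[def$field]]))
      bad <- (!is.na(v) & (v < p$min | v > p$max)) |
             (is.na(v) & isTRUE(p$required))
      c(nrow(tab), sum(bad))
    },
    date_max = {
      v <- as.Date(tab[[def$field]])
      c(nrow(tab), sum(!is.na(v) & v > as.Date(p$max_date)))
    },
    date_after_birth = {
      person <- cdm$PERSON
      yob <- person$year_of_birth[match(tab$person_id, person$person_id)]
      yr <- as.integer(format(as.Date(tab[[def$field]]), "%Y"))
      c(nrow(tab), sum(!is.na(yr) & !is.na(yob) & yr < yob))
    },
    fk_person = {
      c(nrow(tab), sum(!tab$person_id %in% cdm$PERSON$person_id))
    },
    value_in = {
      c(nrow(tab), sum(!tab[[def$field]] %in% p$allowed))
    },
    concept_known = {
      v <- tab[[def$field]]
      c(nrow(tab), sum(!(v == 0L | v %in% p$concept_ids)))
    },
    non_null = {
      v <- tab[[def$field]]
      c(nrow(tab), sum(is.na(v) | (is.character(v) & !nzchar(v))))
    },
    person_has_row = {
      persons <- cdm$PERSON$person_id
      c(length(persons), sum(!persons %in% tab$person_id))
    },
    share_in = {
      n <- nrow(tab)
      if (n == 0L) c(0L, 0L) else {
        share <- sum(tab[[def$field]] %in% p$values) / n
        ok <- share >= p$min_share && share <= p$max_share
        c(n, if (ok) 0L else n)
      }
    },
    rows_per_person = {
      np <- nrow(cdm$PERSON)
      if (np == 0L) c(0L, 0L) else {
        rpp <- nrow(tab) / np
        ok <- rpp >= p$min && rpp <= p$max
        c(np, if (ok) 0L else np)
      }
    },
    stopf("unknown predicate kind: %s", def$predicate_kind))
  check_row(def, counts[1], counts[2])
}

check_row <- function(def, denominator, violating) {
  pct <- if (denominator == 0) NA_real_ else 100 * violating / denominator
  status <- if (denominator == 0) "NOT_APPLICABLE"
            else if (pct > def$threshold_pct) "FAIL" else "PASS"
  data.frame(check_id = def$check_id, category = def$category,
             context = def$context, table = def$table,
             denominator = as.integer(denominator),
             violating = as.integer(violating),
             pct_violated = pct, threshold_pct = def$threshold_pct,
             status = status)
}

#' The built-in check suite
#'
#' Verification checks over plausibility (believable values: birth year
#' after the 1900 sentinel and not in the future, events not before
#' birth or after the reference date, measurement values in a plausible
#' range), conformance (person foreign keys, standard gender concept
#' ids, concept ids known to the vocabulary, required columns non-null)
#' and completeness (persons with at least one row per event table;
#' field non-null fractions).  Validation checks compare observed
#' category shares to externally supplied expectation ranges and are
#' only generated when `expectations` is given; none run by default.
#'
#' @param as_of reference date for temporal plausibility.
#' @param vocab optional `omop_vocabulary` enabling the concept-known
#'   conformance checks.
#' @param thresholds named numeric vector of per-check threshold
#'   overrides (`check_id` = percentage).
#' @param expectations optional list of validation expectations, e.g.
#'   `list(female_share = c(0.45, 0.60), records_per_person =
#'   list(table = "DRUG_EXPOSURE", min = 0.5, max = 50))`.
#' @return list of [check_definition()] objects.
#' @export
builtin_checks <- function(as_of, vocab = NULL, thresholds = NULL,
                           expectations = NULL) {
  as_of <- as.Date(as_of)
  yr <- as.integer(format(as_of, "%Y"))
  defs <- list(
    check_definition("plaus_birth_year_range", "plausibility",
                     "verification", "PERSON", "range",
                     field = "year_of_birth",
                     params = list(min = 1901, max = yr, required = TRUE)),
    check_definition("plaus_measurement_value", "plausibility",
                     "verification", "MEASUREMENT", "range",
                     field = "value_as_number",
                     params = list(min = 0, max = 1000, required = FALSE)))
  event_specs <- list(
    CONDITION_OCCURRENCE = "condition_start_date",
    OBSERVATION = "observation_date",
    MEASUREMENT = "measurement_date",
    PROCEDURE_OCCURRENCE = "procedure_date",
    DRUG_EXPOSURE = "drug_exposure_start_date",
    DEVICE_EXPOSURE = "device_exposure_start_date")
  for (t in names(event_specs)) {
    dc <- event_specs[[t]]
    defs <- c(defs, list(
      check_definition(paste0("plaus_future_date_", tolower(t)),
                       "plausibility", "verification", t, "date_max",
                       field = dc, params = list(max_date = as_of)),
      check_definition(paste0("plaus_before_birth_", tolower(t)),
                       "plausibility", "verification", t,
                       "date_after_birth", field = dc),
      check_definition(paste0("conf_fk_person_", tolower(t)),
                       "conformance", "verification", t, "fk_person"),
      check_definition(paste0("conf_date_nonnull_", tolower(t)),
                       "conformance", "verification", t, "non_null",
                       field = dc)))
  }
  defs <- c(defs, list(
    check_definition("conf_gender_concept", "conformance", "verification",
                     "PERSON", "value_in", field = "gender_concept_id",
                     params = list(allowed = c(8532L, 8507L, 0L))),
    check_definition("comp_person_gender_recorded", "completeness",
                     "verification", "PERSON", "value_in",
                     field = "gender_concept_id",
                     params = list(allowed = c(8532L, 8507L)))))
  if (!is.null(vocab)) {
    known <- vocab$concept$concept_id
    for (t in names(event_specs)) {
      cc <- .cdm_concept_col[[t]]
      defs <- c(defs, list(
        check_definition(paste0("conf_concept_known_", tolower(t)),
                         "conformance", "verification", t, "concept_known",
                         field = cc, params = list(concept_ids = known))))
    }
  }
  for (t in c("CONDITION_OCCURRENCE", "DRUG_EXPOSURE", "OBSERVATION",
              "MEASUREMENT")) {
    defs <- c(defs, list(
      check_definition(paste0("comp_person_has_", tolower(t)),
                       "completeness", "verification", t,
                       "person_has_row")))
  }
  if (!is.null(expectations)) {
    if (!is.null(expectations$female_share)) {
      rng <- expectations$female_share
      defs <- c(defs, list(
        check_definition("val_gender_share_female", "plausibility",
                         "validation", "PERSON", "share_in",
                         field = "gender_concept_id",
                         params = list(values = 8532L,
                                       min_share = rng[1],
                                       max_share = rng[2]))))
    }
    if (!is.null(expectations$records_per_person)) {
      rp <- expectations$records_per_person
      defs <- c(defs, list(
        check_definition("val_records_per_person", "completeness",
                         "validation", rp$table, "rows_per_person",
                         params = list(min = rp$min, max = rp$max))))
    }
  }
  if (!is.null(thresholds)) {
    for (i in seq_along(defs)) {
      id <- defs[[i]]$check_id
      if (id %in% names(thresholds))
        defs[[i]]$threshold_pct <- unname(thresholds[[id]])
    }
  }
  defs
}

#' Run a list of checks
#' @param cdm named list of CDM data.frames.
#' @param defs list of [check_definition()] objects.
#' @return data.frame of one [run_check()] row per definition.
#' @export
run_quality <- function(cdm, defs) {
  out <- do.call(rbind, lapply(defs, function(d) run_check(cdm, d)))
  rownames(out) <- NULL
  out
}

#' Summarise check results by Kahn category and context
#'
#' Counts passes and failures per (category, context) cell, with
#' verification/validation/total column groups and a grand-total row.
#' `NOT_APPLICABLE` results are excluded from all totals (counting an
#' empty table as a pass would inflate quality).  Pass percentages are
#' rounded half-up to integer.
#'
#' @param results data.frame from [run_quality()] (columns `category`,
#'   `context`, `status`).
#' @return an object of class `quality_summary`: data.frame with one
#'   row per category plus `Total`, columns `<context>_{pass,fail,total,pct}`
#'   and `total_{pass,fail,total,pct}`.
#' @export
summarise_quality <- function(results) {
  res <- results[results$status != "NOT_APPLICABLE", , drop = FALSE]
  cell <- function(cat, ctx) {
    sel <- res
    if (cat != "Total") sel <- sel[sel$category == cat, , drop = FALSE]
    if (ctx != "total") sel <- sel[sel$context == ctx, , drop = FALSE]
    n_pass <- sum(sel$status == "PASS")
    n_fail <- sum(sel$status == "FAIL")
    n_tot <- n_pass + n_fail
    c(pass = n_pass, fail = n_fail, total = n_tot,
      pct = if (n_tot == 0) NA_real_
            else round_half_up(100 * n_pass / n_tot))
  }
  rows <- c(.categories, "Total")
  out <- data.frame(category = rows)
  for (ctx in c(.contexts, "total")) {
    m <- t(vapply(rows, cell, numeric(4), ctx = ctx))
    out[[paste0(ctx, "_pass")]] <- as.integer(m[, "pass"])
    out[[paste0(ctx, "_fail")]] <- as.integer(m[, "fail"])
    out[[paste0(ctx, "_total")]] <- as.integer(m[, "total"])
    out[[paste0(ctx, "_pct")]] <- m[, "pct"]
  }
  rownames(out) <- NULL
  structure(out, class = c("quality_summary", "data.frame"))
}

#' @export
print.quality_summary <- function(x, ...) {
  cat("Data-quality summary (pass/fail by Kahn category)\n")
  fmt <- function(p, f, t, pct)
    sprintf("%5d %5d %5d %s", p, f, t,
            ifelse(is.na(pct), "  -", sprintf("%3.0f%%", pct)))
  cat(sprintf("%-13s %23s   %23s   %23s\n", "", "verification",
              "validation", "total"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-13s %s   %s   %s\n", x$category[i],
        fmt(x$verification_pass[i], x$verification_fail[i],
            x$verification_total[i], x$verification_pct[i]),
        fmt(x$validation_pass[i], x$validation_fail[i],
            x$validation_total[i], x$validation_pct[i]),
        fmt(x$total_pass[i], x$total_fail[i], x$total_total[i],
            x$total_pct[i])))
  }
  invisible(x)
}

#' Render quality results as report artifacts
#'
#' Writes `dq_results.json` (full machine-readable results and raw
#' ratios), `dq_results.csv` (one row per check) and `dq_summary.md`
#' (a markdown table with one row per Kahn category plus a Total row,
#' column groups verification / validation / total).
#'
#' @param summary a [summarise_quality()] result.
#' @param results the [run_quality()] data.frame.
#' @param dir output directory.
#' @param formats subset of `c("json", "csv", "markdown")`.
#' @return named vector of written paths, invisibly.
#' @export
render_report <- function(summary, results, dir,
                          formats = c("json", "csv", "markdown")) {
  unknown <- setdiff(formats, c("json", "csv", "markdown"))
  if (length(unknown) > 0L)
    stopf("unknown report format(s): %s", paste(unknown, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if ("json" %in% formats) {
    paths["json"] <- write_json_file(
      list(summary = as.data.frame(summary), results = results),
      file.path(dir, "dq_results.json"))
  }
  if ("csv" %in% formats) {
    paths["csv"] <- write_csv_plain(results, file.path(dir, "dq_results.csv"))
  }
  if ("markdown" %in% formats) {
    md <- c(
      "# Data-quality summary",
      "",
      paste("| Category | Verification pass | Verification fail |",
            "Verification pass % | Validation pass | Validation fail |",
            "Validation pass % | Total pass | Total fail | Total pass % |"),
      "|---|---|---|---|---|---|---|---|---|---|")
    pctf <- function(p) ifelse(is.na(p), "-", sprintf("%d%%", as.integer(p)))
    for (i in seq_len(nrow(summary))) {
      md <- c(md, sprintf(
        "| %s | %d | %d | %s | %d | %d | %s | %d | %d | %s |",
        summary$category[i], summary$verification_pass[i],
        summary$verification_fail[i], pctf(summary$verification_pct[i]),
        summary$validation_pass[i], summary$validation_fail[i],
        pctf(summary$validation_pct[i]), summary$total_pass[i],
        summary$total_fail[i], pctf(summary$total_pct[i])))
    }
    path <- file.path(dir, "dq_summary.md")
    writeLines(md, path)
    paths["markdown"] <- path
  }
  invisible(paths)
}

#' Gender share of a person table or of printed category counts
#'
#' Reports the percentage of each gender category over all persons with
#' a demographic record, rounded half-up to one decimal, as published
#' demographic tables render them.
#'
#' @param x either a named numeric vector of category counts, or a CDM
#'   PERSON data.frame (categories derived from `gender_concept_id`:
#'   8532 female, 8507 male, otherwise not recorded).
#' @return data.frame with `category`, `count`, `pct`.
#' @export
gender_share <- function(x) {
  counts <- if (is.data.frame(x)) {
    cat <- ifelse(x$gender_concept_id == 8532L, "female",
           ifelse(x$gender_concept_id == 8507L, "male", "not_recorded"))
    tab <- table(cat)
    stats::setNames(as.numeric(tab), names(tab))
  } else {
    x
  }
  total <- sum(counts)
  data.frame(category = names(counts),
             count = as.numeric(counts),
             pct = pct_of(as.numeric(counts), total))
}
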