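# ETL into the OMOP CDM v5.4 subset: active-patient filtering, concept
# resolution against the mapping, dated/undated routing, ingredient
# splitting for combination drugs, and a row-conservation log.

#' Active-patient rule
#'
#' A patient is active when they have at least `min_visits` visits
#' within any `window_days`-day period, or at least one visit within
#' `recent_days` of the reference date `as_of`.  Both clauses use
#' inclusive day arithmetic ("2 years" = 730 days) and visits strictly
#' after `as_of` are ignored.  The defaults encode the practice-activity
#' convention used in Australian general practice (3 visits in any
#' 2-year period) extended by a recency clause that keeps new patients
#' with a single recent visit.
#'
#' @param as_of reference date.
#' @param min_visits minimum visits for the window clause (>= 1).
#' @param window_days window width in days (>= 1).
#' @param recent_days recency horizon in days.
#' @return an object of class `active_rule`.
#' @export
active_rule <- function(as_of, min_visits = 3L, window_days = 730L,
                        recent_days = 730L) {
  as_of <- as.Date(as_of)
  stopifnot(!is.na(as_of), min_visits >= 1, window_days >= 1,
            recent_days >= 0)
  structure(list(as_of = as_of, min_visits = as.integer(min_visits),
                 window_days = as.integer(window_days),
                 recent_days = as.integer(recent_days)),
            class = "active_rule")
}

#' @export
print.active_rule <- function(x, ...) {
  cat(sprintf(
    "<active_rule> >=%d visits within %d days, or >=1 visit within %d days of %s\n",
    x$min_visits, x$window_days, x$recent_days, format(x$as_of)))
  invisible(x)
}

#' Test whether a visit history marks an active patient
#'
#' Sorted-window implementation: after discarding missing and
#' future-dated visits, the window clause holds iff some run of
#' `min_visits` consecutive sorted visit dates spans at most
#' `window_days` days; the recency clause holds iff the latest visit is
#' within `recent_days` of `as_of`.  An empty history is inactive.
#'
#' @param visit_dates Date vector (may contain `NA`).
#' @param rule an [active_rule()].
#' @return single logical.
#' @export
is_active <- function(visit_dates, rule) {
  stopifnot(inherits(rule, "active_rule"))
  d <- as.Date(visit_dates)
  d <- d[!is.na(d) & d <= rule$as_of]
  if (length(d) == 0L) return(FALSE)
  d <- sort(as.numeric(d))
  k <- rule$min_visits
  if (length(d) >= k) {
    span <- d[seq.int(k, length(d))] - d[seq.int(1L, length(d) - k + 1L)]
    if (any(span <= rule$window_days)) return(TRUE)
  }
  as.numeric(rule$as_of) - d[length(d)] <= rule$recent_days
}

#' Compute the active patient key set
#'
#' @param staging an `omop_staging` (or anything with `patients` and
#'   `visits` frames keyed by `patient_key`).
#' @param rule an [active_rule()].
#' @return character vector of active patient keys, sorted.
#' @export
filter_active <- function(staging, rule) {
  visits <- staging$visits
  by_pat <- split(visits$visit_date, visits$patient_key)
  keys <- staging$patients$patient_key
  act <- vapply(keys, function(k) {
    v <- by_pat[[k]]
    if (is.null(v)) FALSE else is_active(v, rule)
  }, logical(1), USE.NAMES = FALSE)
  sort(keys[act])
}

# default domain when a term is unmapped, by source table
.default_domain <- c(reason_for_visit = "Condition", history = "Condition",
                     medications = "Drug", immunisations = "Drug",
                     allergic_reactions = "Observation",
                     tests = "Measurement")

#' Resolve a staged term to concept ids and a domain
#'
#' Looks the normalised (and, for medications, pack-stripped) term up in
#' the mapping table.  Mapped terms yield their concept id(s) and the
#' concept's domain from the vocabulary; combination-drug terms yield
#' one id per ingredient.  Unmapped terms yield concept id 0 with a
#' domain defaulted by source table, and the source value is preserved
#' verbatim so no record is lost.
#'
#' @param source_table logical source table of the record.
#' @param term_text raw term text.
#' @param mapping mapping entries data.frame (from [map_terms()] or
#'   [read_mapping_csv()]).
#' @param vocab an `omop_vocabulary`.
#' @return list with `concept_ids` (integer vector; 0 when unmapped) and
#'   `domain_id`.
#' @export
resolve_concept <- function(source_table, term_text, mapping, vocab) {
  tn <- normalise_term(term_text)
  if (source_table == "medications") tn <- strip_pack_size(tn)
  row <- mapping[mapping$term_norm == tn, , drop = FALSE]
  ids <- if (nrow(row) >= 1L && row$status[1L] != "unmapped" &&
             nzchar(row$concept_ids[1L]))
    as.integer(strsplit(row$concept_ids[1L], ";", fixed = TRUE)[[1]])
  else integer(0)
  if (length(ids) == 0L)
    return(list(concept_ids = 0L,
                domain_id = unname(.default_domain[source_table])))
  con <- vocab$concept
  domain <- con$domain_id[match(ids[1L], con$concept_id)]
  if (is.na(domain)) domain <- unname(.default_domain[source_table])
  if (domain == "Drug") {
    split <- split_ingredients(ids[1L], vocab)
    if (length(split$concept_ids) > 0L) ids <- split$concept_ids
  }
  list(concept_ids = ids, domain_id = domain)
}

#' Route a resolved record to its CDM target table(s)
#'
#' Routing rules: reason-for-visit and history records in the Condition
#' domain become CONDITION_OCCURRENCE when dated and OBSERVATION when
#' undated (an undated condition is treated as a past observation, not a
#' current condition); history records can also carry Measurement,
#' Procedure or Device content; medications go to DRUG_EXPOSURE (Device
#' content to DEVICE_EXPOSURE); immunisations are written to both
#' PROCEDURE_OCCURRENCE and DRUG_EXPOSURE; allergic reactions are always
#' stored as observations; tests carry Measurement, Procedure or Device
#' content.  Every record routes to exactly one table, except
#' immunisations which route to two.
#'
#' @param source_table logical source table.
#' @param domain_id resolved domain.
#' @param has_date whether the record carries an event date.
#' @return character vector of CDM table names.
#' @export
route <- function(source_table, domain_id, has_date) {
  if (!source_table %in% .source_tables)
    stopf("unknown source table: %s", source_table)
  cond_route <- function() {
    if (domain_id == "Condition")
      return(if (has_date) "CONDITION_OCCURRENCE" else "OBSERVATION")
    switch(domain_id,
           Measurement = "MEASUREMENT",
           Procedure = "PROCEDURE_OCCURRENCE",
           Device = "DEVICE_EXPOSURE",
           "OBSERVATION")
  }
  switch(source_table,
    reason_for_visit = ,
    history = cond_route(),
    medications = if (domain_id == "Device") "DEVICE_EXPOSURE"
                  else "DRUG_EXPOSURE",
    immunisations = c("PROCEDURE_OCCURRENCE", "DRUG_EXPOSURE"),
    allergic_reactions = "OBSERVATION",
    tests = switch(domain_id,
                   Procedure = "PROCEDURE_OCCURRENCE",
                   Device = "DEVICE_EXPOSURE",
                   "MEASUREMENT"))
}

# CDM column layouts (v5.4 names, subset)
.cdm_columns <- list(
  PERSON = c("person_id", "gender_concept_id", "year_of_birth",
             "person_source_value", "gender_source_value"),
  VISIT_OCCURRENCE = c("visit_occurrence_id", "person_id",
                       "visit_concept_id", "visit_start_date",
                       "visit_end_date", "visit_type_concept_id"),
  CONDITION_OCCURRENCE = c("condition_occurrence_id", "person_id",
                           "condition_concept_id", "condition_start_date",
                           "condition_type_concept_id",
                           "condition_source_value"),
  OBSERVATION = c("observation_id", "person_id", "observation_concept_id",
                  "observation_date", "observation_type_concept_id",
                  "observation_source_value"),
  MEASUREMENT = c("measurement_id", "person_id", "measurement_concept_id",
                  "measurement_date", "measurement_type_concept_id",
                  "value_as_number", "unit_source_value",
                  "measurement_source_value"),
  PROCEDURE_OCCURRENCE = c("procedure_occurrence_id", "person_id",
                           "procedure_concept_id", "procedure_date",
                           "procedure_type_concept_id",
                           "procedure_source_value"),
  DRUG_EXPOSURE = c("drug_exposure_id", "person_id", "drug_concept_id",
                    "drug_exposure_start_date", "drug_type_concept_id",
                    "drug_source_value"),
  DEVICE_EXPOSURE = c("device_exposure_id", "person_id",
                      "device_concept_id", "device_exposure_start_date",
                      "device_type_concept_id", "device_source_value"),
  CDM_SOURCE = c("cdm_source_name", "cdm_source_abbreviation",
                 "cdm_holder", "source_release_date", "cdm_release_date",
                 "cdm_version", "vocabulary_version"))

.cdm_date_col <- c(CONDITION_OCCURRENCE = "condition_start_date",
                   OBSERVATION = "observation_date",
                   MEASUREMENT = "measurement_date",
                   PROCEDURE_OCCURRENCE = "procedure_date",
                   DRUG_EXPOSURE = "drug_exposure_start_date",
                   DEVICE_EXPOSURE = "device_exposure_start_date")

.cdm_concept_col <- c(CONDITION_OCCURRENCE = "condition_concept_id",
                      OBSERVATION = "observation_concept_id",
                      MEASUREMENT = "measurement_concept_id",
                      PROCEDURE_OCCURRENCE = "procedure_concept_id",
                      DRUG_EXPOSURE = "drug_concept_id",
                      DEVICE_EXPOSURE = "device_concept_id")

.cdm_source_col <- c(CONDITION_OCCURRENCE = "condition_source_value",
                     OBSERVATION = "observation_source_value",
                     MEASUREMENT = "measurement_source_value",
                     PROCEDURE_OCCURRENCE = "procedure_source_value",
                     DRUG_EXPOSURE = "drug_source_value",
                     DEVICE_EXPOSURE = "device_source_value")

#' Build the OMOP CDM subset from staging tables
#'
#' Applies the active-patient filter, resolves every staged term against
#' the mapping, routes records to their CDM tables and assembles the CDM
#' with a conservation log.  Only active patients' records are written.
#' PERSON keeps the recorded birth year (1900 sentinels are deliberately
#' not corrected: the quality stage measures them) and the standard
#' gender concept ids (female 8532, male 8507, otherwise 0).  Undated
#' records routed to OBSERVATION receive the patient's most recent visit
#' date on or before `as_of` (else `as_of` itself) as observation date;
#' each such default is logged by row reference.  Events whose patient
#' is not in staging are dropped with reason `orphan`; events of
#' inactive patients with reason `inactive`.  The build is a pure
#' function of its inputs: rerunning yields an identical CDM.
#'
#' @param staging an `omop_staging`.
#' @param mapping mapping entries data.frame.
#' @param vocab an `omop_vocabulary`.
#' @param rule an [active_rule()].
#' @return list with `cdm` (named list of data.frames) and `log`
#'   (per-source-table conservation counts plus defaulted-date refs).
#' @export
build_cdm <- function(staging, mapping, vocab, rule) {
  stopifnot(inherits(staging, "omop_staging"), inherits(rule, "active_rule"))
  active <- filter_active(staging, rule)
  pats <- staging$patients[order(staging$patients$patient_key), , drop = FALSE]
  pats <- pats[pats$patient_key %in% active, , drop = FALSE]
  person_id <- stats::setNames(seq_len(nrow(pats)), pats$patient_key)
  person <- data.frame(
    person_id = unname(person_id),
    gender_concept_id = ifelse(
      pats$gender_source %in% names(.gender_concepts),
      .gender_concepts[pats$gender_source], 0L),
    year_of_birth = pats$birth_year,
    person_source_value = pats$patient_key,
    gender_source_value = pats$gender_source)
  rownames(person) <- NULL

  vis <- staging$visits[staging$visits$patient_key %in% active, ,
                        drop = FALSE]
  vis <- vis[order(vis$patient_key, vis$visit_date, vis$row_ref), ,
             drop = FALSE]
  visit_occ <- data.frame(
    visit_occurrence_id = seq_len(nrow(vis)),
    person_id = unname(person_id[vis$patient_key]) %||% integer(0),
    visit_concept_id = rep(9202L, nrow(vis)),       # outpatient visit
    visit_start_date = vis$visit_date,
    visit_end_date = vis$visit_date,
    visit_type_concept_id = rep(32827L, nrow(vis))) # EHR encounter record

  # latest on-or-before-as_of visit per patient, for undated observations
  vv <- vis[!is.na(vis$visit_date) & vis$visit_date <= rule$as_of, ]
  last_visit <- tapply(as.numeric(vv$visit_date), vv$patient_key, max)

  rec <- staging$records
  # resolve once per distinct (source_table, normalised term)
  tn <- normalise_term(rec$term_text)
  med <- rec$source_table == "medications"
  tn[med] <- strip_pack_size(tn[med])
  key <- paste(rec$source_table, tn, sep = "\x1f")
  ukeys <- unique(key)
  resolved <- lapply(ukeys, function(k) {
    parts <- strsplit(k, "\x1f", fixed = TRUE)[[1]]
    term <- if (length(parts) > 1L) parts[2L] else ""
    resolve_concept_norm(parts[1L], term, mapping, vocab)
  })
  ridx <- match(key, ukeys)
  dom <- vapply(resolved, `[[`, character(1), "domain_id")[ridx]
  ids_list <- lapply(resolved, `[[`, "concept_ids")[ridx]

  known <- rec$patient_key %in% staging$patients$patient_key
  is_act <- rec$patient_key %in% active
  keep <- known & is_act
  has_date <- !is.na(rec$event_date)

  # defaulted observation dates for undated kept rows
  lv <- unname(last_visit[match(rec$patient_key, names(last_visit))])
  fill_date <- as.Date(ifelse(is.na(lv), as.numeric(rule$as_of), lv),
                       origin = "1970-01-01")
  use_date <- rec$event_date
  use_date[is.na(use_date)] <- fill_date[is.na(use_date)]
  defaulted <- sort(unique(rec$row_ref[keep & !has_date]))

  targets <- mapply(route, rec$source_table, dom, has_date,
                    SIMPLIFY = FALSE, USE.NAMES = FALSE)
  log <- list()
  cdm <- list(PERSON = person, VISIT_OCCURRENCE = visit_occ)
  emitted <- stats::setNames(
    lapply(.cdm_event_tables[-1L], function(t) integer(0)),
    .cdm_event_tables[-1L])
  event_dfs <- list()
  for (tgt in .cdm_event_tables[-1L]) {
    goes <- keep & vapply(targets, function(t) tgt %in% t, logical(1))
    sel <- which(goes)
    if (tgt == "DRUG_EXPOSURE") {
      times <- lengths(ids_list[sel])
      ri <- rep(sel, times)
      cid <- as.integer(unlist(ids_list[sel], use.names = FALSE))
    } else {
      ri <- sel
      cid <- vapply(ids_list[sel], `[[`, integer(1), 1L)
    }
    df <- data.frame(person_id = unname(person_id[rec$patient_key[ri]]),
                     concept_id = if (length(ri)) cid else integer(0),
                     event_date = use_date[ri],
                     source_value = rec$term_text[ri],
                     value_as_number = rec$numeric_value[ri],
                     unit_source_value = rec$units[ri],
                     row_ref = rec$row_ref[ri])
    event_dfs[[tgt]] <- df
    cnt <- table(rec$source_table[ri])
    emitted[[tgt]] <- stats::setNames(as.integer(cnt), names(cnt))
  }
  for (tab in .source_tables) {
    in_tab <- rec$source_table == tab
    routed <- lapply(emitted, function(e)
      if (tab %in% names(e)) unname(e[[tab]]) else 0L)
    routed <- routed[vapply(routed, function(v) v > 0L, logical(1))]
    log[[tab]] <- list(
      rows_in = sum(in_tab),
      rows_kept = sum(in_tab & keep),
      rows_dropped = c(orphan = sum(in_tab & !known),
                       inactive = sum(in_tab & known & !is_act)),
      rows_routed = routed)
  }
  for (tgt in .cdm_event_tables[-1L]) {
    df <- event_dfs[[tgt]]
    df <- df[order(df$person_id, df$event_date, df$row_ref,
                   df$concept_id), , drop = FALSE]
    out <- data.frame(id = seq_len(nrow(df)), person_id = df$person_id)
    names(out)[1] <- .cdm_columns[[tgt]][1]
    out[[.cdm_concept_col[[tgt]]]] <- df$concept_id
    out[[.cdm_date_col[[tgt]]]] <- df$event_date
    out[[paste0(tolower(sub("_.*", "", tgt)), "_type_concept_id")]] <-
      rep(32817L, nrow(df))
    if (tgt == "MEASUREMENT") {
      out$value_as_number <- df$value_as_number
      out$unit_source_value <- df$unit_source_value
    }
    out[[.cdm_source_col[[tgt]]]] <- df$source_value
    cdm[[tgt]] <- out[, intersect(.cdm_columns[[tgt]], names(out))]
  }
  cdm$CDM_SOURCE <- data.frame(
    cdm_source_name = "omopforge synthetic primary-care CDM",
    cdm_source_abbreviation = "omopforge",
    cdm_holder = "omopforge",
    source_release_date = format(rule$as_of),
    cdm_release_date = format(rule$as_of),
    cdm_version = "5.4",
    vocabulary_version = sprintf(
      "toy bundle; active rule: min_visits=%d window_days=%d recent_days=%d",
      rule$min_visits, rule$window_days, rule$recent_days))
  structure(list(cdm = cdm,
                 log = list(tables = log, defaulted_dates = defaulted,
                            n_active = length(active))),
            class = "omop_cdm_build")
}

# resolve_concept() on an already-normalised term
resolve_concept_norm <- function(source_table, term_norm, mapping, vocab) {
  row <- mapping[mapping$term_norm == term_norm, , drop = FALSE]
  ids <- if (nrow(row) >= 1L && row$status[1L] != "unmapped" &&
             nzchar(row$concept_ids[1L]))
    as.integer(strsplit(row$concept_ids[1L], ";", fixed = TRUE)[[1]])
  else integer(0)
  if (length(ids) == 0L)
    return(list(concept_ids = 0L,
                domain_id = unname(.default_domain[source_table])))
  con <- vocab$concept
  domain <- con$domain_id[match(ids[1L], con$concept_id)]
  if (is.na(domain)) domain <- unname(.default_domain[source_table])
  if (domain == "Drug") {
    split <- split_ingredients(ids[1L], vocab)
    if (length(split$concept_ids) > 0L) ids <- split$concept_ids
  }
  list(concept_ids = ids, domain_id = domain)
}

#' @export
print.omop_cdm_build <- function(x, ...) {
  cat("<omop_cdm_build>\n")
  for (t in names(x$cdm))
    cat(sprintf("  %-22s %6d rows\n", t, nrow(x$cdm[[t]])))
  invisible(x)
}

#' Export CDM tables as CSV files
#'
#' Writes each populated CDM table as `<TABLE>.csv` with CDM v5.4
#' column names, plus `etl_log.json` with the conservation counts.
#'
#' @param build an `omop_cdm_build`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_cdm <- function(build, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in names(build$cdm)) {
    df <- build$cdm[[t]]
    for (col in names(df))
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]])
    write_csv_plain(df, file.path(dir, paste0(t, ".csv")))
  }
  write_json_file(build$log, file.path(dir, "etl_log.json"))
  invisible(dir)
}

#' Read back a CSV-exported CDM
#' @param dir directory written by [write_cdm()].
#' @return named list of data.frames (dates parsed, ids integer).
#' @export
read_cdm <- function(dir) {
  out <- list()
  for (t in .cdm_tables) {
    path <- file.path(dir, paste0(t, ".csv"))
    if (!file.exists(path)) next
    df <- read_csv_raw(path)
    for (col in names(df)) {
      if (grepl("_id$", col)) df[[col]] <- as.integer(df[[col]])
      if (grepl("(_date|date)$", col) && t != "CDM_SOURCE")
        df[[col]] <- as.Date(df[[col]])
      if (col == "value_as_number")
        df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
      if (col == "year_of_birth") df[[col]] <- as.integer(df[[col]])
    }
    out[[t]] <- df
  }
  out
}
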