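# Dialect reading, harmonisation into unified staging tables, and
# hash-based pseudonymisation of patient and practice identifiers.

#' Load the dialect dictionaries
#'
#' Dialect surface forms (file names, column names, date style, gender
#' encodings) are data, not code: they live in a YAML dictionary so a
#' new dialect is a configuration addition.  The packaged dictionary
#' covers the `bp`, `md` and `zedmed` dialects.
#'
#' @param path optional path to a dialect YAML; defaults to the packaged
#'   dictionary.
#' @return named list of dialect specifications.
#' @export
dialect_specs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dialects.yaml",
                                package = "omopforge")
  if (!nzchar(path) || !file.exists(path))
    stopf("dialect dictionary not found")
  yaml::read_yaml(path)
}

dialect_columns <- function(spec, table) {
  cols <- spec$columns$default
  extra <- spec$columns[[table]]
  if (!is.null(extra)) cols[names(extra)] <- extra
  logical_cols <- switch(table,
    patients = c("row_id", "patient_uid", "practice_id", "name",
                 "gender", "dob"),
    visits = c("row_id", "visit_id", "patient_uid", "practice_id",
               "event_date"),
    c("row_id", "patient_uid", "practice_id", "event_date", "term",
      "source_code", "numeric_value", "units"))
  unlist(cols[logical_cols])
}

#' Write logical tables as a dialect-native file set
#'
#' Renders the generator's logical tables into one directory per
#' dialect, applying that dialect's column names, date format and gender
#' encoding.  Rows are routed to a dialect by the practice that owns
#' them.
#'
#' @param tables named list of logical tables (patients, visits and the
#'   six event tables).
#' @param practices data.frame with `practice_id` and `dialect`.
#' @param out_dir parent output directory.
#' @param specs dialect dictionaries (default: packaged).
#' @return named character vector of per-dialect directories.
#' @export
write_dialect_files <- function(tables, practices, out_dir,
                                specs = dialect_specs()) {
  dialects <- intersect(names(specs), unique(practices$dialect))
  dirs <- character(0)
  for (dl in dialects) {
    spec <- specs[[dl]]
    ddir <- file.path(out_dir, dl)
    dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
    prs <- practices$practice_id[practices$dialect == dl]
    for (tab in .logical_tables) {
      df <- tables[[tab]]
      df <- df[df$practice_id %in% prs, , drop = FALSE]
      cols <- dialect_columns(spec, tab)
      out <- data.frame(row.names = seq_len(nrow(df)))
      for (lc in names(cols)) {
        v <- if (lc %in% names(df)) df[[lc]] else rep("", nrow(df))
        if (lc %in% c("event_date", "dob")) {
          v <- format_dialect_date(as.Date(v), spec$date_style)
        } else if (lc == "gender") {
          enc <- unlist(spec$gender)
          v <- ifelse(v %in% names(enc), enc[v], "")
        } else if (lc == "numeric_value") {
          v <- ifelse(is.na(v), "", format(v, trim = TRUE, scientific = FALSE))
        } else {
          v <- as.character(v)
          v[is.na(v)] <- ""
        }
        out[[cols[[lc]]]] <- v
      }
      write_csv_plain(out, file.path(ddir, spec$files[[tab]]))
    }
    dirs[dl] <- ddir
  }
  dirs
}

#' Read one dialect's extract directory
#'
#' Loads every expected file of the dialect, keeping dialect-native
#' column names, and parses the dialect's date columns.  Date strings
#' that are not valid calendar dates (e.g. 31/02/2020) become absent
#' (`NA`) and are counted in the read log rather than failing the run:
#' the undated pathway is a first-class route downstream.
#'
#' @param dir the dialect directory.
#' @param dialect dialect name present in the dictionary.
#' @param specs dialect dictionaries (default: packaged).
#' @return list with `tables` (native-named data.frames, date columns
#'   parsed to `Date`), `dialect` and `log` (per-table row counts and
#'   unparseable-date counts).
#' @export
read_dialect <- function(dir, dialect, specs = dialect_specs()) {
  if (!dialect %in% names(specs)) stopf("unknown dialect: %s", dialect)
  spec <- specs[[dialect]]
  tables <- list()
  log <- list()
  for (tab in .logical_tables) {
    path <- file.path(dir, spec$files[[tab]])
    if (!file.exists(path))
      stopf("missing required file for dialect '%s': %s", dialect,
            spec$files[[tab]])
    df <- read_csv_raw(path)
    cols <- dialect_columns(spec, tab)
    missing_cols <- setdiff(unname(cols), names(df))
    if (length(missing_cols) > 0L)
      stopf("%s: missing column(s) %s", path,
            paste(missing_cols, collapse = ", "))
    bad_dates <- 0L
    for (lc in intersect(c("event_date", "dob"), names(cols))) {
      nc <- cols[[lc]]
      parsed <- parse_dialect_date(df[[nc]], spec$date_style)
      had_text <- nzchar(trimws(df[[nc]]))
      n_bad <- sum(had_text & is.na(parsed))
      if (n_bad > 0L)
        warning(sprintf("%s: %d unparseable date(s) in %s set to absent",
                        basename(path), n_bad, nc), call. = FALSE)
      bad_dates <- bad_dates + n_bad
      df[[nc]] <- parsed
    }
    tables[[tab]] <- df
    log[[tab]] <- list(rows = nrow(df), unparseable_dates = bad_dates)
  }
  list(tables = tables, dialect = dialect, log = log)
}

#' Pseudonymise an identifier
#'
#' Replaces an identifying string with an opaque key: a SHA-256 hash of
#' the salted input truncated to 16 hex characters.  Deterministic for a
#' fixed salt, and practically collision-free at cohort scale.  The salt
#' should include the practice identifier so patient keys are scoped per
#' practice.
#'
#' @param x character vector of identifiers (all non-empty).
#' @param salt non-empty salt string.
#' @return character vector of 16-hex-character keys.
#' @export
pseudonymise <- function(x, salt) {
  salt <- as.character(salt)
  if (length(salt) == 0L || any(is.na(salt) | !nzchar(salt)))
    stopf("salt must be non-empty")
  if (!length(salt) %in% c(1L, length(x)))
    stopf("salt must have length 1 or length(x)")
  x <- as.character(x)
  if (any(is.na(x) | !nzchar(x))) stopf("empty identifier")
  mapply(function(v, s)
    substr(digest::digest(paste0(s, "\x1f", v), algo = "sha256",
                          serialize = FALSE), 1L, 16L),
    x, rep_len(salt, length(x)), USE.NAMES = FALSE)
}

#' Merge dialect extracts into unified staging tables
#'
#' Combines any number of dialect reads into one staging patient table,
#' one staging visit table and one staging record table covering all six
#' logical event tables, with the dialect recorded per row.  Every input
#' row maps to exactly one staging row; nothing is dropped.  Patient and
#' practice identifiers are pseudonymised, with patient keys scoped per
#' practice.  When the same patient key appears more than once with
#' conflicting demographics, the last record read wins and the conflict
#' is logged.  Passing an already-harmonised staging object returns it
#' unchanged.
#'
#' @param raws list of [read_dialect()] results (or a single one).
#' @param salt pseudonymisation salt.
#' @return an object of class `omop_staging`: list of `patients`,
#'   `visits`, `records` data.frames plus a `log`.
#' @export
harmonise <- function(raws, salt = "omopforge") {
  if (inherits(raws, "omop_staging")) return(raws)
  if (!is.null(raws$tables)) raws <- list(raws)
  pat_l <- list(); vis_l <- list(); rec_l <- list()
  log <- list(tables = list(), demographic_conflicts = 0L)
  specs <- dialect_specs()
  for (raw in raws) {
    dl <- raw$dialect
    spec <- specs[[dl]]
    for (tab in .logical_tables) {
      df <- raw$tables[[tab]]
      cols <- dialect_columns(spec, tab)
      lg <- stats::setNames(
        lapply(names(cols), function(lc) df[[cols[[lc]]]]), names(cols))
      n <- nrow(df)
      if (n == 0L) {
        log$tables[[tab]] <- (log$tables[[tab]] %||% 0L)
        next
      }
      pat_key <- pseudonymise(lg$patient_uid,
                              paste0(salt, "|", lg$practice_id))
      pr_key <- pseudonymise(lg$practice_id, salt)
      if (tab == "patients") {
        genc <- unlist(spec$gender)
        rev_map <- stats::setNames(names(genc), genc)
        gsrc <- ifelse(lg$gender %in% names(rev_map),
                       rev_map[lg$gender], "")
        pat_l[[length(pat_l) + 1L]] <- data.frame(
          patient_key = pat_key, gender_source = gsrc,
          birth_year = as.integer(format(lg$dob, "%Y")),
          practice_key = pr_key, dialect = dl,
          row_ref = paste0(dl, ":", lg$row_id))
      } else if (tab == "visits") {
        vis_l[[length(vis_l) + 1L]] <- data.frame(
          patient_key = pat_key, practice_key = pr_key,
          visit_date = lg$event_date, dialect = dl,
          row_ref = paste0(dl, ":", lg$row_id))
      } else {
        rec_l[[length(rec_l) + 1L]] <- data.frame(
          source_table = tab, patient_key = pat_key,
          practice_key = pr_key, event_date = lg$event_date,
          term_text = lg$term, source_code = lg$source_code,
          numeric_value = suppressWarnings(as.numeric(lg$numeric_value)),
          units = lg$units, dialect = dl,
          row_ref = paste0(dl, ":", lg$row_id))
      }
      log$tables[[tab]] <- (log$tables[[tab]] %||% 0L) + n
    }
  }
  bind <- function(l, proto) if (length(l) == 0L) proto else do.call(rbind, l)
  patients <- bind(pat_l, data.frame(
    patient_key = character(), gender_source = character(),
    birth_year = integer(), practice_key = character(),
    dialect = character(), row_ref = character()))
  dup <- duplicated(patients$patient_key, fromLast = TRUE)
  log$demographic_conflicts <- sum(dup)
  patients_dedup <- patients[!dup, , drop = FALSE]
  visits <- bind(vis_l, data.frame(
    patient_key = character(), practice_key = character(),
    visit_date = as.Date(character()), dialect = character(),
    row_ref = character()))
  records <- bind(rec_l, data.frame(
    source_table = character(), patient_key = character(),
    practice_key = character(), event_date = as.Date(character()),
    term_text = character(), source_code = character(),
    numeric_value = numeric(), units = character(),
    dialect = character(), row_ref = character()))
  rownames(patients_dedup) <- rownames(visits) <- rownames(records) <- NULL
  structure(list(patients = patients_dedup, visits = visits,
                 records = records, log = log),
            class = "omop_staging")
}

#' @export
print.omop_staging <- function(x, ...) {
  cat(sprintf("<omop_staging> %d patients, %d visits, %d event records\n",
              nrow(x$patients), nrow(x$visits), nrow(x$records)))
  if (nrow(x$records) > 0)
    print(table(x$records$source_table))
  invisible(x)
}

#' Write a harmonisation log as JSON
#' @param staging an `omop_staging`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_harmonisation_log <- function(staging, path) {
  write_json_file(list(
    tables_in = staging$log$tables,
    patients_out = nrow(staging$patients),
    visits_out = nrow(staging$visits),
    records_out = nrow(staging$records),
    demographic_conflicts = staging$log$demographic_conflicts), path)
}
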