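# End-to-end orchestration: generate -> harmonise -> map -> etl -> dq ->
# report, with per-stage manifests (input/output hashes), structured
# JSON-lines logging and reproducible runs.

.stage_order <- c("generate", "harmonise", "map", "etl", "dq", "report")

#' Pipeline configuration
#'
#' Per-source-table frequency thresholds default to the workflow's
#' operating points: reason-for-visit 50, history 100, medications 200,
#' immunisations 5, allergic reactions 20, tests 300 (all inclusive).
#'
#' @param out_dir working directory for all stage outputs.
#' @param input_dir directory holding per-dialect extracts and the
#'   vocabulary bundle; defaults to `<out_dir>/input` (populated by the
#'   generate stage).
#' @param thresholds named per-table frequency thresholds (>= 1).
#' @param as_of reference date for the active-patient rule and temporal
#'   checks; defaults to the generator's date-range end.
#' @param min_visits,window_days,recent_days active-rule parameters.
#' @param dq_thresholds named per-check threshold overrides (percent).
#' @param expectations validation expectations (see [builtin_checks()]).
#' @param generator a [generator_config()] for the generate stage.
#' @param salt pseudonymisation salt.
#' @param seed integer seed for the generate stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = file.path(out_dir, "input"),
                            thresholds = c(reason_for_visit = 50,
                                           history = 100,
                                           medications = 200,
                                           immunisations = 5,
                                           allergic_reactions = 20,
                                           tests = 300),
                            as_of = NULL,
                            min_visits = 3L, window_days = 730L,
                            recent_days = 730L,
                            dq_thresholds = NULL,
                            expectations = NULL,
                            generator = NULL,
                            salt = "omopforge",
                            seed = 1L) {
  if (any(thresholds < 1)) stopf("frequency thresholds must be >= 1")
  if (!all(names(thresholds) %in% .source_tables))
    stopf("unknown source table(s) in thresholds")
  gen <- generator %||% generator_config(seed = as.integer(seed))
  as_of <- as.Date(as_of %||% gen$date_range[2])
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 thresholds = thresholds, as_of = as_of,
                 min_visits = min_visits, window_days = window_days,
                 recent_days = recent_days,
                 dq_thresholds = dq_thresholds,
                 expectations = expectations,
                 generator = gen, salt = salt,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_line <- function(path, stage, severity, reason, ...) {
  entry <- c(list(stage = stage, severity = severity, reason = reason),
             list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = path, append = TRUE, sep = "")
}

stage_manifest_path <- function(config, stage) {
  file.path(config$out_dir, sprintf("manifest_%s.json", stage))
}

write_stage_manifest <- function(config, stage, outputs) {
  outputs <- outputs[file.exists(outputs)]
  write_json_file(list(
    stage = stage,
    outputs = stats::setNames(lapply(outputs, hash_file),
                              basename(outputs)),
    paths = outputs), stage_manifest_path(config, stage))
}

check_upstream <- function(config, stage, force = FALSE) {
  ups <- switch(stage, generate = character(0),
                harmonise = "generate", map = "harmonise",
                etl = c("harmonise", "map"), dq = "etl", report = "dq")
  for (up in ups) {
    mpath <- stage_manifest_path(config, up)
    if (!file.exists(mpath)) {
      if (up == "generate" && dir.exists(config$input_dir)) next
      stopf("stage '%s' needs outputs of stage '%s'; run it first",
            stage, up)
    }
    m <- read_json_file(mpath)
    for (p in unlist(m$paths)) {
      if (!file.exists(p))
        stopf("stage '%s': upstream output missing: %s", stage, p)
      if (!identical(hash_file(p), m$outputs[[basename(p)]]) && !force)
        stopf("stage '%s': upstream output %s changed since stage '%s' ran; re-run it or use force",
              stage, basename(p), up)
    }
  }
  invisible(TRUE)
}

staging_dir <- function(config) file.path(config$out_dir, "staging")
map_dir <- function(config) file.path(config$out_dir, "map")
cdm_dir <- function(config) file.path(config$out_dir, "cdm")
dq_dir <- function(config) file.path(config$out_dir, "dq")

write_staging <- function(staging, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in c("patients", "visits", "records")) {
    df <- staging[[t]]
    for (col in names(df))
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]])
    write_csv_plain(df, file.path(dir, paste0(t, ".csv")))
  }
  write_harmonisation_log(staging, file.path(dir, "harmonisation_log.json"))
  invisible(dir)
}

read_staging <- function(dir) {
  patients <- read_csv_raw(file.path(dir, "patients.csv"))
  patients$birth_year <- as.integer(patients$birth_year)
  visits <- read_csv_raw(file.path(dir, "visits.csv"))
  visits$visit_date <- as.Date(visits$visit_date)
  records <- read_csv_raw(file.path(dir, "records.csv"))
  records$event_date <- as.Date(records$event_date)
  records$numeric_value <- suppressWarnings(as.numeric(records$numeric_value))
  structure(list(patients = patients, visits = visits, records = records,
                 log = list(tables = list(), demographic_conflicts = 0L)),
            class = "omop_staging")
}

#' Run one pipeline stage
#'
#' Stages consume only the declared outputs of their upstream stages and
#' are individually re-runnable; a stage refuses to run when an upstream
#' output has changed since its manifest was written, unless `force`.
#'
#' @param config a [pipeline_config()].
#' @param stage one of generate, harmonise, map, etl, dq, report.
#' @param force run even when upstream outputs have changed.
#' @return invisibly, the stage's primary result.
#' @export
run_stage <- function(config, stage, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"),
            stage %in% .stage_order)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logp <- file.path(config$out_dir, "pipeline_log.jsonl")
  check_upstream(config, stage, force = force)
  res <- switch(stage,
    generate = {
      gen <- generate_cohort(config$generator, config$input_dir)
      outs <- list.files(config$input_dir, recursive = TRUE,
                         full.names = TRUE)
      write_stage_manifest(config, "generate", outs)
      log_line(logp, "generate", "info", "cohort_generated",
               n_patients = config$generator$n_patients)
      gen
    },
    harmonise = {
      specs <- dialect_specs()
      dls <- intersect(names(specs), list.dirs(config$input_dir,
                                               recursive = FALSE,
                                               full.names = FALSE))
      if (length(dls) == 0L)
        stopf("no dialect directories found under %s", config$input_dir)
      raws <- withCallingHandlers(
        lapply(dls, function(dl)
          read_dialect(file.path(config$input_dir, dl), dl, specs)),
        warning = function(w) {
          log_line(logp, "harmonise", "warning", "unparseable_date",
                   detail = conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      staging <- harmonise(raws, salt = config$salt)
      write_staging(staging, staging_dir(config))
      outs <- list.files(staging_dir(config), full.names = TRUE)
      write_stage_manifest(config, "harmonise", outs)
      log_line(logp, "harmonise", "info", "staged",
               records = nrow(staging$records))
      staging
    },
    map = {
      staging <- read_staging(staging_dir(config))
      vocab <- read_vocabulary(
        file.path(config$input_dir, "vocabulary", "CONCEPT.csv"),
        file.path(config$input_dir, "vocabulary", "CONCEPT_INGREDIENT.csv"))
      freqs <- term_frequencies(staging$records)
      dir.create(map_dir(config), recursive = TRUE, showWarnings = FALSE)
      outs <- character(0)
      for (tab in intersect(.source_tables, unique(freqs$source_table))) {
        tf <- freqs[freqs$source_table == tab, , drop = FALSE]
        thr <- if (tab %in% names(config$thresholds))
          config$thresholds[[tab]] else 1
        entries <- map_terms(tf, vocab, threshold = thr,
                             strip_pack = FALSE)  # terms already stripped
        p <- file.path(map_dir(config), sprintf("mapping_%s.csv", tab))
        write_mapping_csv(entries, p)
        cov <- record_coverage(entries, tf)
        write_json_file(unclass(cov),
                        file.path(map_dir(config),
                                  sprintf("coverage_%s.json", tab)))
        outs <- c(outs, p)
        log_line(logp, "map", "info", "table_mapped", table = tab,
                 threshold = thr, pct_mapped = cov$pct_mapped)
      }
      outs <- c(outs, list.files(map_dir(config), pattern = "coverage_",
                                 full.names = TRUE))
      write_stage_manifest(config, "map", outs)
      read_pipeline_mapping(config)
    },
    etl = {
      staging <- read_staging(staging_dir(config))
      vocab <- read_vocabulary(
        file.path(config$input_dir, "vocabulary", "CONCEPT.csv"),
        file.path(config$input_dir, "vocabulary", "CONCEPT_INGREDIENT.csv"))
      mapping <- read_pipeline_mapping(config)
      rule <- active_rule(config$as_of, config$min_visits,
                          config$window_days, config$recent_days)
      build <- build_cdm(staging, mapping, vocab, rule)
      write_cdm(build, cdm_dir(config))
      outs <- list.files(cdm_dir(config), full.names = TRUE)
      write_stage_manifest(config, "etl", outs)
      for (ref in build$log$defaulted_dates)
        log_line(logp, "etl", "info", "observation_date_defaulted",
                 row_ref = ref)
      log_line(logp, "etl", "info", "cdm_built",
               n_active = build$log$n_active)
      build
    },
    dq = {
      cdm <- read_cdm(cdm_dir(config))
      vocab <- read_vocabulary(
        file.path(config$input_dir, "vocabulary", "CONCEPT.csv"),
        file.path(config$input_dir, "vocabulary", "CONCEPT_INGREDIENT.csv"))
      defs <- builtin_checks(config$as_of, vocab = vocab,
                             thresholds = config$dq_thresholds,
                             expectations = config$expectations)
      results <- run_quality(cdm, defs)
      summary <- summarise_quality(results)
      dir.create(dq_dir(config), recursive = TRUE, showWarnings = FALSE)
      render_report(summary, results, dq_dir(config))
      outs <- list.files(dq_dir(config), full.names = TRUE)
      write_stage_manifest(config, "dq", outs)
      log_line(logp, "dq", "info", "quality_assessed",
               overall_pass_pct = summary$total_pct[nrow(summary)])
      list(results = results, summary = summary)
    },
    report = {
      manifest <- build_run_manifest(config)
      write_json_file(manifest,
                      file.path(config$out_dir, "run_manifest.json"))
      write_stage_manifest(config, "report",
                           file.path(config$out_dir, "run_manifest.json"))
      log_line(logp, "report", "info", "manifest_written")
      manifest
    })
  invisible(res)
}

read_pipeline_mapping <- function(config) {
  files <- list.files(map_dir(config), pattern = "^mapping_.*\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0L)
    stopf("no mapping files under %s; run the map stage first",
          map_dir(config))
  all <- do.call(rbind, lapply(sort(files), read_mapping_csv))
  # one entry per term: a mapped status wins over unmapped; frequencies sum
  ord <- order(all$term_norm, all$status == "unmapped")
  all <- all[ord, , drop = FALSE]
  freq <- tapply(all$frequency, all$term_norm, sum)
  first <- all[!duplicated(all$term_norm), , drop = FALSE]
  first$frequency <- as.integer(freq[first$term_norm])
  rownames(first) <- NULL
  first
}

build_run_manifest <- function(config) {
  hashes <- list()
  for (stage in c("generate", "harmonise", "map", "etl", "dq")) {
    mpath <- stage_manifest_path(config, stage)
    if (file.exists(mpath)) hashes[[stage]] <- read_json_file(mpath)$outputs
  }
  counts <- list()
  hl <- file.path(staging_dir(config), "harmonisation_log.json")
  if (file.exists(hl)) counts$staging <- read_json_file(hl)
  el <- file.path(cdm_dir(config), "etl_log.json")
  if (file.exists(el)) counts$etl <- read_json_file(el)
  list(tool = "omopforge",
       version = as.character(utils::packageVersion("omopforge")),
       seed = config$seed,
       as_of = as.character(config$as_of),
       thresholds = as.list(config$thresholds),
       active_rule = list(min_visits = config$min_visits,
                          window_days = config$window_days,
                          recent_days = config$recent_days),
       row_counts = counts,
       output_hashes = hashes)
}

#' Run the pipeline end to end
#'
#' Executes the stages in order (optionally skipping generation when the
#' input directory is already populated) and writes a run manifest of
#' versions, seed, row counts and output hashes.  Identical config and
#' seed give identical manifest hashes.
#'
#' @param config a [pipeline_config()].
#' @param stages stages to run, in pipeline order.
#' @param force pass through to [run_stage()].
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config, stages = .stage_order, force = FALSE) {
  stages <- .stage_order[.stage_order %in% stages]
  for (stage in stages) run_stage(config, stage, force = force)
  mpath <- file.path(config$out_dir, "run_manifest.json")
  invisible(if (file.exists(mpath)) read_json_file(mpath))
}
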