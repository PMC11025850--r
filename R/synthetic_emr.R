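# Synthetic three-dialect EMR generator.
#
# Emits per-dialect CSV extracts (patients, visits, reason-for-visit,
# history, medications, immunisations, allergic reactions, tests) that
# share one logical schema but differ in surface form (column names, date
# formats, gender encodings, source-code styles), together with a ground
# truth sidecar: the true term -> concept mapping, the registry of every
# injected data defect, and each patient's active/inactive status.

#' Configuration for the synthetic EMR generator
#'
#' Defaults emulate the shape of an Australian general-practice
#' repository at desk scale: a 50/40/10 split of practices across the
#' Best-Practice-like (`bp`), Medical-Director-like (`md`) and
#' Zedmed-like (`zedmed`) dialects, a roughly 54/46 female/male gender
#' mix with a small "other" remainder, heavy Zipf skew over free-text
#' terms, and low-rate data defects (1900 birth-date sentinels, missing
#' gender, undated and future-dated events, orphan events, misspelled
#' terms).
#'
#' @param n_patients number of patients.
#' @param n_practices number of practices (each practice runs exactly one
#'   EMR dialect).
#' @param dialect_mix named proportions over `bp`, `md`, `zedmed`,
#'   summing to 1.
#' @param date_range character or Date vector of length 2; visits and
#'   events fall in this window and the activity reference date `as_of`
#'   is its end.
#' @param vocab_size number of distinct true concepts in the toy
#'   vocabulary.
#' @param zipf_exponent positive Zipf exponent for term-frequency skew.
#' @param records_per_table named counts for the six event tables.
#' @param defect_rates named fractions in `[0, 1]` for the defect kinds.
#' @param seed integer RNG seed; fixes every random choice.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(
    n_patients = 2000,
    n_practices = 10,
    dialect_mix = c(bp = 0.5, md = 0.4, zedmed = 0.1),
    date_range = c("2015-01-01", "2022-10-20"),
    vocab_size = 150,
    zipf_exponent = 1.1,
    records_per_table = c(reason_for_visit = 6000, history = 5000,
                          medications = 9000, immunisations = 1500,
                          allergic_reactions = 800, tests = 4000),
    defect_rates = c(dob_sentinel_1900 = 0.05, missing_gender = 0.006,
                     missing_event_date = 0.10, future_event_date = 0.01,
                     orphan_event = 0.01, misspelled_term = 0.02),
    seed = 1L) {
  stopifnot(n_patients >= 0, n_practices >= 1, vocab_size >= 1)
  if (zipf_exponent <= 0) stopf("zipf_exponent must be positive")
  if (!setequal(names(dialect_mix), c("bp", "md", "zedmed")) ||
      abs(sum(dialect_mix) - 1) > 1e-9)
    stopf("dialect_mix must cover bp/md/zedmed and sum to 1")
  if (!all(names(defect_rates) %in% .defect_kinds))
    stopf("unknown defect kind(s): %s",
          paste(setdiff(names(defect_rates), .defect_kinds), collapse = ", "))
  if (any(defect_rates < 0 | defect_rates > 1))
    stopf("defect rates must lie in [0, 1]")
  if (!all(names(records_per_table) %in% .source_tables))
    stopf("unknown source table(s) in records_per_table")
  date_range <- as.Date(date_range)
  if (is.na(date_range[1]) || is.na(date_range[2]) ||
      date_range[1] > date_range[2])
    stopf("date_range must be two valid dates, start <= end")
  if (n_patients == 0 && any(records_per_table > 0))
    stopf("cannot generate event records for zero patients")
  structure(list(n_patients = as.integer(n_patients),
                 n_practices = as.integer(n_practices),
                 dialect_mix = dialect_mix[c("bp", "md", "zedmed")],
                 date_range = date_range,
                 vocab_size = as.integer(vocab_size),
                 zipf_exponent = zipf_exponent,
                 records_per_table = records_per_table,
                 defect_rates = defect_rates,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d patients, %d practices, seed %d\n",
              x$n_patients, x$n_practices, x$seed))
  cat("  dialect mix:", paste(sprintf("%s=%.0f%%", names(x$dialect_mix),
                                      100 * x$dialect_mix), collapse = " "), "\n")
  cat("  records:", paste(sprintf("%s=%d", names(x$records_per_table),
                                  x$records_per_table), collapse = " "), "\n")
  invisible(x)
}

#' Sample Zipf-skewed term frequencies
#'
#' Draws a multinomial sample of `n_records` over `vocab_size` ranked
#' terms with probabilities proportional to `rank^-zipf_exponent`, then
#' orders the sampled counts non-increasingly by rank.  This reproduces
#' the situation where a few frequent free-text terms account for most
#' records while a long tail of rare terms does not repay manual mapping.
#'
#' @param vocab_size number of distinct terms (>= 1).
#' @param zipf_exponent positive skew exponent.
#' @param n_records total records to distribute (>= 0).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return data.frame with columns `rank` and `frequency`; frequencies
#'   sum to `n_records` and are non-increasing in rank.
#' @export
sample_term_frequencies <- function(vocab_size, zipf_exponent, n_records,
                                    seed = NULL) {
  stopifnot(vocab_size >= 1, n_records >= 0)
  if (zipf_exponent <= 0) stopf("zipf_exponent must be positive")
  if (!is.null(seed)) set.seed(seed)
  probs <- (seq_len(vocab_size))^(-zipf_exponent)
  probs <- probs / sum(probs)
  counts <- if (n_records == 0) rep(0L, vocab_size)
            else as.vector(stats::rmultinom(1L, n_records, probs))
  data.frame(rank = seq_len(vocab_size),
             frequency = sort(counts, decreasing = TRUE))
}

# single-character edit (substitution, deletion or insertion) on a
# letter position; never empties the string
spell_corrupt <- function(term) {
  chars <- strsplit(term, "")[[1]]
  letters_pos <- which(grepl("[a-z]", chars))
  if (length(letters_pos) == 0L) return(term)
  pos <- if (length(letters_pos) == 1L) letters_pos else sample(letters_pos, 1L)
  op <- sample(c("sub", "del", "ins"), 1L)
  repl <- sample(letters, 1L)
  if (op == "del" && length(chars) <= 1L) op <- "sub"
  out <- switch(op,
    sub = { chars[pos] <- repl; chars },
    del = chars[-pos],
    ins = append(chars, repl, after = pos))
  paste(out, collapse = "")
}

#' Inject data defects into generated rows
#'
#' Applies the configured defect kinds independently per row (Bernoulli
#' at each kind's rate) and records every alteration in a registry.
#' Only kinds applicable to the frame's columns are applied: the birth
#' date sentinel and missing gender need `dob`/`gender` columns
#' (patients), the date/orphan/misspelling kinds need
#' `event_date`/`patient_uid`/`term` columns (event tables).  Rows that
#' draw no defect are returned bit-identical.
#'
#' @param records a logical-schema data.frame with a `row_id` column.
#' @param rates named defect rates in `[0, 1]`.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param table source-table name recorded in the registry.
#' @param as_of reference date used to place future event dates.
#' @return list with `records` (altered frame) and `registry`
#'   (data.frame `table`, `row_key`, `kind`; one row per altered
#'   row-kind pair).
#' @export
inject_defects <- function(records, rates, seed = NULL,
                           table = "unknown", as_of = Sys.Date()) {
  if (!all(names(rates) %in% .defect_kinds))
    stopf("unknown defect kind(s): %s",
          paste(setdiff(names(rates), .defect_kinds), collapse = ", "))
  if (any(rates < 0 | rates > 1)) stopf("defect rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  reg <- list()
  hit <- function(rate) if (n == 0 || rate <= 0) logical(n)
                        else stats::runif(n) < rate
  applicable <- function(kind) switch(kind,
    dob_sentinel_1900  = "dob" %in% names(records),
    missing_gender     = "gender" %in% names(records),
    missing_event_date = ,
    future_event_date  = "event_date" %in% names(records),
    orphan_event       = "patient_uid" %in% names(records) &&
                         "event_date" %in% names(records),
    misspelled_term    = "term" %in% names(records))
  for (kind in intersect(names(rates), .defect_kinds)) {
    if (!applicable(kind)) next
    sel <- hit(rates[[kind]])
    if (kind == "missing_event_date")
      sel <- sel & !is.na(records$event_date)   # already-absent dates stay as-is
    if (!any(sel)) next
    idx <- which(sel)
    records <- within_defect(records, idx, kind, as_of)
    reg[[kind]] <- data.frame(table = table,
                              row_key = records$row_id[idx],
                              kind = kind)
  }
  registry <- if (length(reg) == 0L)
    data.frame(table = character(), row_key = character(),
               kind = character())
  else do.call(rbind, unname(reg))
  rownames(registry) <- NULL
  list(records = records, registry = registry)
}

within_defect <- function(records, idx, kind, as_of) {
  switch(kind,
    dob_sentinel_1900 = { records$dob[idx] <- as.Date("1900-01-01"); records },
    missing_gender = { records$gender[idx] <- ""; records },
    missing_event_date = { records$event_date[idx] <- as.Date(NA); records },
    future_event_date = {
      records$event_date[idx] <- as_of +
        sample(30:400, length(idx), replace = TRUE)
      records
    },
    orphan_event = {
      records$patient_uid[idx] <- sprintf("PX_ORPHAN_%06d", seq_along(idx))
      records
    },
    misspelled_term = {
      records$term[idx] <- vapply(records$term[idx], spell_corrupt,
                                  character(1), USE.NAMES = FALSE)
      records
    })
}

# --- toy vocabulary ---------------------------------------------------------

# deterministic pseudo-clinical word stock
.cond_adjs  <- c("acute", "chronic", "recurrent", "mild", "severe",
                 "atypical", "persistent", "benign", "focal", "diffuse")
.cond_nouns <- c("arthropathy", "dermatitis", "rhinitis", "neuralgia",
                 "gastritis", "myopathy", "otitis", "cystitis",
                 "bronchitis", "fasciitis", "keratosis", "tendinosis",
                 "colitis", "sinusitis", "pharyngitis")
.drug_syll  <- c("zol", "fex", "am", "pra", "vel", "tor", "mab", "cil",
                 "dex", "lor", "met", "ras", "tin", "bex", "qua")
.drug_forms <- c("tab", "cap", "syrup", "inj")
.drug_strengths <- c("5mg", "10mg", "25mg", "50mg", "100mg", "250mg",
                     "500mg", "20mcg", "100iu")
.test_nouns <- c("haemoglobin", "ferritin", "cholesterol", "glucose",
                 "creatinine", "thyrotropin", "urate", "albumin",
                 "triglyceride", "calcium")
.vacc_nouns <- c("influenza", "pertussis", "measles", "zoster",
                 "pneumococcal", "hepatitis", "tetanus", "varicella")
.allergens  <- c("penicillin", "peanut", "latex", "pollen", "sulfa",
                 "aspirin", "shellfish", "egg", "dust mite", "bee venom")

pseudo_word <- function(n_syll = 3) {
  paste(sample(.drug_syll, n_syll, replace = TRUE), collapse = "")
}

#' Build a toy standard-vocabulary bundle
#'
#' Constructs a synthetic OMOP-style concept table with a SNOMED-like
#' condition/observation/measurement/procedure/device branch and an
#' RxNorm-like drug branch: ingredient concepts, single-ingredient brand
#' products ("brand strength form") and two-ingredient combination
#' products, each product linked to its ingredient concept(s) through an
#' ingredient-relationship table.  All content is invented; only the
#' structure mirrors a real vocabulary.
#'
#' @param vocab_size approximate number of concepts (>= 30).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return an `omop_vocabulary` with attribute `pools`: per-source-table
#'   character vectors of concept-name term pools used by the cohort
#'   generator.
#' @export
toy_vocabulary <- function(vocab_size = 150, seed = NULL) {
  stopifnot(vocab_size >= 30)
  if (!is.null(seed)) set.seed(seed)
  n_cond <- max(10L, round(vocab_size * 0.35))
  n_ingr <- max(8L, round(vocab_size * 0.12))
  n_drug <- max(10L, round(vocab_size * 0.30))
  n_combo <- max(3L, round(n_drug * 0.15))
  n_test <- min(length(.test_nouns), max(5L, round(vocab_size * 0.08)))
  n_vacc <- min(length(.vacc_nouns), 8L)
  n_alg  <- min(length(.allergens), 10L)
  n_proc <- 6L
  n_dev  <- 4L

  grid <- expand.grid(a = .cond_adjs, n = .cond_nouns,
                      stringsAsFactors = FALSE)
  cond_names <- paste(grid$a, grid$n)[seq_len(min(n_cond, nrow(grid)))]

  draw_unique <- function(k, n_syll) {
    out <- character(0)
    while (length(out) < k)
      out <- unique(c(out, replicate(k * 2, pseudo_word(n_syll))))
    out[seq_len(k)]
  }
  ingr_names <- paste0(draw_unique(n_ingr, 3), "ine")
  brand_stems <- paste0(draw_unique(n_drug, 2), "ex")
  drug_names <- paste(brand_stems,
                      sample(.drug_strengths, n_drug, replace = TRUE),
                      sample(.drug_forms, n_drug, replace = TRUE))
  proc_names <- paste(c("excision", "aspiration", "suture", "biopsy",
                        "cryotherapy", "drainage")[seq_len(n_proc)],
                      "procedure")
  dev_names <- paste(c("glucose meter", "nebuliser", "insulin pen",
                       "hearing aid")[seq_len(n_dev)], "device")
  test_names <- paste(.test_nouns[seq_len(n_test)], "level")
  vacc_names <- paste(.vacc_nouns[seq_len(n_vacc)], "vaccine")
  alg_names  <- paste(.allergens[seq_len(n_alg)], "allergy")

  rows <- list()
  next_id <- 1000L
  add <- function(names, domain, vocab_id, standard = "S") {
    ids <- next_id + seq_along(names) - 1L
    next_id <<- next_id + length(names)
    data.frame(concept_id = ids, concept_name = names, domain_id = domain,
               vocabulary_id = vocab_id, standard_concept = standard,
               stringsAsFactors = FALSE)
  }
  cond <- add(cond_names, "Condition", "SNOMED")
  proc <- add(proc_names, "Procedure", "SNOMED")
  dev  <- add(dev_names, "Device", "SNOMED")
  test <- add(test_names, "Measurement", "SNOMED")
  alg  <- add(alg_names, "Observation", "SNOMED")
  ingr <- add(ingr_names, "Drug", "RxNorm")
  drug <- add(drug_names, "Drug", "RxNorm")
  vacc <- add(vacc_names, "Drug", "RxNorm")

  # combination products carry two ingredients; plain brands carry one
  combo_idx <- seq_len(n_combo)
  combo_pairs <- t(vapply(combo_idx, function(i)
    sample(ingr$concept_id, 2L), integer(2)))
  combo_names <- paste(paste0(brand_stems[combo_idx], " duo"),
                       sample(.drug_strengths, n_combo, replace = TRUE),
                       sample(.drug_forms, n_combo, replace = TRUE))
  combo <- add(combo_names, "Drug", "RxNorm")
  single_ing <- sample(ingr$concept_id, n_drug, replace = TRUE)
  ingredient <- rbind(
    data.frame(concept_id = rep(combo$concept_id, each = 2L),
               ingredient_concept_id = as.vector(t(combo_pairs))),
    data.frame(concept_id = drug$concept_id,
               ingredient_concept_id = single_ing))

  concept <- rbind(cond, proc, dev, test, alg, ingr, drug, vacc, combo)
  vocab <- new_vocabulary(concept, ingredient)
  attr(vocab, "pools") <- list(
    reason_for_visit = cond$concept_name,
    history = c(cond$concept_name, proc$concept_name, test$concept_name,
                dev$concept_name),
    medications = c(drug$concept_name, combo$concept_name),
    immunisations = vacc$concept_name,
    allergic_reactions = alg$concept_name,
    tests = c(test$concept_name, proc$concept_name, dev$concept_name))
  attr(vocab, "pool_ids") <- list(
    reason_for_visit = cond$concept_id,
    history = c(cond$concept_id, proc$concept_id, test$concept_id,
                dev$concept_id),
    medications = c(drug$concept_id, combo$concept_id),
    immunisations = vacc$concept_id,
    allergic_reactions = alg$concept_id,
    tests = c(test$concept_id, proc$concept_id, dev$concept_id))
  vocab
}

# --- cohort generation ------------------------------------------------------

# brute-force activity oracle: O(n^2) scan over all anchor dates plus a
# recency scan; deliberately independent of the ETL's sorted-window test
brute_force_active <- function(dates, as_of, min_visits = 3L,
                               window_days = 730L, recent_days = 730L) {
  if (length(dates) == 0L) return(FALSE)
  d <- as.numeric(as.Date(dates))
  ref <- as.numeric(as.Date(as_of))
  d <- d[!is.na(d) & d <= ref]
  if (length(d) == 0L) return(FALSE)
  for (anchor in d) {
    if (sum(d >= anchor & d <= anchor + window_days) >= min_visits)
      return(TRUE)
  }
  any(ref - d <= recent_days)
}

#' Generate a synthetic three-dialect EMR cohort
#'
#' Produces one directory per dialect containing that dialect's CSV file
#' set, a toy vocabulary bundle, and a `ground_truth.json` sidecar
#' holding the true term-to-concept mapping, the defect registry and
#' each patient's true active/inactive status (computed by a brute-force
#' window scan, independent of the ETL's activity test).  Byte-identical
#' output for identical config and seed.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `dirs` (per-dialect paths),
#'   `ground_truth`, `vocabulary` and the logical `tables`.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  as_of <- config$date_range[2]

  vocab <- toy_vocabulary(config$vocab_size)
  write_vocabulary(vocab, file.path(out_dir, "vocabulary"))

  # practices: dialect by configured mix (largest-remainder rounding)
  n_pr <- config$n_practices
  quota <- config$dialect_mix * n_pr
  n_by_dialect <- floor(quota)
  rem <- n_pr - sum(n_by_dialect)
  if (rem > 0) {
    extra <- order(quota - n_by_dialect, decreasing = TRUE)[seq_len(rem)]
    n_by_dialect[extra] <- n_by_dialect[extra] + 1L
  }
  practices <- data.frame(
    practice_id = sprintf("PR%03d", seq_len(n_pr)),
    dialect = rep(names(n_by_dialect), n_by_dialect))

  # patients
  n <- config$n_patients
  patients <- if (n == 0) {
    data.frame(row_id = character(), patient_uid = character(),
               practice_id = character(), name = character(),
               gender = character(), dob = as.Date(character()))
  } else {
    age_days <- sample(18:90, n, replace = TRUE) * 365L +
      sample(0:364, n, replace = TRUE)
    data.frame(
      row_id = sprintf("pat%06d", seq_len(n)),
      patient_uid = sprintf("P%06d", seq_len(n)),
      practice_id = sample(practices$practice_id, n, replace = TRUE),
      name = paste0("patient ", pseudo_names(n)),
      gender = sample(c("female", "male", "other", "unknown"), n,
                      replace = TRUE, prob = c(0.539, 0.458, 0.002, 0.001)),
      dob = as_of - age_days)
  }

  # visits: a mix of lapsed low-visit patients and regular attenders
  visits <- if (n == 0) {
    data.frame(row_id = character(), visit_id = character(),
               patient_uid = character(), practice_id = character(),
               event_date = as.Date(character()))
  } else {
    span <- as.integer(config$date_range[2] - config$date_range[1])
    vlist <- lapply(seq_len(n), function(i) {
      kind <- sample(c("none", "lapsed", "regular"), 1L,
                     prob = c(0.08, 0.40, 0.52))
      k <- switch(kind, none = 0L,
                  lapsed = sample(1:2, 1L),
                  regular = sample(3:10, 1L))
      if (k == 0L) return(NULL)
      start <- sample(0:max(span - 60, 1), 1L)
      width <- switch(kind, lapsed = sample(30:400, 1L),
                      regular = sample(200:span, 1L))
      offs <- sort(sample(0:width, k, replace = TRUE))
      d <- pmin(config$date_range[1] + start + offs, config$date_range[2])
      data.frame(patient_uid = patients$patient_uid[i],
                 practice_id = patients$practice_id[i],
                 event_date = d)
    })
    v <- do.call(rbind, vlist)
    if (is.null(v)) v <- data.frame(patient_uid = character(),
                                    practice_id = character(),
                                    event_date = as.Date(character()))
    v$row_id <- sprintf("vis%06d", seq_len(nrow(v)))
    v$visit_id <- v$row_id
    v[c("row_id", "visit_id", "patient_uid", "practice_id", "event_date")]
  }

  # event tables: Zipf frequencies over the table's term pool
  pools <- attr(vocab, "pools")
  pool_ids <- attr(vocab, "pool_ids")
  tables <- list()
  for (tab in .source_tables) {
    n_rec <- if (tab %in% names(config$records_per_table))
      config$records_per_table[[tab]] else 0L
    pool <- pools[[tab]]
    ids <- pool_ids[[tab]]
    if (n_rec == 0 || n == 0) {
      tables[[tab]] <- empty_event_frame(tab)
      next
    }
    perm <- sample(length(pool))           # random rank assignment
    f <- sample_term_frequencies(length(pool), config$zipf_exponent, n_rec)
    reps <- rep(perm, times = f$frequency)
    pat_idx <- sample(n, n_rec, replace = TRUE)
    ev <- data.frame(
      row_id = sprintf("%s%06d", substr(tab, 1, 3), seq_len(n_rec)),
      patient_uid = patients$patient_uid[pat_idx],
      practice_id = patients$practice_id[pat_idx],
      event_date = config$date_range[1] +
        sample(0:as.integer(as_of - config$date_range[1]), n_rec,
               replace = TRUE),
      term = pool[reps],
      concept_id = ids[reps],
      source_code = sprintf("SRC%05d", ids[reps]),
      numeric_value = NA_real_,
      units = "")
    if (tab == "medications")
      ev$term <- paste(ev$term, sample(c("20", "30", "60", "x 5", "x 2"),
                                       n_rec, replace = TRUE))
    if (tab == "tests") {
      ev$numeric_value <- round(stats::rlnorm(n_rec, log(5), 0.6), 2)
      ev$units <- "mmol l"
    }
    tables[[tab]] <- ev
  }

  # defect injection (one shared RNG stream keeps the run deterministic)
  registry <- list()
  res <- inject_defects(patients, config$defect_rates, table = "patients",
                        as_of = as_of)
  patients <- res$records
  registry[["patients"]] <- res$registry
  event_kinds <- c("missing_event_date", "future_event_date",
                   "orphan_event", "misspelled_term")
  date_defect_tables <- c("reason_for_visit", "history", "allergic_reactions")
  for (tab in .source_tables) {
    rates <- config$defect_rates[intersect(names(config$defect_rates),
                                           event_kinds)]
    if (!tab %in% date_defect_tables)
      rates <- rates[setdiff(names(rates), "missing_event_date")]
    res <- inject_defects(tables[[tab]], rates, table = tab, as_of = as_of)
    tables[[tab]] <- res$records
    registry[[tab]] <- res$registry
  }
  defect_registry <- do.call(rbind, unname(registry))
  rownames(defect_registry) <- NULL

  # ground truth: term -> concept ids (post-defect, so misspellings are
  # present with their true concept), activity by brute force
  pairs <- do.call(rbind, lapply(.source_tables, function(tab) {
    ev <- tables[[tab]]
    if (nrow(ev) == 0L) return(NULL)
    tn <- normalise_term(ev$term)
    if (tab == "medications") tn <- strip_pack_size(tn)
    data.frame(key = tn, concept_id = ev$concept_id)
  }))
  term_truth <- if (is.null(pairs)) list()
    else lapply(split(pairs$concept_id, pairs$key),
                function(v) sort(unique(v)))
  activity_truth <- if (n == 0) {
    stats::setNames(logical(0), character(0))
  } else {
    by_pat <- split(visits$event_date, visits$patient_uid)
    act <- vapply(patients$patient_uid, function(p) {
      brute_force_active(by_pat[[p]], as_of)
    }, logical(1))
    stats::setNames(act, patients$patient_uid)
  }

  tables_all <- c(list(patients = patients, visits = visits), tables)
  dirs <- write_dialect_files(tables_all, practices, out_dir)

  ground_truth <- list(
    term_truth = term_truth,
    defect_registry = defect_registry,
    activity_truth = as.list(activity_truth),
    as_of = as.character(as_of),
    practices = practices)
  write_json_file(list(
    term_truth = term_truth,
    defect_registry = defect_registry,
    activity_truth = activity_truth,
    as_of = as.character(as_of)),
    file.path(out_dir, "ground_truth.json"))

  invisible(list(dirs = dirs, ground_truth = ground_truth,
                 vocabulary = vocab, tables = tables_all,
                 config = config))
}

pseudo_names <- function(n) {
  vapply(seq_len(n), function(i) pseudo_word(2), character(1))
}

empty_event_frame <- function(tab) {
  data.frame(row_id = character(), patient_uid = character(),
             practice_id = character(), event_date = as.Date(character()),
             term = character(), concept_id = integer(),
             source_code = character(), numeric_value = numeric(),
             units = character())
}
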