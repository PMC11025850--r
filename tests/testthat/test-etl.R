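test_that("activity rule: clause examples behave as stated", {
  as_of <- as.Date("2022-10-20")
  rule <- active_rule(as_of)

  expect_false(is_active(as.Date(character()), rule))

  # 3 visits spanning 600 days activate via the window clause
  origin <- as.Date("2016-01-01")
  expect_true(is_active(origin + c(0, 300, 600), rule))
  # ... but not when the span exceeds the window
  expect_false(is_active(origin + c(0, 400, 800), rule))

  # a single recent visit activates via the recency clause
  expect_true(is_active(as_of - 100, rule))
  # a single old visit does not
  expect_false(is_active(as_of - 2000, rule))

  # visits after as_of are ignored
  expect_false(is_active(as_of + c(1, 10, 20), rule))
})

test_that("activity rule agrees with the brute-force oracle on random histories", {
  as_of <- as.Date("2022-10-20")
  rule <- active_rule(as_of)
  set.seed(99)
  for (i in 1:1000) {
    k <- sample(0:8, 1)
    dates <- if (k == 0) as.Date(character())
             else as_of - sample(-200:4000, k, replace = TRUE)
    expect_equal(is_active(dates, rule),
                 omopforge:::brute_force_active(dates, as_of),
                 info = paste(format(dates), collapse = ","))
  }
})

test_that("the active set equals generator ground truth and grows monotonically", {
  dir <- withr::local_tempdir()
  cfg <- small_gen_config(seed = 23)
  hc <- harmonised_cohort(cfg, dir)
  rule <- active_rule(cfg$date_range[2])
  active <- filter_active(hc$staging, rule)

  truth <- unlist(hc$gen$ground_truth$activity_truth)
  # map true patient uids to staging keys through the practice scoping
  pats <- hc$gen$tables$patients
  keys <- pseudonymise(pats$patient_uid,
                       paste0("omopforge", "|", pats$practice_id))
  expect_setequal(active, keys[truth[pats$patient_uid]])

  # enlarging the recency horizon never shrinks the active set
  wider <- filter_active(hc$staging,
                         active_rule(cfg$date_range[2],
                                     recent_days = 2000))
  expect_true(all(active %in% wider))

  # all patients visitless -> empty set
  empty_staging <- hc$staging
  empty_staging$visits <- empty_staging$visits[0, ]
  expect_length(filter_active(empty_staging, rule), 0L)
})

test_that("routing follows the dated/undated rule and is total", {
  expect_equal(route("reason_for_visit", "Condition", TRUE),
               "CONDITION_OCCURRENCE")
  expect_equal(route("history", "Condition", FALSE), "OBSERVATION")
  expect_equal(route("history", "Measurement", TRUE), "MEASUREMENT")
  expect_equal(route("history", "Procedure", TRUE), "PROCEDURE_OCCURRENCE")
  expect_equal(route("history", "Device", TRUE), "DEVICE_EXPOSURE")
  expect_equal(route("medications", "Drug", TRUE), "DRUG_EXPOSURE")
  expect_equal(route("medications", "Device", TRUE), "DEVICE_EXPOSURE")
  expect_setequal(route("immunisations", "Drug", TRUE),
                  c("PROCEDURE_OCCURRENCE", "DRUG_EXPOSURE"))
  expect_equal(route("allergic_reactions", "Observation", FALSE),
               "OBSERVATION")
  expect_equal(route("tests", "Measurement", TRUE), "MEASUREMENT")
  expect_equal(route("tests", "Procedure", TRUE), "PROCEDURE_OCCURRENCE")
  expect_error(route("nope", "Drug", TRUE), "unknown source table")

  # totality: every combination routes to exactly one table, two for
  # immunisations
  domains <- c("Condition", "Observation", "Measurement", "Procedure",
               "Drug", "Device")
  for (tab in c("reason_for_visit", "history", "medications",
                "immunisations", "allergic_reactions", "tests")) {
    for (dom in domains) for (dated in c(TRUE, FALSE)) {
      tgt <- route(tab, dom, dated)
      expect_equal(length(tgt), if (tab == "immunisations") 2L else 1L,
                   info = paste(tab, dom, dated))
      expect_true(all(tgt %in% c("CONDITION_OCCURRENCE", "OBSERVATION",
                                 "MEASUREMENT", "PROCEDURE_OCCURRENCE",
                                 "DRUG_EXPOSURE", "DEVICE_EXPOSURE")))
    }
  }
})

test_that("concept resolution: mapped, unmapped and combination terms", {
  vocab <- tiny_vocab()
  mapping <- data.frame(
    term_norm = c("acute otitis", "colddex duo 30mg tab"),
    concept_ids = c("1", "21"),
    status = c("matched_auto", "matched_auto"),
    frequency = c(10L, 5L))

  res <- resolve_concept("reason_for_visit", "Acute Otitis!", mapping, vocab)
  expect_equal(res$concept_ids, 1L)
  expect_equal(res$domain_id, "Condition")

  res <- resolve_concept("medications", "Unseen Drug 5mg", mapping, vocab)
  expect_equal(res$concept_ids, 0L)
  expect_equal(res$domain_id, "Drug")

  # combination drug resolves to one id per ingredient
  res <- resolve_concept("medications", "Colddex Duo 30mg tab 20",
                         mapping, vocab)
  expect_equal(res$concept_ids, c(10L, 11L))
  expect_equal(res$domain_id, "Drug")
})

test_that("a hand-traceable cohort produces exactly the expected CDM rows", {
  vocab <- tiny_vocab()
  as_of <- as.Date("2022-10-20")
  staging <- structure(list(
    patients = data.frame(
      patient_key = c("k1", "k2"), gender_source = c("female", "male"),
      birth_year = c(1980L, 1990L), practice_key = "pr1",
      dialect = "bp", row_ref = c("bp:p1", "bp:p2")),
    visits = data.frame(
      patient_key = "k1", practice_key = "pr1",
      visit_date = as_of - 30, dialect = "bp", row_ref = "bp:v1"),
    records = data.frame(
      source_table = c("reason_for_visit", "medications", "history"),
      patient_key = c("k1", "k1", "k1"),
      practice_key = "pr1",
      event_date = c(as_of - 30, as_of - 30, as.Date(NA)),
      term_text = c("acute otitis", "colddex duo 30mg tab 20",
                    "chronic gastritis"),
      source_code = "", numeric_value = NA_real_, units = "",
      dialect = "bp", row_ref = c("bp:r1", "bp:r2", "bp:r3")),
    log = list(tables = list(), demographic_conflicts = 0L)),
    class = "omop_staging")
  mapping <- data.frame(
    term_norm = c("acute otitis", "colddex duo 30mg tab",
                  "chronic gastritis"),
    concept_ids = c("1", "21", "2"),
    status = "matched_auto",
    frequency = 1L)
  build <- build_cdm(staging, mapping, vocab, active_rule(as_of))
  cdm <- build$cdm

  # only the active patient (k1, recent visit) is written
  expect_equal(nrow(cdm$PERSON), 1L)
  expect_equal(cdm$PERSON$gender_concept_id, 8532L)
  expect_equal(nrow(cdm$CONDITION_OCCURRENCE), 1L)
  expect_equal(cdm$CONDITION_OCCURRENCE$condition_concept_id, 1L)
  # the combination drug fans out to its two ingredients
  expect_equal(sort(cdm$DRUG_EXPOSURE$drug_concept_id), c(10L, 11L))
  # undated condition lands in OBSERVATION, dated with the last visit
  expect_equal(nrow(cdm$OBSERVATION), 1L)
  expect_equal(cdm$OBSERVATION$observation_date, as_of - 30)
  expect_equal(build$log$defaulted_dates, "bp:r3")
  # inactive patient's absence and conservation in the log
  expect_equal(build$log$tables$history$rows_in, 1L)
  expect_equal(nrow(cdm$CDM_SOURCE), 1L)
})

test_that("empty staging still yields a CDM with a CDM_SOURCE row", {
  staging <- harmonise(list())
  build <- build_cdm(staging, data.frame(term_norm = character(),
                                         concept_ids = character(),
                                         status = character(),
                                         frequency = integer()),
                     tiny_vocab(), active_rule("2022-10-20"))
  expect_equal(nrow(build$cdm$PERSON), 0L)
  expect_equal(nrow(build$cdm$DRUG_EXPOSURE), 0L)
  expect_equal(nrow(build$cdm$CDM_SOURCE), 1L)
})

test_that("ETL conserves rows against an independent recount and is idempotent", {
  dir <- withr::local_tempdir()
  cfg <- small_gen_config(seed = 29)
  hc <- harmonised_cohort(cfg, dir)
  vocab <- hc$gen$vocabulary
  freqs <- term_frequencies(hc$staging$records)
  mapping <- map_terms(freqs, vocab, threshold = 1)
  rule <- active_rule(cfg$date_range[2])
  build <- build_cdm(hc$staging, mapping, vocab, rule)

  # independent recount: apply the routing rules in a standalone pass
  active <- filter_active(hc$staging, rule)
  known <- hc$staging$patients$patient_key
  expected <- stats::setNames(numeric(6), c(
    "CONDITION_OCCURRENCE", "OBSERVATION", "MEASUREMENT",
    "PROCEDURE_OCCURRENCE", "DRUG_EXPOSURE", "DEVICE_EXPOSURE"))
  rec <- hc$staging$records
  for (i in seq_len(nrow(rec))) {
    if (!rec$patient_key[i] %in% known) next
    if (!rec$patient_key[i] %in% active) next
    res <- resolve_concept(rec$source_table[i], rec$term_text[i],
                           mapping, vocab)
    for (tgt in route(rec$source_table[i], res$domain_id,
                      !is.na(rec$event_date[i]))) {
      n_rows <- if (tgt == "DRUG_EXPOSURE") length(res$concept_ids) else 1L
      expected[tgt] <- expected[tgt] + n_rows
    }
  }
  for (tgt in names(expected))
    expect_equal(nrow(build$cdm[[tgt]]), unname(expected[tgt]), info = tgt)

  # conservation per source table: in = kept + dropped
  for (tab in names(build$log$tables)) {
    lg <- build$log$tables[[tab]]
    expect_equal(lg$rows_in, lg$rows_kept + sum(lg$rows_dropped),
                 info = tab)
  }
  # orphan drops equal the injected orphan defects on active patients' rows
  reg <- hc$gen$ground_truth$defect_registry
  n_orphans_dropped <- sum(vapply(build$log$tables, function(lg)
    lg$rows_dropped[["orphan"]], numeric(1)))
  expect_equal(n_orphans_dropped, sum(reg$kind == "orphan_event"))

  # idempotence: rebuilding and re-exporting is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cdm(build, d1)
  write_cdm(build_cdm(hc$staging, mapping, vocab, rule), d2)
  expect_identical(dir_hashes(d1), dir_hashes(d2))

  # referential integrity
  for (tgt in names(expected)) {
    expect_true(all(build$cdm[[tgt]]$person_id %in%
                    build$cdm$PERSON$person_id), info = tgt)
  }
})
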