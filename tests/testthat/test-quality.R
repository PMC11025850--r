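# minimal CDM scaffold for check-level tests
mini_cdm <- function(n = 1000, n_bad = 1, as_of = as.Date("2022-10-20")) {
  person <- data.frame(
    person_id = seq_len(n),
    gender_concept_id = rep(8532L, n),
    year_of_birth = c(rep(1900L, n_bad), rep(1970L, n - n_bad)),
    person_source_value = sprintf("k%04d", seq_len(n)),
    gender_source_value = "female")
  empty_event <- function(prefix, date_col, concept_col) {
    df <- data.frame(id = integer(), person_id = integer(),
                     concept = integer(), date = as.Date(character()),
                     type = integer(), src = character())
    names(df) <- c(paste0(prefix, "_id"), "person_id", concept_col,
                   date_col, paste0(prefix, "_type_concept_id"),
                   paste0(prefix, "_source_value"))
    df
  }
  list(PERSON = person,
       CONDITION_OCCURRENCE = empty_event("condition_occurrence",
         "condition_start_date", "condition_concept_id"),
       OBSERVATION = empty_event("observation", "observation_date",
         "observation_concept_id"),
       MEASUREMENT = empty_event("measurement", "measurement_date",
         "measurement_concept_id"),
       PROCEDURE_OCCURRENCE = empty_event("procedure_occurrence",
         "procedure_date", "procedure_concept_id"),
       DRUG_EXPOSURE = empty_event("drug_exposure",
         "drug_exposure_start_date", "drug_concept_id"),
       DEVICE_EXPOSURE = empty_event("device_exposure",
         "device_exposure_start_date", "device_concept_id"))
}

test_that("strict-exceed FAIL semantics, including the exact boundary", {
  cdm <- mini_cdm(n = 1000, n_bad = 1)
  def <- check_definition("plaus_birth_year_range", "plausibility",
                          "verification", "PERSON", "range",
                          field = "year_of_birth",
                          params = list(min = 1901, max = 2022,
                                        required = TRUE),
                          threshold_pct = 0)
  res <- run_check(cdm, def)
  expect_equal(res$violating, 1L)
  expect_equal(res$status, "FAIL")   # 0.1% > 0%

  # violation rate exactly at the threshold passes
  cdm50 <- mini_cdm(n = 1000, n_bad = 50)
  def5 <- check_definition("b", "plausibility", "verification", "PERSON",
                           "range", field = "year_of_birth",
                           params = list(min = 1901, max = 2022,
                                         required = TRUE),
                           threshold_pct = 5.0)
  res5 <- run_check(cdm50, def5)
  expect_equal(res5$pct_violated, 5.0)
  expect_equal(res5$status, "PASS")
  # ... and one more violation flips it
  cdm51 <- mini_cdm(n = 1000, n_bad = 51)
  expect_equal(run_check(cdm51, def5)$status, "FAIL")

  # empty table is not applicable
  def_empty <- check_definition("c", "conformance", "verification",
                                "OBSERVATION", "fk_person")
  expect_equal(run_check(cdm, def_empty)$status, "NOT_APPLICABLE")

  # unknown predicate and missing column
  expect_error(run_check(cdm, check_definition(
    "d", "conformance", "verification", "PERSON", "wat")), "unknown predicate")
  expect_warning(res_na <- run_check(cdm, check_definition(
    "e", "conformance", "verification", "PERSON", "non_null",
    field = "ghost_column")), "missing")
  expect_equal(res_na$status, "NOT_APPLICABLE")
})

test_that("raising a threshold never converts a PASS into a FAIL", {
  cdm <- mini_cdm(n = 200, n_bad = 20)  # 10% violation
  prev <- "FAIL"
  for (thr in c(0, 5, 9.99, 10, 10.01, 50, 100)) {
    def <- check_definition("t", "plausibility", "verification", "PERSON",
                            "range", field = "year_of_birth",
                            params = list(min = 1901, max = 2022,
                                          required = TRUE),
                            threshold_pct = thr)
    st <- run_check(cdm, def)$status
    if (prev == "PASS") expect_equal(st, "PASS")
    prev <- st
  }
  expect_equal(prev, "PASS")
})

test_that("a published-style summary table is reproduced from its counts", {
  fabricate <- function(category, context, pass, fail) {
    data.frame(check_id = sprintf("%s_%s_%04d", category, context,
                                  seq_len(pass + fail)),
               category = category, context = context, table = "PERSON",
               denominator = 100L, violating = 0L, pct_violated = 0,
               threshold_pct = 0,
               status = c(rep("PASS", pass), rep("FAIL", fail)))
  }
  results <- rbind(
    fabricate("plausibility", "verification", 1982, 53),
    fabricate("plausibility", "validation", 285, 2),
    fabricate("conformance", "verification", 746, 30),
    fabricate("conformance", "validation", 157, 0),
    fabricate("completeness", "verification", 289, 14),
    fabricate("completeness", "validation", 6, 6))
  s <- summarise_quality(results)

  total <- s[s$category == "Total", ]
  expect_equal(total$total_total, 3570L)
  expect_equal(total$total_pass, 3465L)
  expect_equal(total$total_pct, 97)
  expect_equal(total$verification_pct, 97)
  expect_equal(total$validation_pct, 98)

  plaus <- s[s$category == "plausibility", ]
  expect_equal(plaus$total_pass, 2267L)
  expect_equal(plaus$total_total, 2322L)
  expect_equal(plaus$total_pct, 98)
  expect_equal(plaus$validation_pct, 99)

  conf <- s[s$category == "conformance", ]
  expect_equal(conf$total_pct, 97)
  expect_equal(conf$verification_pct, 96)
  expect_equal(conf$validation_pct, 100)

  # completeness follows the arithmetic of its own cells
  comp <- s[s$category == "completeness", ]
  expect_equal(comp$total_pass, 295L)
  expect_equal(comp$total_fail, 20L)
  expect_equal(comp$total_total, 315L)
  expect_equal(comp$total_pct, 94)
  expect_equal(comp$validation_pct, 50)

  # summary conservation: cells add up to the number of applicable checks
  cats <- s[s$category != "Total", ]
  expect_equal(sum(cats$total_total), nrow(results))
})

test_that("an all-pass suite summarises to 100% and NA results are excluded", {
  results <- data.frame(check_id = c("a", "b", "c"),
                        category = c("plausibility", "conformance",
                                     "completeness"),
                        context = "verification", table = "PERSON",
                        denominator = c(10L, 10L, 0L),
                        violating = 0L, pct_violated = c(0, 0, NA),
                        threshold_pct = 0,
                        status = c("PASS", "PASS", "NOT_APPLICABLE"))
  s <- summarise_quality(results)
  expect_equal(s$total_pct[s$category == "Total"], 100)
  expect_equal(s$total_total[s$category == "Total"], 2L)
  expect_equal(s$total_total[s$category == "completeness"], 0L)
})

test_that("reports round-trip through JSON and CSV without losing counts", {
  dir <- withr::local_tempdir()
  cdm <- mini_cdm(n = 50, n_bad = 5)
  defs <- builtin_checks(as.Date("2022-10-20"))
  results <- suppressWarnings(run_quality(cdm, defs))
  s <- summarise_quality(results)
  paths <- render_report(s, results, dir)
  expect_true(all(file.exists(paths)))

  back_json <- jsonlite::read_json(file.path(dir, "dq_results.json"),
                                   simplifyVector = TRUE)
  back_csv <- utils::read.csv(file.path(dir, "dq_results.csv"))
  expect_equal(back_csv$violating, results$violating)
  expect_equal(back_json$results$denominator, results$denominator)
  expect_equal(back_json$results$status, results$status)

  md <- readLines(file.path(dir, "dq_summary.md"))
  data_rows <- grep("^\\| (plausibility|conformance|completeness|Total)", md)
  expect_length(data_rows, 4L)

  expect_error(render_report(s, results, dir, formats = "pdf"),
               "unknown report format")

  # empty result set renders without crashing
  empty <- results[0, ]
  s0 <- summarise_quality(empty)
  expect_no_error(render_report(s0, empty, dir))
  expect_equal(s0$total_total[s0$category == "Total"], 0L)
})

test_that("an injected birth-year defect is recovered exactly and flips at its rate", {
  dir <- withr::local_tempdir()
  cfg <- small_gen_config(seed = 37, n_patients = 1200)
  hc <- harmonised_cohort(cfg, dir)
  vocab <- hc$gen$vocabulary
  mapping <- map_terms(term_frequencies(hc$staging$records), vocab,
                       threshold = 1)
  rule <- active_rule(cfg$date_range[2])
  build <- build_cdm(hc$staging, mapping, vocab, rule)

  # expected violation percentage from the defect registry, restricted
  # to patients that made it into PERSON (active only)
  reg <- hc$gen$ground_truth$defect_registry
  pats <- hc$gen$tables$patients
  sent_rows <- reg$row_key[reg$kind == "dob_sentinel_1900"]
  sent_uids <- pats$patient_uid[pats$row_id %in% sent_rows]
  keys <- pseudonymise(pats$patient_uid,
                       paste0("omopforge", "|", pats$practice_id))
  names(keys) <- pats$patient_uid
  in_person <- build$cdm$PERSON$person_source_value
  n_sentinel_in_person <- sum(keys[sent_uids] %in% in_person)
  expected_pct <- 100 * n_sentinel_in_person / nrow(build$cdm$PERSON)

  def <- function(thr) check_definition(
    "plaus_birth_year_range", "plausibility", "verification", "PERSON",
    "range", field = "year_of_birth",
    params = list(min = 1901, max = 2022, required = TRUE),
    threshold_pct = thr)
  res <- run_check(build$cdm, def(0))
  expect_equal(res$pct_violated, expected_pct)
  expect_gt(expected_pct, 0)

  # FAIL below the injected rate, PASS at or above it
  expect_equal(run_check(build$cdm, def(expected_pct - 0.5))$status, "FAIL")
  expect_equal(run_check(build$cdm, def(expected_pct))$status, "PASS")
  expect_equal(run_check(build$cdm, def(expected_pct + 0.5))$status, "PASS")
})

test_that("gender shares reproduce published-style percentages from counts", {
  counts <- c(female = 1086934, male = 924140, not_recorded = 11526,
              other = 494, unknown = 67)
  share <- gender_share(counts)
  expect_equal(share$pct[share$category == "female"], 53.7)
  expect_equal(share$pct[share$category == "male"], 45.7)
  expect_equal(share$pct[share$category == "not_recorded"], 0.6)
  expect_equal(sum(share$count), 2023161)

  # and from a PERSON table
  person <- data.frame(gender_concept_id = c(rep(8532L, 6), rep(8507L, 3),
                                             0L))
  share2 <- gender_share(person)
  expect_equal(share2$pct[share2$category == "female"], 60.0)
})
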