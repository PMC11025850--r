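# Shared fixtures and independent oracles.

# A small hand-built vocabulary exercised through the public CSV
# interface.  Contains a standard/non-standard name clash, a
# two-ingredient combination drug, single-ingredient brands and a
# nested combination (combo -> combo -> ingredients) for the
# transitive-closure check.
tiny_vocab <- function() {
  concept <- data.frame(
    concept_id = c(1L, 2L, 3L, 10L, 11L, 12L, 20L, 21L, 22L, 23L, 30L),
    concept_name = c(
      "acute otitis", "chronic gastritis", "acute otitis",
      "pseudoephedrine", "codeine", "paracetamol",
      "sniffex 30mg tab", "colddex duo 30mg tab",
      "tripledex 10mg cap", "haemoglobin level", "glucose meter device"),
    domain_id = c("Condition", "Condition", "Condition",
                  "Drug", "Drug", "Drug",
                  "Drug", "Drug", "Drug", "Measurement", "Device"),
    vocabulary_id = c("SNOMED", "SNOMED", "SNOMED",
                      "RxNorm", "RxNorm", "RxNorm",
                      "RxNorm", "RxNorm", "RxNorm", "SNOMED", "SNOMED"),
    standard_concept = c("S", "S", "", "S", "S", "S",
                         "S", "S", "S", "S", "S"))
  ingredient <- data.frame(
    concept_id =            c(20L, 21L, 21L, 22L, 22L),
    ingredient_concept_id = c(10L, 10L, 11L, 21L, 12L))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  cp <- file.path(dir, "CONCEPT.csv")
  ip <- file.path(dir, "CONCEPT_INGREDIENT.csv")
  utils::write.csv(concept, cp, row.names = FALSE)
  utils::write.csv(ingredient, ip, row.names = FALSE)
  read_vocabulary(cp, ip)
}

# Independent dynamic-programming Levenshtein distance (the package
# uses utils::adist; this one is hand-rolled so the two routes are
# independent).
lev_dp <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  d <- matrix(0L, na + 1L, nb + 1L)
  d[, 1L] <- 0:na; d[1L, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    cost <- if (ca[i] == cb[j]) 0L else 1L
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + cost)
  }
  d[na + 1L, nb + 1L]
}

# The package's declared similarity recomputed independently of
# term_similarity(): 0.7 * char-level + 0.3 * token-set, exact match 1.
sim_oracle <- function(term, name) {
  if (term == name) return(1)
  cs <- 1 - lev_dp(term, name) / max(nchar(term), nchar(name), 1L)
  ta <- strsplit(term, " ")[[1]]; tb <- strsplit(name, " ")[[1]]
  ts <- length(intersect(ta, tb)) / length(union(ta, tb))
  0.7 * cs + 0.3 * ts
}

# small, fast generator configuration used across tests
small_gen_config <- function(seed = 11, n_patients = 250, ...) {
  generator_config(
    n_patients = n_patients, n_practices = 6,
    records_per_table = c(reason_for_visit = 600, history = 500,
                          medications = 900, immunisations = 150,
                          allergic_reactions = 100, tests = 400),
    seed = seed, ...)
}

# generate + harmonise in one step
harmonised_cohort <- function(cfg, dir) {
  gen <- generate_cohort(cfg, dir)
  raws <- lapply(names(gen$dirs), function(dl) {
    suppressWarnings(read_dialect(gen$dirs[[dl]], dl))
  })
  list(gen = gen, staging = harmonise(raws))
}

# hash every file under a directory (relative path -> sha256)
dir_hashes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(vapply(files, hash_file, character(1)),
                  substring(files, nchar(dir) + 2L))
}
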