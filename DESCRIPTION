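Package: omopforge
Title: Harmonise Free-Text Primary-Care EMR Extracts into the OMOP Common
    Data Model and Score Them with Kahn-Framework Quality Checks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for converting heterogeneous,
    free-text-heavy primary-care electronic medical record (EMR) extracts
    into a subset of the OMOP Common Data Model (CDM) v5.4.  Includes a
    synthetic three-dialect EMR generator with ground truth and injectable
    data defects; term normalisation, pack-size stripping, direct and fuzzy
    vocabulary matching with frequency-threshold prioritisation and record
    coverage statistics; dialect harmonisation into unified staging tables
    with hash-based pseudonymisation; an ETL stage with an active-patient
    filter, dated/undated condition routing and ingredient splitting for
    combination drugs; and a Kahn-framework data-quality engine
    (plausibility, conformance, completeness x verification, validation)
    with threshold-based pass/fail reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
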