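# Shared constants (this file is collated before the module files).

# logical EMR source tables carrying mappable free-text terms
.source_tables <- c("reason_for_visit", "history", "medications",
                    "immunisations", "allergic_reactions", "tests")

.logical_tables <- c("patients", "visits", .source_tables)

.defect_kinds <- c("dob_sentinel_1900", "missing_gender",
                   "missing_event_date", "future_event_date",
                   "orphan_event", "misspelled_term")

.domains <- c("Condition", "Observation", "Measurement", "Procedure",
              "Drug", "Device")

# OMOP CDM event tables populated by the ETL
.cdm_event_tables <- c("VISIT_OCCURRENCE", "CONDITION_OCCURRENCE",
                       "OBSERVATION", "MEASUREMENT",
                       "PROCEDURE_OCCURRENCE", "DRUG_EXPOSURE",
                       "DEVICE_EXPOSURE")

.cdm_tables <- c("PERSON", .cdm_event_tables, "CDM_SOURCE")

# OMOP standard gender concept identifiers
.gender_concepts <- c(female = 8532L, male = 8507L)
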