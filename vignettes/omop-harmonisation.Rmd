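---
title: "Harmonising free-text primary-care EMR data into the OMOP CDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonising free-text primary-care EMR data into the OMOP CDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Australian general practices run several proprietary EMR systems, each
with its own schema, date conventions and coding habits, and much of the
clinically relevant content — reasons for visit, history entries,
medication names — lives in free text. Making such data usable for
observational research requires three things: harmonising the dialects
into one logical schema, mapping the free-text terms onto standard
vocabularies (SNOMED-style concepts for conditions, RxNorm-style
concepts for drugs), and measuring how trustworthy the resulting
database is. `omopforge` implements that whole pathway against a subset
of the OMOP Common Data Model v5.4, together with a synthetic
three-dialect EMR generator that supplies ground truth for every stage.

## Frequency-threshold mapping

The volume of distinct free-text terms (tens of thousands of distinct
medication strings in a production repository) makes exhaustive manual
mapping impractical. Term frequency, however, is heavily skewed: a small
head of frequent terms accounts for most records. The mapping stage
therefore ranks distinct normalised terms by record frequency and sends
only terms at or above a per-table threshold to the review queue. The
threshold is inclusive ("n times or more"). Given a target coverage
fraction `p`, `threshold_for_target_coverage()` returns the largest
threshold `t` such that terms with frequency ≥ `t` jointly cover at
least `p` of all records; `record_coverage()` then reports the achieved
record-level coverage, with percentages rounded half-up to one decimal
(the convention used in published coverage tables). Unmapped terms are
never dropped: they keep `status = "unmapped"` and flow into the CDM
with concept id 0 and the verbatim source value, the standard OMOP
convention.

Default per-table thresholds are the workflow's operating points:
reason-for-visit 50, history 100, medications 200, immunisations 5,
allergic reactions 20, tests 300. At production scale (~51 million drug
exposure records) the medications threshold of 200 covers about 97% of
records; at desk scale the absolute thresholds are far more aggressive
relative to volume, which is why the coverage-driven
`threshold_for_target_coverage()` is the recommended way to pick a
threshold for small cohorts.

Term normalisation lowercases, replaces punctuation with spaces and
collapses whitespace; it is idempotent. For medications, a trailing
pack-size token (`"x 5"`, `"30 pack"`, or a final bare integer after a
form word) is stripped before matching because pack size defeats
vocabulary text matching; strength tokens attached to their units
(`500mg`, `10ml`, `100iu`) are protected. The exact normalisation
grammar is a declared convention of this package, not a reconstruction
of any production pipeline's cleaning rules.

Matching is two-stage. `direct_match()` requires exact equality of
normalised names, prefers standard concepts, and breaks ties toward the
lowest concept id so results are total-ordered and reproducible.
`suggest_candidates()` ranks fuzzy candidates by a similarity in
`[0, 1]`, a 0.7/0.3 blend of character-level normalised Levenshtein
similarity and token-set overlap. The character component is what lets
a single-character misspelling of a single-token drug name rank its
true concept first (a pure token-set measure scores zero there); the
token component rewards reordered multi-word terms. Exact matches score
exactly 1. In the pipeline, a frequent term that fails direct match is
auto-assigned to its best candidate only at similarity ≥ 0.85, standing
in for a human mapper's decision; anything weaker stays unmapped.

Combination medicines are expanded by `split_ingredients()`, which
follows ingredient links transitively and emits one drug-exposure row
per constituent ingredient, so a two-ingredient product contributes two
rows rather than one unmappable code.

## The active-patient rule

Clinical-indicator reporting uses "active patients" as its denominator:
at least 3 visits within any 2-year period. Applied alone this excludes
genuinely current patients with a single recent visit, so a recency
clause admits anyone with at least one visit in the last 2 years. The
rule is implemented with fixed-day arithmetic — "2 years" is exactly
730 days, boundaries inclusive — because the publication-level
definition does not fix the window arithmetic and fixed days make the
independent brute-force oracle unambiguous. Visits strictly after the
reference date `as_of` are ignored everywhere, which prevents
future-dated data defects from activating patients. The window clause
has no recency requirement of its own: a patient with three clustered
visits years ago remains active under the stated definition, and the
implementation follows that definition rather than "correcting" it.
Visits are pooled across a patient's practices; the practice-scoped
alternative is noted as a possible configuration but not implemented as
a switch.

`is_active()` is the production path (sorted dates, O(n) window scan);
the generator computes its activity ground truth with a deliberately
independent O(n²) scan over all anchor dates, and the test suite holds
the two equal on 1,000 random histories plus a full synthetic cohort.

## Routing into the CDM

Source EMRs have no table matching CONDITION_OCCURRENCE; conditions are
spread across reason-for-visit and history. The routing rule is: a
condition entry with a date is a current condition
(CONDITION_OCCURRENCE); an undated condition is a past observation
(OBSERVATION). History rows whose mapped concept is a measurement,
procedure or device go to MEASUREMENT, PROCEDURE_OCCURRENCE or
DEVICE_EXPOSURE respectively; medications go to DRUG_EXPOSURE (devices
to DEVICE_EXPOSURE); immunisations are deliberately dual-written to
both PROCEDURE_OCCURRENCE and DRUG_EXPOSURE; allergic reactions are
always observations; tests carry measurement, procedure or device
content. Every record routes to exactly one table except immunisations
(two), and the ETL log records rows in, rows kept, rows dropped (with
reason codes `orphan` and `inactive`) and rows emitted per target, so
conservation is checkable exactly. Dual-written immunisation rows are
counted separately in drug-exposure totals and flagged as such rather
than de-duplicated.

Undated records routed to OBSERVATION still need an observation date
downstream; the patient's most recent visit on or before `as_of` is
used, falling back to `as_of` itself, and every defaulted date is
logged by row reference. PERSON keeps the recorded birth year — 1900
sentinels are *not* corrected, because measuring them is the quality
stage's job — and uses the standard gender concept ids (8532 female,
8507 male, 0 otherwise). NOTE, NOTE_NLP, VISIT_DETAIL and
PAYER_PLAN_PERIOD are intentionally not populated.

The CDM is persisted as a directory of CSV tables with CDM v5.4 column
names plus JSON logs. A plain-text store keeps the pipeline's
determinism contract directly observable — two runs with the same
configuration and seed must produce byte-identical exports, and the
test suite compares file hashes to enforce it.

## Pseudonymisation

Patient and practice identifiers are replaced by SHA-256 hashes
truncated to 16 hex characters, salted, with the practice identifier
included in the patient salt so keys are scoped per practice and
cross-practice collisions are structurally impossible. This is a
hash-based stand-in for a production de-identification tool: it gives
deterministic, linkable, non-reversible keys, but performs no
probabilistic record linkage between practices.

## The quality engine

Checks are declarative: a category (plausibility, conformance,
completeness), a context (verification against internal consistency,
validation against external expectations), a target table, a predicate
and a threshold percentage. A check FAILS when its violation percentage
*strictly exceeds* the threshold — a rate exactly at the threshold
passes — and an empty denominator yields NOT_APPLICABLE, which is
excluded from pass-rate totals rather than counted as a pass (counting
empty tables as passing would inflate quality, and empty tables are a
real feature of this kind of data). Denominators are rows for row-level
checks and persons for completeness-by-person checks.

The built-in verification suite covers: birth year strictly after 1900
and not in the future (the 1900 sentinel encodes a missing date of
birth and is treated as implausible, not corrected); event dates not
before birth and not after `as_of`; measurement values within a
configured range; person foreign keys; gender concept ids in
{8532, 8507, 0}; concept ids known to the vocabulary bundle; required
date columns non-null; and per-person completeness of the main event
tables. Validation checks (for example the female share of persons, or
mean records per person) require an explicit expectations
configuration and none run by default, since meaningful external
expectations are site-specific.

The summary aggregates pass/fail counts per category × context with
half-up integer percentages, mirroring the published rendering of such
tables (2267/2322 → 98%). The default completeness threshold of zero
makes any table with less than full per-person coverage fail; that is
the intended behaviour of a strict default, and per-check threshold
overrides exist precisely because a one-size-fits-all zero is not
appropriate for primary-care data (condition tables covering ~60% of
patients are normal). The engine is an analogue of the OHDSI Data
Quality Dashboard's threshold semantics, not a port of its 3,570-check
catalogue.

## The synthetic generator

The generator emulates, at desk scale, the characteristics that make
this pathway hard: three dialects that differ only in surface form
(column names; dd/mm/yyyy vs yyyy-mm-dd vs dd-Mon-yyyy dates; F/M vs
Female/Male vs 1/2 gender codes) over one shared logical schema, so
harmonisation has real work to do without inventing unverifiable
clinical semantics; Zipf-skewed term frequencies (default exponent 1.1)
so frequency-threshold mapping has a realistic head/tail structure;
drug strings composed as brand + strength + form + pack size so
pack-size stripping is exercised; practices split 50/40/10 across the
dialects and a gender mix of roughly 54% female / 46% male with small
other/unknown remainders, matching the shape of the motivating
repository's published demographics; and injectable defects at
configurable rates — 1900 birth-date sentinels (default 5%), missing
gender (0.6%), undated events (10%, applied to the tables where
undated entries naturally occur), future-dated events (1%), orphan
events (1%) and single-character misspellings (2%). Every injected
defect is recorded in a registry, every generated term maps to a known
true concept, and activity status is computed by the independent brute
force, so downstream stages can be tested for *exact* recovery, not
just statistical agreement.

Default volumes (2,000 patients, 26,300 event rows across six tables)
are chosen for desk-scale runs: large enough for three-standard-
deviation binomial checks on the defect rates, small enough that the
full suite and an end-to-end run finish in seconds. The generator makes
no attempt at realistic clinical narratives, drug interactions or
longitudinal disease models; passing tests demonstrate the mechanics of
harmonisation, mapping, routing and quality measurement, not clinical
validity on real data. Real extracts bring challenges the generator
does not emulate — vendor-specific code systems with erroneous codes,
free text whose meaning disagrees with its code, and demographic
conflicts across visits (the harmoniser resolves those
latest-record-wins and logs the count, a choice the generator only
lightly exercises).

## Numerical and design choices

- Percentages are rounded half-up (coverage to 1 decimal, summary cells
  to integer) because published tables use half-up rendering; base R's
  banker's rounding disagrees at exact ties. Raw ratios are kept in the
  JSON outputs.
- Invalid calendar dates (e.g. 31/02/2020) degrade to "absent" with a
  logged warning instead of failing the run: the undated pathway is a
  first-class route, and a single malformed date should not abort an
  ETL.
- All tie-breaks (match preference, candidate ordering, person-id
  assignment, event ordering) are total orders, which is what makes
  byte-identical reruns possible.
- Mapping entries are produced per source table (each with its own
  threshold) and merged for the ETL with mapped status winning over
  unmapped when the same normalised term occurs in several tables.
- The month names used in the dd-Mon-yyyy dialect are a fixed English
  table, not locale-dependent formatting, so generation and parsing are
  stable across environments.
- Seeds: one integer seed drives the whole generator through a single
  RNG stream; the same configuration and seed reproduce every file
  byte-for-byte.

## Known limitations

The vocabulary bundle is a toy: structurally faithful (standard flags,
domains, ingredient relationships) but synthetic in content, so mapping
accuracy on real SNOMED/RxNorm content is out of scope. The quality
suite is representative rather than exhaustive. The pipeline targets
the populated subset of CDM v5.4, not the full 39-table DDL, and
derives no drug or condition eras. Record linkage across practices and
FHIR-based mapping exchange are explicitly out of scope.
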