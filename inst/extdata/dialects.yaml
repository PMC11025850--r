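# Dialect dictionaries: per-EMR-dialect file names, column names, date
# style and gender encodings.  New dialects are data-only additions here;
# no code change is needed as long as the logical schema is the same.
bp:
  date_style: dmy_slash
  files:
    patients: PATIENTS.csv
    visits: VISITS.csv
    reason_for_visit: REASONFORVISIT.csv
    history: HISTORY.csv
    medications: MEDICATIONS.csv
    immunisations: IMMUNISATIONS.csv
    allergic_reactions: REACTIONS.csv
    tests: INVESTIGATIONS.csv
  columns:
    default:
      row_id: RECORDID
      patient_uid: INTERNALID
      practice_id: PRACTICEID
      event_date: EVENTDATE
      term: DESCRIPTION
      source_code: BPCODE
      numeric_value: VALUE
      units: UNITS
    patients:
      name: FULLNAME
      gender: SEX
      dob: DOB
    visits:
      visit_id: VISITID
      event_date: VISITDATE
  gender:
    female: F
    male: M
    other: O
    unknown: U
md:
  date_style: iso
  files:
    patients: Patient.csv
    visits: Visit.csv
    reason_for_visit: ReasonForVisit.csv
    history: History.csv
    medications: Medication.csv
    immunisations: Immunisation.csv
    allergic_reactions: AllergicReaction.csv
    tests: Test.csv
  columns:
    default:
      row_id: RowId
      patient_uid: PatientId
      practice_id: PracticeId
      event_date: EventDate
      term: Description
      source_code: MdCode
      numeric_value: Value
      units: Units
    patients:
      name: PatientName
      gender: Gender
      dob: DateOfBirth
    visits:
      visit_id: VisitId
      event_date: VisitDate
  gender:
    female: Female
    male: Male
    other: Other
    unknown: Unknown
zedmed:
  date_style: dmon
  files:
    patients: pat.csv
    visits: vis.csv
    reason_for_visit: rfv.csv
    history: hist.csv
    medications: med.csv
    immunisations: imm.csv
    allergic_reactions: alrg.csv
    tests: tst.csv
  columns:
    default:
      row_id: rec_id
      patient_uid: pat_id
      practice_id: prac_id
      event_date: evt_date
      term: descr
      source_code: z_code
      numeric_value: val
      units: unit
    patients:
      name: pat_name
      gender: sex_code
      dob: birth_date
    visits:
      visit_id: vis_id
      event_date: vis_date
  gender:
    female: "1"
    male: "2"
    other: "3"
    unknown: "9"
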