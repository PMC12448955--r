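# Column mapping matching the synthetic generator's export schema.
id_column: accession
text_columns:
  - gross_findings
  - histopathology
  - ancillary_tests
  - diagnosis
metadata_columns:
  species: species
  sex: sex
  age_class: age_class
  submission_date: submission_date
date_format: "%Y-%m-%d"
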