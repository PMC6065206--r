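prefixes:
  hypertension:
  - I10
  - I11
  - I12
  - I13
  - I15
  - I16
  obesity: E66
  diabetes:
  - E10
  - E11
  ckd: N18
thresholds:
  bmi: 30.0
  hba1c: 6.5
  fasting_glucose: 126.0
  egfr: 60.0
  egfr_chronicity_days: 90.0
  bp_single:
    systolic: 160.0
    diastolic: 100.0
  bp_repeat:
    systolic: 140.0
    diastolic: 90.0
bp_rule: or
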