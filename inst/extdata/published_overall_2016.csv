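level,observed_pct,predicted_org_pct,predicted_ref_pct
claims_only,29.1,33.2,38.5
plus_problem_list,30.0,33.9,38.5
plus_clinical,36.0,39.5,38.5
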