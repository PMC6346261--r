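# Demonstration end-to-end run on synthetic reports: five screened drugs,
# one injected signal (nilotinib-like ROR 2.5), five strata.
seed: 20181218
output_dir: demo_run
simulate:
  n_cases: 6000
  background_event_prob: 0.05
  drugs:
    - {name: drug_a, exposure_prob: 0.04, true_ror: 1.0}
    - {name: drug_b, exposure_prob: 0.03, true_ror: 1.0}
    - {name: drug_c, exposure_prob: 0.03, true_ror: 2.5}
    - {name: drug_d, exposure_prob: 0.02, true_ror: 1.0}
    - {name: drug_e, exposure_prob: 0.02, true_ror: 1.0}
eligibility:
  require_sex: true
  require_age: true
  min_age_years: 20
term_set: bundled
screen:
  drugs: [drug_a, drug_b, drug_c, drug_d, drug_e]
  strata: [overall, male, female, 20-60s, 70-90s]
time_to_onset:
  drug: drug_c
  date_policy: impute_month_start
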