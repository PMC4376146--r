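# Example run configuration for the fairlink pipeline.
# Paths are resolved relative to the working directory of the run.
seed: 42
out_dir: fair-out
paths:
  patients: fair-out/patients.csv
  reference: fair-out/reference.csv
  links: fair-out/links.csv
  annotations: fair-out/annotations.csv
mode: per_child
cohort:
  max_age_years: 17
  sample_size: null
  area_code: null
classifier:
  reference_date: 2014-06-30
  min_age_gap_years: 15
  max_age_gap_years: 50
  tie_break_cascade:
    - [insurance, phone]
    - [insurance]
    - [phone]
normalization:
  phone_min_digits: 10
  insurance_rules:
    - {pattern: "^MCD", mode: individual_unique}
    - {pattern: "-", mode: strip_member_suffix, delimiter: "-"}
    - {pattern: ".*", mode: keep_whole}
strategy: insurance_or_phone
strategies:
  - insurance
  - phone
  - address
  - insurance_or_phone
  - insurance_phone_or_address
  - insurance_and_phone
simulation:
  n_children: 500
  p_mother_in_system: 0.802
  p_safety_net_insurance: 0.25
  p_family_insurance_number: 0.85
  p_phone_churn: 0.15
  p_multi_unit: 0.30
  p_unit_missing: 0.40
  p_stepmother: 0.05
  n_decoy_households: 2
  seed: 42
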