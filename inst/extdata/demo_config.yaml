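n_individuals: 700
age_range:
- 16.0
- 100.0
sigma_delta: 5.0
assays:
- name: metabolite_panel
  n_features: 30
  age_loading_scale: 0.05
  delta_loading_scale: 0.12
  noise_sd: 1.0
  batch_levels: 3
  batch_sd: 0.3
- name: lipidomics
  n_features: 60
  age_loading_scale: 0.12
  delta_loading_scale: 0.1
  noise_sd: 1.0
  batch_levels: 3
  batch_sd: 0.3
- name: proteomics
  n_features: 150
  age_loading_scale: 0.25
  delta_loading_scale: 0.1
  noise_sd: 1.0
  batch_levels: 4
  batch_sd: 0.3
- name: methylation
  n_features: 80
  age_loading_scale: 0.35
  delta_loading_scale: 0.08
  noise_sd: 1.0
  batch_levels: 2
  batch_sd: 0.3
risk_factors:
- name: bmi
  beta_age: 0.02
  beta_delta: 0.03
  noise_sd: 1.0
- name: sbp
  beta_age: 0.03
  beta_delta: 0.02
  noise_sd: 1.0
- name: cortisol
  beta_age: 0.012
  beta_delta: 0.015
  noise_sd: 1.0
- name: creatinine
  beta_age: 0.015
  beta_delta: 0.02
  noise_sd: 1.0
- name: crp
  beta_age: 0.015
  beta_delta: 0.04
  noise_sd: 1.0
- name: fev1
  beta_age: -0.03
  beta_delta: -0.02
  noise_sd: 1.0
- name: total_cholesterol
  beta_age: 0.018
  beta_delta: 0.02
  noise_sd: 1.0
diseases:
- name: C00-C97
  baseline_rate: 0.0003
  log_hr_age: 0.0492
  log_hr_delta: 0.0492
  prevalence_window_years: 10.0
- name: E10-E14
  baseline_rate: 0.0005
  log_hr_age: 0.0492
  log_hr_delta: 0.0492
  prevalence_window_years: 10.0
- name: I10-I15
  baseline_rate: 0.0008
  log_hr_age: 0.0492
  log_hr_delta: 0.0492
  prevalence_window_years: 10.0
- name: J09-J18
  baseline_rate: 0.0005
  log_hr_age: 0.0492
  log_hr_delta: 0.0492
  prevalence_window_years: 10.0
followup_years: 10.0
seed: 1
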