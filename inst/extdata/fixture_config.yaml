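n_individuals: 200
n_intervals: 30
arm_fractions:
  LCM: 0.5
  CDM: 0.5
baseline_cd4:
  sqrt_mean: 14.2
  sqrt_sd: 3.42
cd4_dynamics:
  drift_stable: 0.04
  drift_failing: -0.16
  drift_secondline: 0.3
  noise_sd: 0.35
  meas_sd: 0.8
  sqrt_floor: 1.0
  sqrt_cap: 18.0
failure_fraction: 0.18
event_hazards:
  who3:
  - -5.4
  - 0.3
  esoph_candida:
  - -6.7
  - 0.35
  who4_noncandida:
  - -7.0
  - 0.55
  tb_pulmonary:
  - -6.3
  - 0.25
  tb_extrapulmonary:
  - -7.4
  - 0.45
death_hazard:
  intercept: -7.72
  cd4_slope: 0.62
  who4_recent: 1.3
  secondline: -0.35
switch_behavior:
  lcm_intercept: -7.8
  cdm_intercept: -6.6
  lcm_cd4_lt100: 3.8
  lcm_cd4_lt50: 1.0
  who4_recent: 5.0
  who3_recent: 3.0
ltfu_hazard: 0.0011
substudy:
  fraction: 0.27
  entry_interval: 1
missingness:
  miss_visits: 0.02
  miss_doses: 0.08
baseline_covariates:
  center_probs:
  - 0.45
  - 0.35
  - 0.2
  regimen_probs:
  - 0.73
  - 0.17
  - 0.1
  bmi_low_prob: 0.15
  hb_low_prob: 0.06
  who4_wk24_48_prob: 0.05
  cotrim_prob: 0.7
seed: 424242
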