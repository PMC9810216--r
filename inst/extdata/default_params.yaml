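# Default simulation configuration.
#
# Two natural-history parameter sets (model_a, model_b) are shipped; runs
# report the min-max across them to emulate a cross-model outcome range.
# Values are chosen so that, without screening, lifetime clinical CRC risk
# is about 4-6% and the mean preclinical sojourn is 3-4 years; they are
# sanity-targeted defaults, not a calibration to any registry.
natural_history:
  model_a:
    baseline_log_risk_mean: 0.0
    baseline_log_risk_sd: 1.1
    age_intensity_knots:
      ages: [20.0, 50.0, 60.0, 70.0]
      log_intensity: [-7.5, -4.3, -3.9, -3.6]
    growth_time_to_10mm: {scale: 12.0, shape: 2.0}
    d0: 1.0
    d_inf: 50.0
    transition_hazard_per_mm: 2.5e-4
    sojourn: {meanlog: 1.1278, sdlog: 0.5}      # mean ~3.5 yr
    stage_probs_clinical: [0.18, 0.28, 0.29, 0.25]
    stage_shift_screen:
      - [1.00, 0.00, 0.00, 0.00]
      - [0.50, 0.50, 0.00, 0.00]
      - [0.35, 0.35, 0.30, 0.00]
      - [0.20, 0.30, 0.30, 0.20]
    crc_survival:
      type: exponential
      rate_by_stage: [0.010, 0.030, 0.089, 0.440]   # ~5-yr survival 95/86/64/11%
    lifetable: {type: gompertz, a: 3.0e-5, b: 0.095, makeham: 5.0e-4}
  model_b:
    baseline_log_risk_mean: 0.0
    baseline_log_risk_sd: 1.3
    age_intensity_knots:
      ages: [20.0, 50.0, 60.0, 70.0]
      log_intensity: [-7.8, -4.4, -4.0, -3.7]
    growth_time_to_10mm: {scale: 10.0, shape: 1.8}
    d0: 1.0
    d_inf: 50.0
    transition_hazard_per_mm: 2.6e-4
    sojourn: {meanlog: 0.9186, sdlog: 0.6}      # mean ~3.0 yr
    stage_probs_clinical: [0.22, 0.30, 0.27, 0.21]
    stage_shift_screen:
      - [1.00, 0.00, 0.00, 0.00]
      - [0.55, 0.45, 0.00, 0.00]
      - [0.40, 0.35, 0.25, 0.00]
      - [0.25, 0.30, 0.30, 0.15]
    crc_survival:
      type: exponential
      rate_by_stage: [0.010, 0.030, 0.089, 0.440]
    lifetable: {type: gompertz, a: 3.0e-5, b: 0.095, makeham: 5.0e-4}
test_characteristics:
  high_sensitivity:
    colonoscopy:
      sens_small: 0.75
      sens_medium: 0.85
      sens_large: 0.95
      sens_preclinical_crc: 0.95
      specificity: 0.86
    fit:
      sens_small: 0.05
      sens_medium: 0.10
      sens_large: 0.22
      sens_preclinical_crc: 0.74
      specificity: 0.96
  low_sensitivity:
    colonoscopy:
      sens_small: 0.65
      sens_medium: 0.75
      sens_large: 0.85
      sens_preclinical_crc: 0.90
      specificity: 0.86
    fit:
      sens_small: 0.05
      sens_medium: 0.10
      sens_large: 0.22
      sens_preclinical_crc: 0.74
      specificity: 0.96
surveillance:
  interval_high_risk: 3
  interval_low_risk: 5
  interval_clear: 10
  max_surveillance_age: 80
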