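# Default configuration: reference parameter estimates of the linked
# Mayo Clinical Score model and the designs of the five emulated
# placebo/standard-of-care trials.
#
# Times are in days inside the package; phase durations and visit spacing
# are given in weeks here and converted on ingest.  Visit spacing within
# phases was reported only as a 2-6 week range; the concrete calendar below
# (2-weekly induction, 4-weekly maintenance symptom visits; endoscopy at
# week 0, end of induction, week 32/36 and the final week) is an assumption
# of the emulation.

covariate_scope: alpha1   # covariate factors multiply alpha_1 only ("all": every cut-point)

# Exchangeable Gaussian-copula correlation of the three baseline
# subscores, calibrated once so the pooled baseline MCS SD matches the
# reported 1.63 (independent draws underdisperse: SD 1.36).
baseline_correlation: 0.5

scm_thresholds:
  forward: 3.84           # chi-square, p < 0.05, 1 df
  backward: 10.8          # chi-square, p < 0.001, 1 df

vpc:
  n_replicates: 500

sentinel: -99             # DV code for imputed post-dropout rows

parameters:
  rbsf:
    alpha1: 5.34
    df: [-2.34, -1.32, -1.37, -1.66, -2.27]
    covariates:
      - {column: BASE_RBSF, type: continuous, theta: 0.18, center: 4}
      - {column: TNF, type: categorical, theta: 0.14}
    slope_induction: 0.015      # 1/day
    slope_maintenance: 0.001    # 1/day
    omega_sq: 3.47
  endo:
    alpha1: 0.53
    df: [-2.84, -2.56]
    covariates:
      - {column: BASE_ENDO3, type: categorical, theta: 0.41}
      - {column: PDV_RBSF, type: continuous, theta: 1.63}
    slope_induction: 0.0
    slope_maintenance: 0.0
    omega_sq: 1.01
  pga:
    alpha1: 0.009
    df: [-4.56, -4.77]
    covariates:
      - {column: BASE_PGA, type: continuous, theta: 0.24, center: 2}
      - {column: PDV_MMCS, type: continuous, theta: 130}
    slope_induction: 0.016
    slope_maintenance: 0.0023
    omega_sq: 1.21
  dropout:
    intercept_induction: -1.94
    slope_induction: 0.68
    intercept_maintenance: -4.65
    slope_maintenance: 0.84

visit_spacing:
  rbsf_induction_weeks: 2
  rbsf_maintenance_weeks: 4

# Baseline subscore marginals are per-study category counts
# (RB+SF 0..6, ENDO 0..3, PGA 0..3); subjects with missing values are
# excluded from the counts.
designs:
  - study_id: IND-A
    n_enrolled: 222
    induction_weeks: 8
    tnf_prior_fraction: 0.0
    endo_visit_weeks: [0, 8]
    baseline:
      rbsf: [0, 2, 21, 47, 67, 59, 26]
      endo: [0, 1, 112, 109]
      pga: [0, 8, 155, 59]
  - study_id: MAINT-B
    n_enrolled: 256
    induction_weeks: 8
    maintenance_weeks: 44
    tnf_prior_fraction: 0.40
    endo_visit_weeks: [0, 8, 32, 52]
    baseline:
      rbsf: [1, 4, 22, 41, 65, 83, 40]
      endo: [0, 0, 138, 118]
      pga: [1, 16, 161, 78]
  - study_id: MAINT-C
    n_enrolled: 96
    induction_weeks: 8
    maintenance_weeks: 44
    tnf_prior_fraction: 0.0
    endo_visit_weeks: [0, 8, 32, 52]
    baseline:
      rbsf: [0, 2, 11, 16, 33, 29, 5]
      endo: [0, 0, 55, 41]
      pga: [0, 4, 73, 19]
  - study_id: MAINT-D
    n_enrolled: 135
    induction_weeks: 12
    maintenance_weeks: 40
    tnf_prior_fraction: 0.20
    endo_visit_weeks: [0, 12, 36, 52]
    baseline:
      rbsf: [0, 3, 16, 31, 36, 37, 11]
      endo: [0, 0, 55, 79]
      pga: [0, 5, 94, 36]
  - study_id: IND-E
    n_enrolled: 46
    induction_weeks: 8
    tnf_prior_fraction: 0.26
    endo_visit_weeks: [0, 8]
    baseline:
      rbsf: [1, 0, 6, 14, 12, 11, 2]
      endo: [0, 0, 24, 22]
      pga: [0, 1, 36, 9]

pooled_baseline:
  rbsf: [2, 11, 76, 149, 213, 219, 84]
  endo: [0, 1, 384, 369]
  pga: [1, 34, 519, 201]
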