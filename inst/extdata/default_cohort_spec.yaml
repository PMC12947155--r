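# Default synthetic cohort specification, calibrated to the study
# population's printed summaries: 108 patients (75 male / 33 female),
# cohort haematocrit 0.40 +/- 0.05, median BMI 27.2 kg/m^2, median ECV
# 0.32. Stratum slopes/intercepts are the published sex- and BMI-specific
# calibration lines (Hct-percent per HU); hct_mean/hct_sd are targets in
# Hct-percent; r_squared is the target fit strength from which the HU SD
# and residual SD are solved. The female low-BMI stratum has slope 0 and
# target R^2 of 0: no significant calibration exists there.
n_male: 75
n_female: 33
subgroups:
- sex: male
  bmi_low: -.inf
  bmi_high: 30.7
  slope: 1.16
  intercept: -17.2
  hct_mean: 40.2
  hct_sd: 5.0
  r_squared: 0.55
- sex: male
  bmi_low: 30.7
  bmi_high: .inf
  slope: 0.669
  intercept: 8.38
  hct_mean: 40.2
  hct_sd: 5.0
  r_squared: 0.55
- sex: female
  bmi_low: 22.4
  bmi_high: .inf
  slope: 0.669
  intercept: 8.19
  hct_mean: 38.7
  hct_sd: 4.0
  r_squared: 0.33
- sex: female
  bmi_low: -.inf
  bmi_high: 22.4
  slope: 0.0
  intercept: 38.7
  hct_mean: 38.7
  hct_sd: 4.0
  r_squared: 0.0
demographics:
- sex: male
  age_median: 80
  age_iqr: 10
  bmi_median: 27.6
  bmi_iqr: 7.7
  egfr_mean: 62.7
  egfr_sd: 20.3
  creat_median: 95
  creat_iqr: 34
- sex: female
  age_median: 83
  age_iqr: 7.5
  bmi_median: 25.9
  bmi_iqr: 7.3
  egfr_mean: 63.4
  egfr_sd: 17.9
  creat_median: 77
  creat_iqr: 22
ecv_median: 0.32
ecv_iqr: 0.05
dhu_blood_mean: 60
dhu_blood_sd: 8
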