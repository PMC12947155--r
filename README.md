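# synecv

Synthetic haematocrit and extracellular volume estimation from cardiac CT.

## The problem

Myocardial extracellular volume (ECV) — an imaging biomarker of diffuse
fibrosis — is computed from a registered pair of cardiac CT scans as

```
ECV = (1 − Hct) · ΔHU_myo / ΔHU_blood
```

where `ΔHU_myo` is the voxel-wise attenuation change in the LV myocardium
between baseline and late iodine-enhanced acquisitions, `ΔHU_blood` the
mean change in an eroded central blood-pool sample, and `Hct` the serum
haematocrit. The haematocrit requires same-day blood sampling — a real
barrier to routine ECV. Because red cells attenuate X-rays more than
plasma, the mean pre-contrast blood-pool attenuation itself predicts
haematocrit through a linear calibration

```
synHct [%] = slope · HU_blood + intercept
```

and this *synthetic* haematocrit can replace the blood test. The catch is
that one line does not fit everyone: the calibration differs by sex, is
modified by BMI in males (break near 30.7 kg/m²), and simply does not
exist for females below BMI 22.4.

`synecv` is for imaging scientists and biostatisticians working with
CT-derived ECV. It provides:

* the published calibration models (literature model `0.51·HU + 17.4`,
  refitted baseline `0.864·HU − 2.09`, and the three sex/BMI stratum
  lines) plus an explicitly routed, explicitly failing stratified
  dispatcher (`published_models()`, `route()`, `predict_hct()`);
* the covariate-influence procedure that selects stratifications:
  interaction-term testing (`fit_interaction()`), significance-gated bin
  enumeration (`bin_search()`), and sliding-window subgroup restriction
  (`window_search()`), with family-wise gate correction and held-out
  selection scoring by default;
* voxel-wise ECV maps from registered NIfTI volume pairs, including
  blood-pool erosion (`compute_ecv_map()`, `erode_mask()`,
  `write_ecv_map()`);
* an evaluation harness — MAE, Pearson R with Fisher-z 95% CIs — and a
  model-family comparison table (`evaluate_model()`,
  `comparison_table()`);
* a calibrated synthetic cohort and phantom generator
  (`generate_cohort()`, `generate_volume_pair()`) reproducing the study
  population's printed structure (108 patients, 75 M / 33 F, Hct
  0.40 ± 0.05, median ECV 0.32), so the entire pipeline runs and is
  tested without patient data.

Everything is tidyverse-native: cohorts are tibbles, results carry
`tidy()`/`glance()` methods, result objects have `autoplot()` methods, and
a thin command-line front end lives at `inst/cli/synecv.R`
(`generate`, `fit`, `search`, `evaluate`, `ecv-map`).

## Worked example

```r
library(synecv)
library(dplyr)

# a synthetic cohort with the study's structure
cohort <- generate_cohort(cohort_spec(), seed = 1)
count(cohort, sex)
#>   sex        n
#> 1 female    33
#> 2 male      75

# does sex modify the attenuation-haematocrit slope?
glance(fit_interaction(cohort, "sex"))
#>   covariate  beta3 p.beta3  nobs
#> 1 sex       -0.670 0.00184   108

# compare the whole calibration family on this cohort
comparison_table(cohort) |>
  select(label, mae_hct, r_hct, mae_ecv, r_ecv, n_scored, n_unroutable)
#>   label      mae_hct r_hct mae_ecv r_ecv n_scored n_unroutable
#> 1 literature  0.0382 0.624  0.0199 0.869      108            0
#> 2 baseline    0.0308 0.624  0.0165 0.878      108            0
#> 3 male        0.0299 0.714  0.0161 0.897       75           33
#> 4 male_bmi    0.0277 0.759  0.0148 0.910       75           33
#> 5 female      0.0299 0.189  0.0155 0.875       33           75
#> 6 female_bmi  0.0230 0.512  0.0114 0.948       23           85
#> 7 combined    0.0266 0.752  0.0140 0.918       98           10
```

The table reads as the method intends: refitting the baseline on the
cohort cuts haematocrit MAE from 0.038 to 0.031; sex-specific models help
males (R 0.62 → 0.71) but expose the weak female relationship (R 0.19);
restricting females to BMI > 22.4 rescues it (R 0.51); and the combined
sex- and BMI-routed model reaches R 0.75 for haematocrit and 0.92 for ECV
while honestly refusing to predict the 10 uncovered low-BMI females
(`n_unroutable`).

The stratification search recovers the injected male BMI break from data
alone:

```r
males <- generate_cohort(cohort_spec(n_male = 2000, n_female = 0), seed = 1)
bin_search(males, "bmi")
#> <bin_search_result> bmi: 2 bins (edges 30.86), score 1.000
#>   28/959 candidates retained at alpha = 5.21e-05
#>     bin    low  high     n slope intercept r_squared     p_cor
#>   1   1 -Inf    30.9  1400 1.17     -17.8      0.556 6.15e-249
#>   2   2   30.9 Inf     600 0.667      8.50     0.555 3.79e-107
```

and the ECV pipeline round-trips a phantom exactly:

```r
pair <- generate_volume_pair(0.32, hct = 0.40, dhu_blood = 60)
compute_ecv_map(pair, hct = 0.40)
#> <ecv_map> conventional (Hct 0.400)
#>   mean LV ECV 0.3200 over 50096 voxels; dHU_blood 60.00; 0 flagged

round(pearson_ci(0.68, 108), 2)   # Fisher-z 95% CI
#>  low high
#> 0.56 0.77
```

See `vignette source in vignettes/synthetic-hct-ecv.Rmd` for the model
family, the search procedure's gates and scoring, the generator's
calibration maths, and known limitations.

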