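# dsemodel

Construction and validation of multiparametric logistic models that detect
stress-induced myocardial ischemia from quantitative dobutamine stress
echocardiography (DSE) parameters.

## The problem

Visual wall-motion reading during DSE is subjective and
experience-dependent. Speckle-tracking imaging yields many per-segment
quantitative markers — longitudinal velocities (S′, E′, A′), times to peak,
longitudinal/radial systolic, post-systolic and maximal strain, strain
rates, radial displacement — but single markers have only modest accuracy.
`dsemodel` implements, end to end and fully tested, a three-step
construction that combines segment-level markers into per-patient and
per-vessel (LAD, LCX, RCA) classifiers of angiographic coronary stenosis
(≥ 50 %), and quantifies how much of the apparent accuracy survives
independent validation. It is aimed at biostatisticians and echo
researchers studying multiparametric diagnostic model building and its
overfitting behavior.

## The method

For each candidate covariate *a* — a (parameter, segment, phase) triple, plus
the visual ΔWMSI = WMSI<sub>stress</sub> − WMSI<sub>rest</sub> —:

1. **Screening.** Fit the univariable logistic model
   Pr(y = 1 | x) = φ(β₀ₐ + β₁ₐx), φ(u) = eᵘ/(1+eᵘ), on complete cases;
   keep covariates with Wald p < 0.05; compute the Youden-optimal
   classification threshold Tₐ on the fitted-probability scale.
2. **Rescaling.** Replace each raw value by
   r(x) = (p − Tₐ)/(1 − Tₐ) if p > Tₐ, else (Tₐ − p)/Tₐ, with
   p = φ(β₀ₐ + β₁ₐx), and missing values by 0 — a complete matrix with all
   entries in [0, 1].
3. **Combination.** Bidirectional AIC stepwise logistic regression over the
   rescaled matrix gives one model per endpoint (any stenosis, LAD, LCX,
   RCA).

Models are evaluated by sensitivity, specificity, PPV and NPV with Wilson
95 % CIs, compared by the CI-overlap rule. A seeded synthetic cohort
generator reproduces the cohort structure the analysis assumes (151
construction / 105 validation patients, prevalence 0.503 / 0.657, realistic
segment missingness), so everything is testable without patient data.

## Worked example

```r
library(dsemodel)
train      <- simulate_cohort(cohort_config(preset = "test", seed = 1))
validation <- simulate_cohort(cohort_config(preset = "validation", seed = 2))
train
#> <dse_cohort> 151 patients (test), 50.3% with >=1 stenotic vessel
#>   segment measurements: 47112 (3.5% missing)

study <- run_study(train, validation)
study
#> <dse_study>
#>   any: 39 features selected
#>   ...
#>         group        method       sensitivity         specificity ...
#> 1        test        visual 76.3 (65.6; 84.5)   92.0 (83.6; 96.3)
#> 2        test model_patient 72.4 (61.4; 81.2)   81.3 (71.1; 88.5)
#> ...
#> 7  validation model_patient 69.1 (57.4; 78.8)   67.6 (51.5; 80.4)
```

Each row reports a diagnostic method on one cohort: the visual wall-motion
criterion or one of the four fitted models, with percentage statistics and
95 % CIs. The characteristic pattern — the multiparametric model's apparent
(training) discrimination exceeding its validation discrimination, while the
visual reading holds steady — is the methodological point: univariable
screening of hundreds of candidates without multiplicity control followed by
stepwise selection overfits cohorts of this size.

Individual stages are exposed directly: `screen_all()`, `rescale_value()`
/ `build_matrix()`, `stepwise_fit()`, `predict_proba()`, `classify()`,
`performance()`, plus derived measures (`psi()`, `maximal_strain()`,
`wmsi()`, `delta_wmsi()`) and CSV/JSON round-trips (`write_cohort()`,
`write_model()`). A thin command-line front end lives at
`inst/scripts/dse-study.R` (`simulate`, `train`, `predict`, `evaluate`,
`report` subcommands, YAML-configured).

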