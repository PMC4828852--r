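---
title: "Multiparametric models for ischemia detection in stress echocardiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric models for ischemia detection in stress echocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsemodel)
```

## The problem

During dobutamine stress echocardiography (DSE), stress-induced myocardial
ischemia is conventionally detected by visual wall-motion reading: an
experienced echocardiographer grades each left-ventricular segment (1 normal
to 4 dyskinetic) at rest and peak stress, and calls the test positive when a
new or worsening dyssynergy appears. Speckle-tracking imaging offers an
alternative: per-segment quantitative markers — longitudinal velocities
(S', E', A'), times to peak, longitudinal and radial strain, post-systolic
and maximal strain, strain rates, radial displacement — each of which responds
to ischemia, but each of which alone has modest accuracy. `dsemodel`
implements a complete, testable version of a multiparametric construction
that combines many such segment-level markers into per-patient and
per-vessel (LAD, LCX, RCA) logistic classifiers of angiographic stenosis
(≥ 50 % lumen reduction), and evaluates them on a construction cohort and an
independent validation cohort.

## The three-step construction

**Step 1 — univariable screening.** Because velocity and deformation
amplitudes vary systematically from base to apex and wall to wall, each
candidate covariate is a (parameter, segment, phase) triple, screened
separately. For endpoint label $y$ and covariate $x_a$, a simple logistic
model $\Pr(y=1\mid x) = \varphi(\beta_{0a} + \beta_{1a} x)$ with
$\varphi(u) = e^u/(1+e^u)$ is fitted on complete cases; covariates with a
two-sided Wald $p < 0.05$ are retained. No multiplicity correction is applied
across the several hundred tests — an intentional fidelity to the original
procedure, and the reason apparent performance must be checked out of sample.
For each retained covariate an optimal classification threshold $T_a$ on the
fitted-probability scale is computed by maximizing Youden's $J$
(sensitivity + specificity − 1) over the midpoints between consecutive
distinct fitted probabilities, with midpoint tie-breaking; the equivalent
raw-scale cutoff $(\mathrm{logit}(T_a) - \beta_{0a})/\beta_{1a}$ is stored
alongside. The visual covariate, the stress-minus-rest change in wall motion
score index ($\Delta$WMSI), always enters the candidate set.

**Step 2 — rescaling with zero imputation.** Every raw value is replaced by
its rescaled logistic response. With $p = \varphi(\beta_{0a}+\beta_{1a}x)$:

$$
r(x) = \begin{cases}
\dfrac{p - T_a}{1 - T_a}, & p > T_a\\[6pt]
\dfrac{T_a - p}{T_a}, & p \le T_a
\end{cases}
\qquad
\tilde{x}_i = \begin{cases} 0, & x_i \text{ missing}\\ r(x_i), & \text{otherwise.}\end{cases}
$$

$r$ lies in $[0,1]$, vanishes exactly at $p = T_a$, is continuous across the
branch boundary, and saturates at 1 as the fitted probability approaches
0 *or* 1. Mapping missing (uninterpretable) segments to 0 — the
at-threshold, "no information" point — yields a complete matrix without
discarding patients. Two properties deserve emphasis. First, the printed
branch condition compares the linear predictor to $T_a$, but $T_a \in (0,1)$
is a probability-scale threshold; the package applies the condition to
$\varphi(\beta_0+\beta_1 x)$, the only reading under which both denominators
and the $[0,1]$ range are coherent (the literal linear-predictor comparison
is available via `strict_fidelity = TRUE`). Second, both branches are
nonnegative, so supra- and sub-threshold deviations of equal size are
indistinguishable downstream; direction information is deliberately not
recoverable from $r$ alone. This is implemented exactly as specified, and
its consequences are visible in the package's own simulations: a covariate
whose classes sit symmetrically on either side of its threshold carries
little signal after rescaling.

**Step 3 — stepwise combination.** On the complete rescaled matrix, a
stepwise logistic regression selects the final covariate subset per endpoint.
The selection criterion is unspecified in the original description; the
package defaults to bidirectional AIC from the intercept-only model, which is
reproducible and tuning-free, with classical p-value forward selection
(enter 0.05 / remove 0.10) behind `stepwise_criterion = "pvalue"`. The
stepwise search runs in compiled code (an Armadillo IRLS loop) and is
verified against `MASS::stepAIC` in the test suite. If the final model is
separated, a ridge-penalized refit (glmnet, fixed small $\lambda = 0.01$)
replaces the diverging MLE with a warning. Classification uses a default
probability cutpoint of 0.5 (ties positive), overridable per model. The four
endpoint models (any stenosis, LAD, LCX, RCA) are constructed fully
independently.

## Evaluation

Sensitivity, specificity, PPV and NPV are computed from the confusion counts
with Wilson score 95 % CIs (chosen for small-sample behavior and guaranteed
$[0,1]$ bounds; Clopper–Pearson available). Statistics with empty
denominators are reported as `NA`, never silently 0. Two methods are
compared by the CI-overlap rule: a difference is significant at the 0.05
level exactly when the 95 % CIs are disjoint (shared endpoints count as
overlap). Observer reproducibility uses the mean percentage difference,
$\mathrm{mean}\,|v_1 - v_2| / \overline{v}$, with zero-mean pairs excluded;
the absolute value makes the statistic order-invariant. Printed-style
percentages round half away from zero to one decimal. Per-vessel models are
evaluated against that vessel's label over *all* patients of a cohort, since
no subsetting rule is defined for the per-vessel denominators; this
assumption is stated here rather than buried in code.

## The synthetic cohort generator

No patient data accompany the construction, so the generator supplies
cohorts with the statistical structure the analysis assumes. Defaults
reproduce the study conditions: 151 construction / 105 validation patients;
prevalence of ≥ 1 stenotic vessel 0.503 / 0.657; segment-level missingness
2.1 % / 2.5 % at rest and 5.0 % / 5.2 % at stress, missing completely at
random per cell (only marginal uninterpretable-segment rates are reported,
so no informative missingness is modeled). Twelve apical-view segments
(6 per view) carry the 13 quantitative parameters at rest and stress; the
per-parameter means and SDs (see `dse_parameters()`) were fixed once at
values typical of speckle-tracking DSE series — e.g. longitudinal systolic
strain −18 ± 4 % at rest, S' 5.5 ± 1.2 cm/s rising under dobutamine,
time-to-peak shortening with heart rate — and are not tuned thereafter.
Diseased patients draw per-vessel stenosis labels independently
(conditional probabilities LAD 0.55, LCX 0.40, RCA 0.50, chosen to match
the observed multivessel mix of roughly 1.9 involved vessels per diseased
patient), renormalized so that at least one vessel is involved. For each
stenotic vessel, stress-phase values of the segments in its territory
(conventional ASE-style map, overridable) shift by `effect_size` stress-SDs
in the ischemic direction: strain and strain rate toward zero, times
prolonged, S' blunted, post-systolic and positive systolic strain
augmented, radial thickening and displacement reduced. The default
`effect_size = 0.8` SD represents a moderate, realistic separation — large
enough that screening finds true territory features, small enough that
single markers remain imperfect classifiers. WMSI is simulated directly at
the patient level (rest 1.02 ± 0.04; stress increment 0.25 ± 0.15 diseased
vs 0.03 ± 0.08 healthy), and visual positivity is ΔWMSI ≥ 0.13, which
yields visual sensitivity/specificity near the high-70s/high-80s seen in
practice.

What the generator does *not* emulate: within-patient correlation between
parameters and between neighboring segments (cells are conditionally
independent given disease status), informative missingness (poor windows
cluster in real patients), hemodynamic covariates, measurement drift between
cohorts, and any relationship between stenosis severity and flow physiology.
Passing tests therefore demonstrate that the *procedure* behaves as claimed
under its own assumptions — not that the model would transfer to real
patients, where correlated noise and distribution shift make validation
shrinkage worse, not better.

## Numerical choices and degenerate inputs

Univariable fits flag quasi-complete separation (non-convergence or
diverging coefficients) and exclude the covariate with a logged reason
rather than returning unstable estimates. Threshold computation requires
non-constant fitted probabilities. The threshold/raw-cutoff pair is kept
consistent to $10^{-9}$. Rescaling rejects thresholds outside $(0,1)$.
Zero-imputation is applied identically at training and prediction time, so
prediction never fails on incomplete patients; a patient with every
covariate missing receives $\varphi(\text{intercept})$. The AIC search stops
when no single addition or deletion improves AIC by more than $10^{-8}$;
model JSON serialization uses 17 significant digits so reloaded models
reproduce predictions bit-identically.

## Problem sizes used in the shipped simulations

The package's own validation studies (test suite and acceptance script) use:
null-screening calibration on four cohorts of n = 300 (≈ 1250 univariable
tests); threshold-search equivalence on 500 random instances with n ≤ 50;
stepwise selection consistency over 200 repetitions at n = 400 with one
informative (1.0 SD class shift on the rescaled scale) and nine null
features; and the overfitting study over 50 seeds at the study scale
(151/105) plus 50 seeds each at n = 50 and n = 500. These sizes give
comfortable Monte-Carlo margins for the properties asserted while keeping a
full run in the minutes range.

## The central negative finding, reproduced

With all defaults, apparent (training) performance exceeds validation
performance systematically: at n = 151 with several hundred screened
candidates and no multiplicity control, stepwise selection capitalizes on
chance, and the training Youden J overstates the validation J by a wide
margin that grows as the training cohort shrinks. The package reproduces
this qualitatively in `test-acceptance.R` and `scripts/acceptance.R`: the
multiparametric model looks excellent in the cohort it was built on and
loses most of its advantage out of sample — the methodological point the
pipeline exists to demonstrate.

```{r example, eval = FALSE}
train <- simulate_cohort(cohort_config(preset = "test", seed = 1))
validation <- simulate_cohort(cohort_config(preset = "validation", seed = 2))
study <- run_study(train, validation)
study
```

## Known limitations

* The unsigned rescaling transform discards the side of the threshold a
  value falls on; a signed variant would likely be more informative but is
  out of scope by design.
* Per-vessel evaluation denominators include all patients (assumption
  stated above).
* Only main effects enter the stepwise pool; no interactions.
* The CI-overlap significance rule is conservative relative to a paired
  test; no DeLong/McNemar comparisons are provided, matching the original
  evaluation design.
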