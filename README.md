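# wase

Composite biomechanical injury-risk scoring and its simulation-based
validation.

## The problem

Many sports injuries look less like the endpoint of gradual wear and more
like a critical transition: a biomechanical system that has been compensating
successfully crosses a tipping point and abruptly becomes injury-prone.
Classic early-warning signals of such transitions — rising variance, growing
asymmetry, loss of coordination — are measurable in gait. `wase` implements a
composite score that aggregates four such gait-level instability indices into
a single bounded risk index, and — because no real-world validation data
exist for it yet — the complete Monte-Carlo validation study that
characterizes its expected diagnostic behaviour: cohort simulation, injury
linkage, and a full evaluation battery. The intended users are biostatistics
and sports-science researchers who want to reproduce, stress-test or extend
that validation.

## The model

Each participant contributes four dimensionless, non-negative indices:

* **FV** — force variability: coefficient of variation of peak vertical
  ground reaction force across consecutive gait cycles;
* **TA** — temporal asymmetry: stance-time difference ratio;
* **LD** — load distribution: spatial pressure-distribution index;
* **BA** — bilateral asymmetry: kinematic/kinetic limb-comparison index.

The composite score is

```
WASe = (w1·FV + w2·TA + w3·LD + w4·BA) × Ω ,   clipped to [0, 1]
```

with weights `(w1, w2, w3, w4) = (0.35, 0.28, 0.22, 0.15)` derived by taking
the midpoint of each component's literature-reported contribution range
(30–40%, 25–30%, 20–25%, 10–20%) and normalizing to unit sum
(`derive_weights()`). The convergence factor

```
Ω = Σᵢ wᵢ · Vᵢ · σᵢ² / (√T · ΔH)
```

summarizes proximity to a critical transition over an observation window of
length `T` from the per-component variances `σᵢ²` and the entropy shift
`ΔH`; in cross-sectional use (one observation per participant, as in the
validation study) `Ω = 1`. Components exceeding their risk thresholds
(FV > 0.18, TA > 0.15, LD > 0.22, BA > 0.18) are flagged individually.

The validation study simulates a cohort of 1,000 virtual athletes
(stratified demographics; correlated truncated-normal components; 5% CV
multiplicative measurement noise), links injuries to scores through a
logistic model calibrated jointly to 20% incidence and expected AUC 0.89,
and evaluates the score with ROC/AUC, Youden thresholding, stratified
bootstrap CIs, 5-fold cross-validation, subgroup DeLong comparisons,
Hosmer–Lemeshow calibration and weight-sensitivity analysis. See the
methods vignette (`vignettes/wase-methods.Rmd`) for the full account.

## Worked example

```r
library(wase)

# score one participant and flag at-risk components
p <- component_profile(fv = 0.19, ta = 0.09, ld = 0.14, ba = 0.11)
compute_wase(p, default_weights())
#> WASe score: 0.1390 (raw 0.1390 x omega 1.0000, cross_sectional mode)
flag_components(p)
#> [1] "fv"

# the full validation study under the shipped defaults
st <- run_full_study(study_config())
st
#> WASe validation study (config 3bf683ff )
#>   cohort n = 1000; age 25.4 +/- 3.9; injury rate 0.206
#> Operating point (score > 0.1439): 206 cases / 794 controls
#>   auc         0.871 (95% CI 0.843-0.895)
#>   sensitivity 0.762 (95% CI 0.704-0.820)
#>   specificity 0.829 (95% CI 0.802-0.854)
#>   ppv         0.536 (95% CI 0.494-0.581)
#>   npv         0.931 (95% CI 0.915-0.945)
#>   accuracy    0.815 (95% CI 0.791-0.839)
#>   CV (5 folds): AUC 0.871 +/- 0.029
#>   Calibration: chi2 = 17.13 (df 8, p = 0.029)
#>   Weight sensitivity: max |dAUC| = 0.0016 over +/-0.05 perturbations
```

The single-seed run above shows the usual Monte-Carlo scatter (its AUC of
0.871 sits about 1.5 SD below the calibrated 0.89); averaging the headline
metrics over replicate seeds (`study_config(replicates = 20)`) concentrates
them near the calibration targets. The injury rate is the realized Bernoulli
draw around the calibrated 20%; PPV/NPV follow from sensitivity, specificity
and prevalence by Bayes' rule.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/wase.R full-study --seed 42 --out results/
Rscript inst/cli/wase.R simulate --seed 7 --out sim/       # cohort + linkage
Rscript inst/cli/wase.R evaluate --cohort sim/cohort.csv --out sim/
```

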