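---
title: "Methods: the WASe composite score and its simulation-based validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the WASe composite score and its simulation-based validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes: the scoring
model and its assumptions, the virtual-cohort generator and the injury
linkage, the evaluation battery, the numerical conventions, and the design
choices that were genuinely open. It states no result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The score

A participant's biomechanical state is summarized by four dimensionless,
non-negative instability indices — force variability (FV), temporal
asymmetry (TA), load distribution (LD), bilateral asymmetry (BA) — each of
which is, in the critical-transitions view of injury, an early-warning
signal: variance and asymmetry rise as a compensated system approaches a
tipping point. The composite score is the weighted sum

$$\mathrm{WASe} = (w_1\,\mathrm{FV} + w_2\,\mathrm{TA} + w_3\,\mathrm{LD} +
w_4\,\mathrm{BA}) \times \Omega,$$

clipped to $[0, 1]$. `compute_wase()` records whether clipping fired: the
unit bound holds algebraically only when $\Omega = 1$ and the components lie
in $[0,1]$, so saturation is surfaced rather than silent.

**Weights.** `derive_weights()` implements the two-step derivation: the
midpoint of each component's literature contribution range (FV 30–40%,
TA 25–30%, LD 20–25%, BA 10–20%) is normalized to unit sum and rounded to
two decimals. Rounding is half-to-even — the only standard rule that maps
the normalized midpoints 0.275 and 0.225 to the published 0.28 and 0.22 —
implemented on the scaled values with an explicit half test, because binary
floating point misrepresents decimal halves (`round(0.275, 2)` in R gives
0.27). If rounding breaks the unit sum, a single ±0.01 correction to the
largest weight is attempted; anything else is an error, not a silent
renormalization. The shipped default is $(0.35, 0.28, 0.22, 0.15)$.

**The convergence factor.** For windowed (dynamic) monitoring,

$$\Omega = \frac{\sum_i w_i V_i \sigma_i^2}{\sqrt{T}\,\Delta H},$$

where $V_i$ is the component's current value, $\sigma_i^2$ its variance over
the observation window, $T$ the window length (in sessions) and $\Delta H$
the entropy shift. Three conventions are ours to state: $V_i$ is taken to be
the raw current component value (the formulation does not further specify
it); $\Delta H$ and $T$ are accepted as inputs — the package deliberately
ships no entropy estimator, since none is specified and inventing one would
change the score's meaning; and a negative $\Omega$ (entropy decreasing,
i.e. the system ordering itself) is clamped to 0 and flagged, because a
bounded-below risk score cannot meaningfully go negative. $|\Delta H|$ below
`eps_h` ($10^{-6}$ by default) is an error rather than an astronomically
large score. The cohort study runs cross-sectionally — one observation per
participant leaves $\sigma_i^2$, $T$ and $\Delta H$ undefined — so there
$\Omega = 1$ throughout, and `compute_omega()` exists for windowed use only.

**Flagging.** Per-component risk thresholds (FV > 0.18, TA > 0.15,
LD > 0.22, BA > 0.18) are strict inequalities; a value exactly at threshold
is not flagged.

## The virtual cohort

`generate_cohort()` emulates the study population whose features the score
was validated against:

| Parameter | Default | Unit |
| --- | --- | --- |
| `n` | 1000 | participants |
| age | 24.5 ± 5.2, truncated to [18, 35] | years |
| sex split | 50% male | — |
| sports | running 40%, jumping 30%, cutting 30% | — |
| training | 8.5 ± 3.1, truncated at 0 | h/week |
| component means | FV 0.15, TA 0.08, LD 0.12, BA 0.10 | — |
| component SDs | 0.04, 0.03, 0.05, 0.04 | — |
| component bounds | FV [0.08, 0.25], TA [0.05, 0.20], LD [0.10, 0.28], BA [0.06, 0.22] | — |
| correlations | 0.25–0.65 (six pairs, see below) | — |
| `noise_cv` | 0.05 | — |

Design choices that were genuinely open:

* **Exact stratification.** Sex and sport could be drawn binomially /
  multinomially, but the reported population tables are exactly balanced
  (500/500; 400/300/300). We apportion counts by largest remainder and
  shuffle, which reproduces those tables for any `n` and removes a source
  of pure bookkeeping noise. Ages are truncated to [18, 35] so the two
  subgroup age bands partition the cohort.
* **The correlation matrix.** Only the range 0.25–0.65 is documented. The
  shipped default — FV–TA 0.45, FV–LD 0.35, FV–BA 0.55, TA–LD 0.25,
  TA–BA 0.65, LD–BA 0.30 — spans that range, pairs the two asymmetry
  indices most strongly, and is checked for positive definiteness at load
  time; any user matrix within the range is accepted.
* **Truncation by rejection.** Component vectors are drawn from the
  4-variate normal (`build_covariance()` gives
  $\Sigma_{ij} = \rho_{ij}\sigma_i\sigma_j$) and whole vectors are
  rejected until all four components lie inside their bounds. Clipping
  would pile probability mass onto the boundary; rejection preserves the
  joint shape inside the box. A retry cap (1000 rounds) converts
  pathological bounds into a clear "infeasible configuration" error.
  Note the box truncation is asymmetric for TA, LD and BA (their lower
  bounds sit about 1 SD below the mean, the upper bounds 3–4 SD above),
  so the realized marginal means sit slightly above the nominal means —
  the test suite checks them against an independent Monte-Carlo oracle
  rather than the univariate truncated-normal mean.
* **Measurement noise.** A 5% coefficient of variation is naturally
  multiplicative for positive ratio-scale quantities:
  `measured = latent × (1 + N(0, 0.05))`, re-truncated to the bounds by
  clamping (deterministic; the boundary atoms this creates are negligible
  at 5% CV). Scoring uses the measured components — the linkage is meant
  to act on the feature set as observed — with `use_true = TRUE` available
  for sensitivity experiments.
* **Seed discipline.** One master seed derives named substreams
  (demographics, components, noise, outcomes, folds, bootstrap, weight
  configurations) via a 32-bit FNV-1a hash, so adding or reordering stages
  never perturbs other stages' draws, and every stage is independently
  reproducible. All derived seeds stay below $2^{31}$.

What the generator does *not* emulate: sport- or sex-specific shifts in the
component distributions (subgroup differences are sampling noise by
construction — which is exactly what makes the subgroup analysis a null
check), longitudinal within-athlete dynamics, non-Gaussian tails, and any
real measurement pipeline from force plates or wearables to the four
indices. Passing tests therefore demonstrate internal consistency of the
scoring-and-evaluation machinery under the stated population model, not
real-world predictive performance.

## The injury linkage and its calibration

Outcomes are linked to scores through a logistic model on the standardized
score, $p_i = \mathrm{logit}^{-1}(\beta_0 + \beta_1 z_i)$ with
$z_i = (s_i - \bar s)/\mathrm{sd}(s)$, and `injured ~ Bernoulli(p_i)`
independently. Standardizing makes $\beta_1$ comparable across weight
configurations and cohorts.

`calibrate_linkage()` solves the two stated objectives — 20% incidence and
a strong positive score–risk relationship, which we pin down as expected
AUC 0.89 — by nested bisection: the outer loop moves $\beta_1 \in [0, 50]$
until the *expected* AUC hits its target; for each trial slope the inner
loop moves $\beta_0$ (bracket $[-20, 20]$, expanded geometrically if the
root escapes it at extreme slopes) until the mean of $p_i$ equals the
target prevalence. The expected AUC is computed without resampling: with
case weight $p_i$ and control weight $1 - p_j$ on every ordered pair
($i \ne j$),

$$\mathrm{E[AUC]} = \frac{\sum_{i \ne j} p_i (1-p_j)\,
[\,\mathbf{1}(s_i > s_j) + \tfrac12 \mathbf{1}(s_i = s_j)\,]}
{\sum_{i \ne j} p_i (1-p_j)},$$

accumulated in one pass over the sorted scores (ties handled by grouping,
self-pairs excluded). This function is non-decreasing in $\beta_1$, which
makes the outer bisection valid; the suite checks the monotonicity on a
grid, the fixed-point property of recalibration, and both residuals
($< 10^{-4}$). Bisection runs to a parameter tolerance of $10^{-6}$.

Calibration uses probabilities, not realized draws, so the achieved
prevalence and AUC are exact in expectation; a realized cohort then
scatters binomially around them (prevalence SD ≈ 1.3 percentage points at
n = 1000), which is why the acceptance checks average over 20 replicate
seeds.

## The evaluation battery

* **AUC** — midrank Mann–Whitney, identical to pair counting
  (wins + ½ ties); checked against brute-force enumeration on all small
  instances and against `pROC` on larger ones.
* **Operating point** — the published sensitivity/specificity pair comes
  with no stated thresholding rule; we adopt Youden-$J$ maximization, ties
  broken toward higher sensitivity and then lower threshold (risk
  screening prefers catching cases). Classification is strict:
  positive iff score > threshold, matching the strict component
  thresholds. PPV and NPV are reported as computed from the confusion
  matrix — i.e. Bayes-consistent with prevalence, sensitivity and
  specificity. At 20% prevalence with sensitivity ≈ 0.82 and specificity
  ≈ 0.87 Bayes' rule forces PPV ≈ 0.61 and NPV ≈ 0.95; the published
  0.79/0.89 pair is not internally consistent with its own operating
  point, so it is deliberately not matched. Metrics with zero
  denominators are reported absent (`NA`), never as 0.
* **Bootstrap CIs** — percentile intervals from B = 2000 stratified
  resamples (cases and controls separately, preserving prevalence);
  percentile was chosen over BCa as assumption-light and cheap, and the
  CIs here describe internal stability, not population inference.
  Undefined resamples are redrawn with a retry cap.
* **DeLong test** — the *unpaired* placement-value variant, because the
  compared subgroups are disjoint sets of participants:
  $\mathrm{var}(\hat A) = S_{10}/n_1 + S_{01}/n_0$ per sample and a
  two-sided normal reference for $z$. (`pROC` refers the same statistic
  to a Welch $t$; the suite checks the statistic exactly and the p-value
  to distribution-choice accuracy.)
* **Hosmer–Lemeshow** — g = 10 equal-count bins (largest-remainder sizes,
  tied probabilities kept together), $\chi^2$ over both outcome classes,
  df = g − 2. Bins with a zero expected count in either class are merged
  with a neighbor, with a message. The deciles convention matches a
  reported df of 8.
* **Cross-validation** — 5 folds stratified by outcome (at 20% prevalence
  unstratified folds risk single-class test sets). "Training" for a fixed
  formula can only mean threshold selection, so the Youden threshold is
  re-derived on each training set and applied to the held-out fold; AUC,
  sensitivity, specificity and accuracy are reported per fold with mean
  and SD.
* **Subgroups** — metrics within sex, age band (18–25 / 26–35) and sport
  at the *global* Youden threshold, mirroring deployment of one rule
  across groups; DeLong comparisons male–female, band–band, and all three
  sport pairs, with the headline sport p-value from the max-AUC vs
  min-AUC pair (a single printed p for three groups is otherwise
  underdetermined; all pairs are reported too).
* **Weight sensitivity** — the cohort draw *and* the simulated outcomes
  are held fixed; only the scoring weights vary (each weight ±0.05,
  renormalized, plus 100 random vectors uniform in the ±0.05 box around
  the defaults, renormalized — the sampling scheme for the "100
  configurations" being otherwise unspecified). Re-simulating outcomes
  would confound calibration with weighting. Because outcomes were linked
  to the default-weight score, perturbed weights can essentially only
  lower the AUC, which is the right reading of the published "< 0.03"
  stability bound.

The full study (`run_full_study()`) composes these stages and is a pure
function of (configuration, seed): outcomes are simulated once per
replicate, and neither threshold re-derivation nor weight perturbation ever
redraws them. With `replicates > 1`, headline metrics are additionally
averaged over replicate seeds; detailed tables come from the first
replicate.

## An honest note on the operating point

With a logistic linkage whose slope is calibrated on near-normal composite
scores, the case and control score distributions are approximately
location-shifted versions of one another, so the ROC curve is nearly
symmetric about its anti-diagonal and the Youden point lands where
sensitivity ≈ specificity (≈ 0.81 for an AUC-0.89 curve; the spec-side
tie-break toward sensitivity shifts the pair slightly apart). A markedly
asymmetric pair such as (0.82, 0.87) implies $J = 0.69$, which a symmetric
AUC-0.89 curve cannot reach (its maximum is ≈ 0.63). The package reports
what the specified generative design actually produces — the acceptance
suite asserts the published pair at its stated tolerance and is expected to
fail for specificity and accuracy, by design rather than by accident. The
same internal tension appears in the published PPV/NPV (see above).

## Problem sizes and runtime choices

The shipped defaults (n = 1000, B = 2000, 5 folds, 10 bins, 100 weight
configurations) are the study's own scale and run in seconds. The test
suite uses n = 40–2000 for unit checks, n = 10,000 for the
distributional-oracle checks, B = 10,000 for the bootstrap-vs-binomial
oracle, and 20 replicate seeds for the acceptance-level Monte-Carlo means —
sizes chosen so Monte-Carlo error is well inside each assertion's
tolerance.

## Known limitations

* The score's dynamic mode is only as meaningful as its inputs; no
  estimator for the entropy shift is provided, deliberately.
* The generator's Gaussian-in-a-box components cannot represent skewed or
  heavy-tailed biomechanical indices, and its injury mechanism is exactly
  the logistic model the evaluation then recovers — the study validates
  machinery, not biology.
* Calibration matches first-moment (prevalence) and pairwise-ranking
  (AUC) targets; higher-order features of the published tables (per-fold
  scatter, subgroup spreads) are emergent and only reproduced at
  Monte-Carlo tolerance.
* The Hosmer–Lemeshow statistic is computed against the linkage's own
  probabilities, so it is a null-consistency check (its χ² fluctuates
  around its degrees of freedom) rather than a test of an estimated
  model.
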