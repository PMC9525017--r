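---
title: "Regional brain-age gaps in cerebral small vessel disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional brain-age gaps in cerebral small vessel disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Cerebral small vessel disease (CSVD) is diagnosed on MRI through three
markers — white-matter hyperintensities (WMH), lacunes and cerebral
microbleeds (CMBs) — yet its cognitive consequences are heterogeneous.
One candidate explanation is *strategic brain aging*: CSVD may accelerate
structural aging in particular brain regions, and it is the regional, not
the global, excess aging that drives cognitive impairment.

`csvdbag` implements the full post-imaging analysis chain needed to test
this hypothesis on tabular grey-matter-volume (GMV) data:

1. train global and regional **brain-age models** on a healthy cohort,
2. estimate each application subject's **brain-age gap**
   (BAG = predicted − chronological age, in years; positive values mean
   advanced aging),
3. **classify CSVD** from the MRI markers by a median-split rule,
4. compare BAG between groups with **covariate-adjusted ANCOVA** under
   Bonferroni control, and
5. test whether regional BAG **mediates** the CSVD–cognition association
   with a bias-corrected and accelerated (BCa) bootstrap.

Because suitable MRI cohorts are not publicly deposited, the package
ships a synthetic-cohort generator with known ground truth; every claim
the package makes about its own statistical machinery is checked against
that ground truth by simulation.

## Brain-age models

Each model is an epsilon-insensitive support-vector regression with a
radial-basis-function kernel (`e1071::svm`, i.e. libsvm). The **global**
model uses the region-mean GMV of all atlas regions as features; one
**regional** model per region uses only that region's voxel-level GMV
features. The default atlas mirrors a common composite parcellation:
400 cortical parcels (labelled with the seven canonical functional
networks), 14 subcortical and 28 cerebellar regions — 442 in all.

Hyperparameters `C` and `gamma` are each searched over the seven values
0.001, 0.01, 0.1, 1, 10, 100, 1000 (49 pairs). Accuracy is estimated by
**nested 5-fold cross-validation**: the inner loop selects the pair with
the smallest cross-validated MAE using only the outer-training folds;
the outer loop predicts the held-out fold; pooled MAE, R² and Pearson r
are computed on the concatenated out-of-fold predictions, so no subject
is ever scored by a model that saw it. The final model is refit on the
whole training set with the pair chosen by a plain 5-fold search.

Choices the underlying study design leaves open, fixed here as:

* **Feature standardization.** Columns are z-scored with training-fold
  means and SDs before kernel evaluation (RBF distances need comparable
  scales); held-out data always reuse the training statistics. Constant
  columns get unit scale with a warning.
* **Epsilon.** The insensitive-loss width defaults to 0.1 (the library
  convention) and is recorded in the model spec.
* **Tie-breaking.** Grid ties resolve to the smallest `C`, then the
  smallest `gamma`, making selection deterministic.
* **Fold assignment.** Subjects are stratified by age decile and dealt
  into folds after one seeded shuffle, which stabilizes small-n folds.
* **No prediction-time bias correction.** Regression-to-the-mean age
  bias in BAG is handled downstream by covarying age and age² in every
  group comparison and mediation model, not by post-hoc re-regression of
  the predictions.
* **Degenerate targets.** If all training ages are equal the SVR
  solution is that constant; the model predicts it, MAE is 0, and R² is
  reported as `NaN` with a warning rather than an arbitrary number.

`nested = FALSE` skips the outer loop and reports metrics from the final
single-level search's out-of-fold predictions. These are mildly
optimistic (the selected pair has seen the whole set), which is why the
simulation experiments — where only the final model matters — use it,
while accuracy claims should come from `nested = TRUE`.

## CSVD classification

A subject is CSVD-positive when

* the WMH/TIV ratio (lesion volume normalized by total intracranial
  volume, unit-reconciled) is **at or above** the cohort's empirical
  50th percentile, and
* at least one lacune **or** one CMB is present.

The percentile uses the median-unbiased quantile convention
(`type = 8`); the convention and the realized threshold are logged with
every run, since the rule's `>=` comparison together with the
interpolation rule defines group membership exactly. The percentile is
computed on the analyzed cohort (after any exclusions).

## Group comparison

Each scope's BAG is compared between groups by ANCOVA, realized as OLS
with a single-df test on the group indicator, adjusted for chronological
age, age², sex, education years, the EFC image-quality index, TIV and
the four vascular risk flags (hypertension, diabetes, dyslipidemia,
smoking). The effect size is partial eta-squared,
η² = SS_group / (SS_group + SS_residual), computed from the partial
(drop-one) sum of squares; for the single-df group term this equals
t²/(t² + df). Regional tests use the Bonferroni threshold α/K over the
K regions tested; the global BAG — a single collapsed measure — is
tested uncorrected. All tests are two-sided.

## Mediation with BCa bootstrap

For exposure X (CSVD), mediator M (a region's BAG) and outcome Y (a
cognitive score), three OLS models are fitted, each including the
mediation covariate set (age, age², sex, education, EFC, TIV):

* `M ~ X + covs` → path *a*
* `Y ~ X + covs` → total effect *c*
* `Y ~ M + X + covs` → paths *b* and *c′*

With a shared covariate set, `c = c′ + a·b` is an exact identity of
nested least squares; the package asserts it to 1e-10 at every fit.
Including the covariates as regressors is point-equivalent to
pre-residualizing all variables on them (Frisch–Waugh–Lovell) — the test
suite verifies both routes agree — and keeps case-resampling bootstrap
valid, which is why inclusion is the implementation.

Inference resamples whole subject rows B times (default 10 000).
For each statistic θ ∈ {a, b, a·b, proportion mediated}:

* bias constant `z0 = Φ⁻¹(#{θ* < θ̂}/B)` (counts clamped away from 0 and
  B so z0 stays finite);
* acceleration `â` from the skewness of leave-one-out jackknife values;
* the BCa interval takes empirical type-7 quantiles of the replicates at
  the adjusted tail probabilities
  `Φ(z0 + (z0 + z_α)/(1 − â(z0 + z_α)))`; with z0 = â = 0 this reduces
  exactly to the percentile interval (a `method` switch restores the
  plain bias-corrected or percentile variants);
* the two-sided p-value is the smallest α at which the BCa interval
  excludes 0, found by bisection (endpoints are monotone in α).

Resamples in which X or M collapse to a constant are redrawn up to a
capped retry count, then error. The **proportion mediated**,
100·a·b/c, is reported raw — values outside 0–100 (suppression) are not
truncated — with an `undefined` flag when |c| is numerically zero, and
carries a CI but no p-value (it is a descriptive ratio, not a tested
null). A screened model is declared a significant mediation only when
*a*, *b* and *a·b* all reach p < α (configurable via `require`), which
makes the screen conservative under the null; an optional Bonferroni
family-wise flag over the number of screened models is also reported.

## The synthetic cohort generator

The generator emulates the *statistical* structure the analysis assumes,
not real MRI data:

| parameter | meaning | default | rationale |
|---|---|---|---|
| `train_age_range` | healthy cohort ages (y) | 18–92 | matches the intended training span |
| `app_age_range` | application ages (y) | 50–90 | older community cohort |
| `beta` / `slope_range` | GMV loss per year | drawn from 0.8–1.8 | plausible regional atrophy rates, varied across regions |
| `sigma_g` | voxel noise SD (GMV units) | 5 | moderate measurement noise; 0 gives the noise-free limit |
| `delta_years` | mean extra aging in affected regions of CSVD subjects (y) | 0 | the planted effect under study |
| `delta_cv` | subject-level spread of the extra aging | 0 | see below |
| marker model | lognormal WMH (age- and severity-linked), Poisson lacunes/CMBs | see `sim_config()` | produces a median-split threshold and ~15–20% CSVD prevalence |
| cognitive model | linear in covariates + planted mediation + `c_prime` | null mediation | effects planted only where an experiment needs them |

Ages are drawn uniformly over their range (only the range is specified
by the design, and uniform support is best for model fitting). CSVD
status is **not** stored as a label: markers are generated from a latent
severity coupled to age, and the classification rule applied to those
markers defines the groups — so the classifier itself is exercised
end-to-end, and ground truth records the assignment it induced.

**Why `delta_cv` exists.** If every CSVD subject received exactly the
same offset Δ, the true mediator would be a deterministic function of
group membership: in `Y ~ M + X + covs` the mediator carries no
variation beyond X, path *b* is unidentifiable, and no mediation
analysis could recover the planted proportion mediated. Real disease
severity varies between patients, so the generator scales each CSVD
subject's offsets by a multiplier drawn from N(1, `delta_cv`²) truncated
to [0, 2] — symmetric truncation keeps the mean offset at Δ. The default
0 preserves the pure-offset reading; the recovery experiments use 0.5.
A consequence of the single shared multiplier is that all planted
regions' BAGs are strongly correlated, so in a marginal per-region
screen each of them mediates — the screen is per-region by design, as in
the study it mirrors, and does not attempt to adjudicate between
correlated mediators.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: subject-level heterogeneity in global
brain aging (real BAG SDs are several years even in health; here BAG
variance comes only from measurement noise, so model fits at the
low-noise experiment settings are nearly perfect and group SDs are
small), scanner and site effects, spatially correlated voxel noise,
non-linear atrophy trajectories (a quadratic term is available but off
by default), and realistic effect-size magnitudes. The experiments
demonstrate that the estimators recover what was planted at the stated
conditions; they are not forecasts of effect sizes in any real cohort.

## Validation experiments and problem sizes

Three seeded Monte-Carlo studies back the package's statistical claims,
all at desk scale (the sizes are the package's own choice, balancing
replication count against a single-CPU run):

* **Type-I error of the a·b test**: X moves M (a ≠ 0) but M does not
  move Y (b = 0); 500 replicates of n = 200 at B = 1000 — the rejection
  rate at α = 0.05 should sit near nominal (BCa is known to run a point
  or two above it at these sample sizes).
* **Family-wise error of the regional screen**: 40-region null cohorts;
  the Bonferroni screen should flag any region in at most ~5% of
  replicates.
* **Planted-effect recovery**: 40 regions, 10 voxels each, n = 200/250,
  a mean Δ = 8 y in five regions spanning all three compartments,
  `sigma_g = 1` (low noise) and `delta_cv = 0.5`; application ages are
  capped at 75 so effective ages stay inside the training support
  instead of saturating the SVR. Across 20 replicates the screen should
  flag exactly the five planted regions, and the true proportion
  mediated (80% by construction: 100·(−0.5·8)/(−0.5·8 − 1)) should fall
  inside its 95% BCa interval in ≥90% of replicates. The experiment
  grids use a reduced hyperparameter grid (C ∈ {1, 10, 100},
  γ ∈ {0.01, 0.1}) and `nested = FALSE`, since only the final models
  matter there; the full 7×7 grid-search path is verified separately
  against exhaustive enumeration.

The same conditions (scaled to n = 400/300) drive the numbered scripts
under `analysis/`, and `scripts/acceptance.R` re-runs the whole chain
from scratch and writes its headline numbers as JSON.

## Known limitations

* The mediation model is single-level with a binary exposure; no
  moderated or multilevel mediation, and no causal sensitivity analysis.
* The BCa p-value is defined by CI inversion; other constructions give
  slightly different values at the same B.
* SVR prediction error attenuates mediation paths estimated from BAG
  (classical measurement-error bias); at the low-noise experiment
  settings the attenuation is small, but on noisier data proportions
  mediated will be biased toward zero.
* The screen treats regions marginally; correlated regional BAGs yield
  correlated mediation findings.
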