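---
title: "Deriving latent neuropsychiatric dimensions: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving latent neuropsychiatric dimensions: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npdim)
```

## The problem

Population cohorts collect dozens of overlapping mental-health questionnaires
(depressive symptoms, anxiety, trauma exposure, alcohol use, ...). Their
composite scores are strongly intercorrelated, which frustrates any attempt to
relate an individual instrument to disease risk. `npdim` addresses this by
reducing ordinal item responses to a small number of correlated latent
dimensions via exploratory factor analysis (EFA), checking that the same
dimensions exist in each diagnostic group (healthy controls, a cerebrovascular
disease control group, and Parkinson's disease), projecting comparable scores
for everyone, and then relating those scores to age, time since diagnosis,
subcortical imaging phenotypes, genotype carrier status, and cognitive/motor
measures.

Because the motivating data (a large access-restricted biobank) cannot ship
with the package, a synthetic cohort generator with fully known ground truth
stands in for it. The generator is first-class, tested code: every downstream
stage is validated by parameter recovery against the truth it encodes.

## The measurement model

The generator draws, for participant $i$, latent scores
$f_i \sim \mathcal N(\mu_{g(i)}(a_i, t_i), \Phi)$ where $g(i)$ is the group,
$a_i$ age, $t_i$ time since diagnosis (negative before diagnosis, `NA` for
controls), and $\Phi$ a $k \times k$ correlation matrix. Continuous item
responses follow the common factor model
$$ y_i = \Lambda f_i + \varepsilon_i, \qquad
   \varepsilon_i \sim \mathcal N(0, \Psi), $$
and are discretised to each instrument's ordinal range through fixed,
equiprobable standard-normal cut points. Fixed thresholds (rather than
per-sample quantiles) keep the item mapping deterministic given the
specification, so identical seeds reproduce cohorts bitwise.

Defaults encode a 51-item battery in 11 questionnaire blocks with
simple-structure loadings on four factors:

* **Depression** — nine depressive-symptom items, four (reverse-coded)
  well-being items, two loneliness items;
* **Anxiety** — seven generalised-anxiety items and two panic items;
* **Stress-Adversity** — five childhood-trauma items (one reverse-coded), six
  post-traumatic-stress items, two self-harm items;
* **ASRB** (alcohol- and substance-related behaviours) — ten alcohol-use
  items plus weaker-loading cannabis and addiction items.

Primary loadings run from 0.35 (addiction) to 0.78 (anxiety); $\Phi$ couples
the internalising factors strongly (0.55 Depression–Anxiety, 0.40
Depression–Stress-Adversity) and ASRB only weakly (0.10–0.15); uniquenesses
default to $1 - \lambda^2$ so continuous items have unit variance. These
values were chosen once, as a realistic transdiagnostic structure for this
battery, and are not tuned thereafter.

Group trajectories default to: controls flat at zero; the cerebrovascular
group flat but elevated on Depression (+0.25) and Stress-Adversity (+0.15)
with slightly lower Anxiety; Parkinson's disease with Depression ramping
steeply through the pre-diagnostic decade and beyond
($0.2 + 0.5\,\sigma((t+2)/2)$ in latent SD units, $\sigma$ the logistic),
ASRB declining with progression, and modest peri-diagnostic bumps in the other
two factors. Diagnosed groups mix prevalent and incident cases (42% and 57%
prevalent for the two patient groups), so a configurable fraction of
participants sits pre-diagnosis at questionnaire time.

Per-group age distributions (63.9 ± 7.7, 68.5 ± 6.6, 69.5 ± 5.5 years),
genotype carrier frequencies (GBA1 ≈ 4.3% in controls vs 6.8% in the disease
group; APOE4 ≈ 2%), a GBA1 main effect of −0.04 on Stress-Adversity and a
GBA1-carrier-by-age slope of −0.04 per year on ASRB mirror the study
population the generator emulates. Missingness is block-structured — a
participant skips a whole questionnaire with probability 0.05 per block,
missing completely at random by default; an optional MAR mode tilts the skip
probability with age and is off by default.

Imaging phenotypes are 23 head-size-corrected bilateral subcortical measures
(eight regions × volume/T2\*/QSM, minus the substantia-nigra volume slot,
which the segmentation pipeline the defaults emulate does not produce). Each
is a linear combination of the latent factors, centred age and a group
offset plus unit-variance noise; the default couplings encode the
qualitative pattern of interest (ASRB positively coupled to nigral and
putaminal QSM and negatively to subcortical volumes; Depression negatively
coupled to limbic T2\*; a positive disease-group offset on nigral QSM).
Clinical measures comprise four executive tasks loading 0.75–0.85 on one
latent ability (stored alongside as ground truth), grip strength and
reaction time at two visits with steeper decline in the disease group.

What the generator deliberately does **not** emulate: real biobank field
codings, item-level response distributions of the named instruments,
record-linkage artefacts, MRI images (only derived phenotypes), and
treatment effects. Passing recovery tests therefore demonstrates the
pipeline's correctness and calibration under a plausible generative model,
not robustness to every pathology of real questionnaire data.

## Item preparation

`prepare_items()` chains the preparation exactly as the analysis expects:

1. **Reverse coding** maps flagged items $x \mapsto \min + \max - x$; it is
   an involution, so re-applying it restores the raw coding.
2. **Missingness trade-off** (`threshold_tradeoff()`): for each candidate
   threshold $t$ (minimum non-missing observations per variable), the
   variables observed at least $t$ times are kept, the complete cases
   $n(t)$ over them counted, and the operating point scored as
   $\mathrm{info}(t) = v(t) \cdot n(t) / \max_{t'} n(t')$ — retained
   variables times sample size, normalised across the grid by the maximum
   complete-case count (the normalisation had to be fixed somehow; dividing
   by the grid maximum keeps the score in variable units). Ties prefer more
   variables, then the smaller threshold: reproducible, and favouring item
   coverage. Thresholds are absolute counts; values in (0, 1) are read as
   fractions of the sample and converted.
3. **Complete-case filtering** then **zero-variance removal**, each emitting
   a removal log; the pair is idempotent. No imputation anywhere — the
   pipeline is complete-case throughout.
4. **Standardisation** z-scores items against their own statistics or a
   supplied reference (see scoring below).

Composite per-questionnaire totals are available (`composite_scores()`) with
strict missing propagation — any missing constituent makes the total missing —
but they are reporting conveniences only; the factor analysis runs at item
level.

## Factor analysis

`run_efa()` chains adequacy diagnostics and extraction:

* **KMO** compares squared raw correlations against squared anti-image
  partial correlations from $R^{-1}$; values above 0.8 are treated as
  adequate. **Bartlett's sphericity** uses
  $\chi^2 = -(n - 1 - (2p+5)/6)\log\det R$.
* **Factor count**: eigenvalues of $R$ with the strict Kaiser rule
  ($\lambda > 1$); the eigenvalue series is exported as scree data and is
  advisory — the factor number is ultimately a modelling choice passed as
  `k`. At small samples the rule over-extracts because trailing sample
  eigenvalues are inflated by roughly $(1 + \sqrt{p/n})^2$; with the default
  51 items it is reliable from a few thousand complete cases upward.
* **Extraction** is minimum-residual (unweighted least squares): minimise
  $\sum_{j>k} \lambda_j^2$ of $R - \mathrm{diag}(\Psi)$ over the
  uniquenesses via `nlminb` with the analytic gradient
  $-2\sum_{j>k}\lambda_j v_{ij}^2$, starting from squared-multiple-
  correlation communalities, bounded to $[5\times10^{-4}, 1]$. If the
  optimiser fails to converge, iterated principal-axis updates serve as a
  fallback and the result is flagged, never silent.
* **Rotation** is oblimin by gradient projection on the oblique manifold
  (columns of the transformation constrained to unit norm), with
  $\gamma = 0$ (direct quartimin), no Kaiser row normalisation, tolerance
  $10^{-6}$ on the projected gradient norm, an iteration cap of 1000, and
  ten random oblique restarts besides the identity (drawn from a private
  RNG stream so rotation never perturbs the caller's random state); the
  lowest criterion value wins. These settings are echoed in the fit object
  for auditability.
* **Conventions**: factors are ordered by descending sum of squared pattern
  loadings and signed so each column's largest-magnitude loading is
  positive; names (`F1`...`F4`) are positional. Interpretive labels are
  assigned by absolute Tucker congruence against a reference loading
  template (`label_factors()`), never hard-coded by index. Oblique pattern
  coefficients may legitimately exceed 1 slightly; values beyond 1.1 are
  capped with a warning.

## Cross-group comparability and scoring

Group loadings are compared after **orthogonal Procrustes** alignment
(rotation/reflection only, from the SVD of $\Lambda_B^\top \Lambda_A$;
unscaled and untranslated). Orthogonal rather than oblique Procrustes was
chosen for uniqueness and testability, and is recorded in the output.
**Tucker congruence** is computed on the aligned loadings; absolute diagonal
values above 0.90 are read as "the same factor". Any factor whose aligned
diagonal congruence is negative is flagged for sign reversal so score
interpretation stays consistent across groups.

Factor scores use the regression method: coefficients
$W = R^{-1}\Lambda\Phi$ from the **reference group's** correlation matrix and
rotated solution — through the structure matrix $\Lambda\Phi$, because for
correlated factors that is the projection with maximal score validity;
`score_coefficients()` also accepts pattern-only projection
($W = R^{-1}\Lambda$) when `phi` is omitted. Comparison groups are, by
default, standardised against the reference group's item means and SDs, so
genuine group mean differences survive into the scores; a same-group
standardisation mode exists for sensitivity analyses, and the mode used is
recorded in the output. Which convention the motivating analyses used is not
derivable from their description, hence both are implemented and the default
documented rather than asserted.

## Conditional trajectories

`conditional_curve()` implements a sliding-window kernel estimate in
quantile space: observations are ranked, $u_i = \mathrm{rank}_i / n$, and
for each of 100 equally spaced evaluation quantiles $p_j$ the curve value is
the Gaussian-weighted mean with weights
$w_i = \exp\{-(u_i - p_j)^2 / 2\sigma^2\}$ and $\sigma = 0.20$ of the
quantile range. "20% kernel" is interpreted as the kernel SD; both the
fraction and the grid size are configurable because the convention is a
choice, not a law. Working in rank space makes the estimate invariant to any
monotone transform of the x-axis; the reported `x` per grid point is the
kernel-weighted mean of the raw x, so curves plot in natural units (years).

The default 95% band is $\pm 1.96$ weighted standard errors with effective
sample size $(\sum w)^2 / \sum w^2$; a seeded bootstrap (500 replicates) is
available for skewed outcomes, and the two agree within 20% of band width on
Gaussian data. Weighted means are computed with summation centred on the
first observation, which reduces cancellation and returns a constant input
exactly.

`group_trajectory_report()` residualises scores on age before plotting. The
residualisation is anchored on the reference group: the age regression is
fitted among controls and its prediction subtracted from everyone, so the
control curve traces the zero line by construction and patient curves read
directly as deviations from controls at the same age. Curves are produced
against age for all groups and against time since diagnosis (questionnaire
age minus the earliest recorded diagnosis age across sources; negative =
prodromal) for diagnosed groups. Groups with fewer than 10 usable
observations are skipped with a warning.

## Association models

All association models are covariate-adjusted least squares:

* `partial_correlation()` residualises both variables on the covariates and
  correlates the residuals, with $t = r\sqrt{df/(1-r^2)}$,
  $df = n - c - 2$.
* `imaging_association_grid()` runs one partial correlation per factor ×
  phenotype cell and Bonferroni-corrects over the family actually evaluated
  — with the default 4 factors × 23 phenotypes that is $m = 92$, but $m$ is
  always derived from the grid, never hard-coded.
* `linear_contrasts()` fits group contrasts (reference-coded) and genotype
  main and age-interaction effects. Age is mean-centred within the fitted
  sample before interactions are formed, decorrelating main and interaction
  terms. The motivating analyses describe mixed-effects fits; with one
  observation per participant per model the random-effects structure is
  unidentifiable, and the reported degrees of freedom indicate essentially
  fixed-effects estimates, so fixed-effects least squares is used and
  documented as an approximation, not claimed equivalent.
* `executive_composite()` reuses the one-factor extractor on z-scored task
  measures, sign-reversing time-based tasks first so higher always means
  better; scores are regression-method projections standardised to unit
  variance. A battery whose mean absolute inter-task correlation falls
  below 0.1 triggers a null-structure warning — note that on sampled data a
  minres fit to pure noise can still park a spurious (even Heywood) loading
  on one task, so the warning keys on the correlations, not the loadings.
  Degenerate, perfectly collinear batteries are scored through a
  pseudo-inverse.
* `visit_change_model()` regresses visit-3 minus visit-1 change on group,
  an above/below-median factor indicator (median computed within the
  analysed sample and logged) and covariates; unpaired rows are dropped
  with a count.

## Numerical and degenerate-input policy

Symmetric positive definiteness is checked by Cholesky; factor correlation
inputs must have unit diagonal. Near-singular correlation matrices are
rejected with a condition-number diagnostic in scoring (threshold $10^{10}$)
and KMO ($10^{12}$); the extractor's SMC start falls back to a ridge-
regularised inverse when $R$ is singular. Rank-deficient regression designs
are rejected with the aliased columns named. All stochastic components —
cohort generation, rotation restarts, bootstrap — take explicit seeds, and
the pipeline reproduces byte-identical reports under a fixed seed.

## Problem sizes in the test suite

The package's own benchmarks run at sizes chosen to make sampling error
negligible relative to the tolerances they assert: moment-matching and
missingness calibration at $n = 20{,}000$; factor-recovery congruence
($\geq 0.95$ per factor) over ten seeds at $n = 20{,}000$; cross-cohort
congruence ($> 0.90$) on two cohorts of $n = 10{,}000$; trajectory fidelity
at $n = 5{,}000$; genotype-interaction coverage over 100 replicates at
$n = 50{,}000$; and null error control over 200 replicates of the full
92-cell grid. Brute-force oracles (cofactor inversion, explicit loops,
normal equations) cross-check every statistical primitive at toy sizes.

## Known limitations

Pearson-based EFA on ordinal items attenuates loadings relative to the
latent model (roughly the product of the items' discretisation
attenuations); recovered structure is congruent with the truth, but
loading magnitudes are biased low. Polychoric correlations, parallel
analysis, confirmatory fit indices and non-regression score methods
(Bartlett, Anderson–Rubin) are deliberately out of scope. The generator's
MCAR default is more benign than real questionnaire missingness; the MAR
mode covers only a single age-driven mechanism. Mixed-effects estimation
for the longitudinal models is approximated by fixed effects, as noted
above.
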