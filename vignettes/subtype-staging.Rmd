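---
title: "Subtype and stage inference from regional atrophy: methods and design"
author: "sustainz authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype and stage inference from regional atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sustainz)
```

## The problem

Corticobasal syndrome (CBS) is clinically defined but pathologically
heterogeneous: autopsy series find corticobasal degeneration (CBD) in only
about half of cases, with progressive supranuclear palsy (PSP), Alzheimer
pathology (AD) and other processes accounting for the rest. Because
disease-modifying trials target specific proteinopathies, a way of
predicting the underlying pathology from in-vivo imaging matters. This
package implements a complete analysis pipeline that starts from regional
grey-matter volumes with scanner and demographic covariates and ends with
data-driven *spatiotemporal subtypes* of atrophy, per-scan *disease
stages*, longitudinal validation of both, and tests of whether subtypes
are enriched for particular pathologies.

The modelling core is a z-score event-based mixture model in the SuStaIn
family: disease progression is represented as an ordered sequence of
*events*, each event being one biomarker crossing one fixed z-score
threshold, and the population is modelled as a mixture of a small number
of such sequences (subtypes).

## Model

### Events, sequences and trajectories

Each of $B$ biomarkers $i$ carries increasing thresholds
$z_{i,1} < \dots < z_{i,R_i}$ (default $\{1, 2, 3\}$ z-units) and a
ceiling $z^{max}_i$ (default 5). The $N = \sum_i R_i$ threshold crossings
are ordered by a sequence $S$, a bijection from positions $1..N$ to
events, constrained so that each biomarker's thresholds appear in
increasing order. A subject at integer stage $t \in \{0..N\}$ has expected
z-score $g_i(t)$ for biomarker $i$: the piecewise-linear curve through
$(0, 0)$, each $(\mathrm{pos}(i,j), z_{i,j})$, and $(N, z^{max}_i)$ when
the biomarker's last event falls before position $N$ (when its last event
occupies position $N$ the curve is capped at that final threshold).
`trajectory_matrix()` evaluates $g$ at all integer stages.

### Likelihood

Observed z-scores are the trajectory plus independent Gaussian noise with
per-biomarker scale $\sigma_i$ (default 1, appropriate for z-scored
inputs). With a uniform prior over the $N+1$ stages, a subject with
z-vector $x$ has marginal likelihood under sequence $S$

$$P(x \mid S) = \frac{1}{N+1} \sum_{t=0}^{N} \prod_{i=1}^{B}
  \phi\!\left(x_i;\, g_i(t),\, \sigma_i\right),$$

and a $C$-subtype model with fractions $f_c$ gives
$P(x) = \sum_c f_c\, P(x \mid S_c)$. All densities are evaluated in
log-space with log-sum-exp (`subject_loglik()`, `mixture_loglik()`).
Fixing evaluation to integer stages (no within-stage integration), the
uniform stage prior, and Gaussian noise are deliberate simplifications:
they are the minimal model consistent with z-scored inputs, and every one
of them is configurable at the API level.

### Fitting

`optimize_sequence()` maximizes the (optionally responsibility-weighted)
total log-likelihood by greedy coordinate ascent: starting from a random
valid ordering, each event in turn is removed and re-inserted at the
valid position that maximizes the objective, until a full pass makes no
change; the best of `n_starts` (default 25) restarts is kept. Ties keep
the current position, which guarantees termination; all tie-breaks take
the first-encountered maximum in deterministic order. On grids small
enough to enumerate (`all_valid_sequences()`, $N \le 10$) the greedy
optimum can be checked against exhaustive search; the test suite does
this on random instances.

`fit_subtypes()` grows the mixture hierarchically. The $C$-subtype model
starts from the fitted $(C-1)$-model: each parent cluster's
maximum-likelihood members are randomly bisected, a sequence is fitted to
each half, and the resulting $C$-cluster configuration is refined by EM
(E-step: responsibilities $\propto f_c P(x \mid S_c)$; M-step: each
sequence re-optimized under its responsibilities, fractions set to mean
responsibility). The best split by post-EM log-likelihood wins, followed
by a final joint EM to convergence (relative tolerance $10^{-6}$, at most
100 iterations). Four random bisections are tried per parent: with fewer,
we observed the post-split EM occasionally settling in a symmetric local
optimum several hundred log-likelihood units below the good fit, and the
extra attempts are cheap insurance. A cluster emptied during EM is
re-seeded from the worst-fit subjects.

### Uncertainty and model selection

`mcmc_sample()` runs Metropolis-Hastings over sequences and fractions:
with probability 0.9 one random event of one random subtype is relocated
to a random valid position, otherwise the fractions take a Gaussian step
(SD 0.01) on the simplex and are renormalized; proposals are accepted
with probability $\min(1, e^{\Delta \log L})$. The first 10% of
iterations are burn-in. Retained samples give each subtype's *positional
variance diagram* (PVD): the event-by-position matrix of posterior
probabilities, whose rows sum to 1 by construction.

`cross_validate()` selects the number of subtypes: subjects (not scans)
are partitioned into $K$ seeded folds, models for $C = 1..C_{max}$ are
fitted on each training set, and
$\mathrm{CVIC}(C) = \sum_{\text{folds}} -2 \log L_{\text{test}}$
is minimized. Two practical observations from our simulations are worth
recording. First, the comparison between $C=1$ and $C=2$ on data truly
generated from one sequence is only clean when the candidate fits are
well converged: with few random restarts the two half-sequences of the
$C=2$ model disagree slightly, and their mixture acts as model averaging
that genuinely improves out-of-sample likelihood, masking the complexity
penalty. Second, any systematic misspecification — for example the few
percent of z-scale error introduced by estimating the control SD on a
finite control sample — also favours the richer model out of sample, for
the same reason. CVIC is therefore best read as "does a second subtype
explain held-out data better", not as a pure complexity penalty.

## Harmonization and z-scoring

Volumes are adjusted with a control-anchored regression: per region,
ordinary least squares of combined (left+right) volume on scanner field
strength, manufacturer, sex, age and total intracranial volume, fitted on
baseline controls only and propagated unchanged to cases
(`fit_covariate_model()`, `apply_harmonization()`). The adjusted volume
is residual plus control grand mean, keeping mm³ units interpretable.
Categorical covariates are encoded as 0/1 indicators against the
control-majority reference level; a single-level categorical raises an
explicit singular-design error. Regions are selected by Cohen's $d$
(pooled SD, $n-1$ weights) between baseline cases and controls at
$|d| \ge 0.6$, after hemisphere combination and before z-scoring — the
order is fixed here because the upstream description lists combined
regions first and selects among them. Z-scores are atrophy-positive:
$z = (\mu_{ctl} - v)/\sigma_{ctl}$, so a smaller volume maps to a larger
z. The per-scan laterality index is
$|\sum L - \sum R| / \text{total brain volume} \times 100$ over paired
regions, with total brain volume taken as the sum of all 24 regional raw
volumes (the source description does not pin this denominator down; a
per-region variant is exposed via `per_region = TRUE`).

## The synthetic cohort generator

No source imaging data are publicly available, so `generate_cohort()`
emulates the study's statistical structure with known ground truth:

* 252 controls and 135 cases by default (configurable), with age, sex,
  TIV, field strength and manufacturer drawn from realistic marginals and
  additive covariate effects on every regional volume (defaults: −0.4% of
  the region mean per year of age, +3.5% for male sex, a TIV slope
  placing ~35% of TIV variation in each region, +1% at 3T, −0.6% on GE
  scanners — magnitudes typical of volumetric covariate models).
* Cases draw a latent subtype from the mixture fractions, a latent stage
  uniformly on $0..N$, and a pathology label (CBD/PSP/AD/IDT) from a
  per-subtype mixing table whose defaults echo the observed
  pathology-by-subtype proportions.
* Latent z-scores (trajectory value plus $N(0, \sigma)$ noise, controls
  at $z \equiv 0$) become volumes via
  $v = \mu_r - z\,\sigma_r$ — atrophy lowers volume, matching the sign
  flip in z-scoring — before covariate effects are added and paired
  regions are split into left/right columns with a configurable
  per-subtype asymmetry fraction (default 0).
* Follow-ups (default: half the cases, 1–3 visits with probabilities
  0.39/0.58/0.03, 1.04 years apart) advance the latent stage by
  non-negative draws, Poisson(1.5) by default, capped at $N$. The upstream
  description gives no per-year stage-advance distribution; Poisson(1.5)
  is a pragmatic choice that produces the observed preponderance of
  advancing scans, and it is fully configurable.

Two generator design points deserve emphasis. Default sequences are
*biomarker-major*: each region crosses all its thresholds before the next
region starts. The alternative, level-major interleaving (all $z=1$
events, then all $z=2$, ...), makes "reversed orderings"
non-identifiable at the midpoint stage — both subtypes then have every
biomarker at the same threshold, and even the true model cannot exceed
~0.79 assignment accuracy in our simulations — so interleaved sequences
are available (`staged_sequence(..., interleave = TRUE)`) but not the
default for recovery studies. Second, `simulate_zscore_cohort()`
generates z-scores directly from the model, bypassing volumes and
harmonization; this is the clean setting for studying the fitting and
selection machinery in isolation, and the model-selection checks use it
for the reason given above.

What passing tests on these cohorts do **not** show: real atrophy
accumulates gradually and regions overlap in their progression
(biomarker-major sequences are a stylized extreme); measurement noise is
neither Gaussian nor homoscedastic across scanners; asymmetry in real CBD
is spatially structured rather than a uniform fraction; and real stage
occupancy is not uniform. Results on synthetic cohorts validate the
machinery, not the biology.

## Staging and validation

`assign_cohort()` assigns each scan its maximum-likelihood subtype
(argmax of $f_c P(x \mid S_c)$), then its maximum-likelihood stage under
that subtype; ties break toward the lower index/stage, and a joint
(subtype, stage) argmax is available via `joint = TRUE`. The sequential
reading matches "maximum likelihood subtype and stage" as used upstream.
Scans with ML stage 0 are *normal appearing*: they show no detectable
atrophy relative to controls, carry no subtype label in reports, and are
excluded from subtype-level post-hoc analyses (but retained in staging
outputs). Follow-up scans are z-scored with the baseline-fitted
harmonization model and assigned by the identical trained model — no
refitting.

`subtype_stability()` counts a subtypable follow-up as stable when it
keeps its baseline subtype or when a normal-appearing baseline became
subtypable; follow-ups normal-appearing at both visits leave the
denominator. `stage_progression()` classifies each follow-up against the
immediately preceding visit (advanced/same/regressed); with multiple
follow-ups per subject this convention is adopted, a baseline-vs-last
per-subject view is reported alongside, and `against = "baseline"`
switches the comparison. Denominators count follow-up comparisons
(scans); the per-subject table gives the other view.

`enrichment_test()` is Pearson's χ² without continuity correction on the
pathology-by-subtype table of subtypable baseline scans; expected counts
below 5 produce a warning, never a silent method switch.
`regional_comparison()` runs pairwise pooled-variance t-tests on all 24
baseline adjusted regional volumes between subtypes (Welch optional),
`laterality_comparison()` does the same for the laterality index across
groups and visits; all families are Bonferroni-adjusted, which preserves
the rank order of p-values.

## Numerical choices and degenerate inputs

* All likelihoods in log-space; log-sum-exp everywhere a mixture or
  stage marginal is formed.
* Greedy and EM tie-breaks: first-encountered maximum in deterministic
  iteration order; greedy moves only on strict improvement.
* EM convergence: relative log-likelihood change below $10^{-6}$ or 100
  iterations; training log-likelihood is non-decreasing (tested).
* Every stochastic routine takes a seed and restores the caller's RNG
  state; one pipeline seed fans out to per-stage seeds by fixed offsets
  so single stages can be re-run reproducibly.
* Degenerate inputs fail loudly with named offenders: unknown regions,
  missing hemisphere columns, unseen categorical levels, single-level
  categoricals, zero control SD at z-scoring, dimension mismatches,
  empty grids, K exceeding the subject count. Zero-variance groups in
  t-tests are skipped with a warning rather than producing NaN.

## Problem sizes

The test suite and the acceptance script run, on one core, with:
recovery studies of 300 cases / 252 controls over a 6-biomarker,
12-event grid (25 restarts); model selection over 10 (two-subtype) and 5
(one-subtype) seeds at 3 folds; exhaustive-search comparisons on 100
random grids with at most 5 events; and MCMC chains of a few thousand
iterations for PVD checks. The full-scale analysis scripts under
`analysis/` fit the 19-region, 57-event grid on 135 cases with 5
restarts, 2-fold CVIC and $2 \times 10^4$ MCMC iterations. All of these
sizes are choices, not limits; `fit_settings()` scales each one.

## Known limitations

* The number of subtypes recoverable from 135 cases is small; the
  three-subtype setting is supported but under-determined at that size,
  mirroring the upstream study's own caution.
* CVIC inherits the model-averaging subtlety described above; treat
  near-ties between adjacent $C$ as ties.
* $\sigma$ is fixed rather than estimated; grossly mis-scaled inputs
  (e.g. z-scores computed against a tiny control sample) shift event
  placements before they break anything visibly.
* Stage is an ordinal index along a subtype's sequence, not a time; equal
  stage increments do not correspond to equal elapsed time.
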