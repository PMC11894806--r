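# sustainz

Subtype and stage inference for regional brain atrophy with z-score
events.

## What this is for

Corticobasal syndrome (CBS) looks clinically uniform but hides several
pathologies — corticobasal degeneration (CBD), progressive supranuclear
palsy (PSP), Alzheimer pathology (AD) — that cannot be told apart
reliably in life. This package implements, as a tested and reusable R
pipeline, the analysis that infers *spatiotemporal atrophy subtypes* and
*disease stages* from regional grey-matter volumes:

1. **Harmonization** — per-region OLS of volume on scanner field
   strength, manufacturer, sex, age and TIV, fitted on controls and
   propagated to cases; hemisphere combination; Cohen's *d* ≥ 0.6 region
   selection; atrophy-positive z-scores
   *z* = (μ<sub>ctl</sub> − v)/σ<sub>ctl</sub>.
2. **Modelling** — a z-score event-based mixture (SuStaIn family): each
   biomarker *i* crosses thresholds z<sub>i,1</sub> < … <
   z<sub>i,R_i</sub>; a subtype is an ordering *S* of all N = Σ R_i
   crossings; a subject at stage *t* ∈ {0..N} has expected z-scores from
   the piecewise-linear trajectory through the event anchors, observed
   with Gaussian noise; subjects marginalize a uniform stage prior and
   mix over C subtypes:
   P(x) = Σ<sub>c</sub> f<sub>c</sub> · (N+1)<sup>−1</sup>
   Σ<sub>t</sub> Π<sub>i</sub> φ(x<sub>i</sub>; g<sup>c</sup><sub>i</sub>(t), σ<sub>i</sub>).
3. **Fitting** — greedy sequence optimization with random restarts,
   hierarchical cluster splitting with EM refinement, MCMC positional
   variance diagrams, and cross-validated selection of C by CVIC
   (Σ<sub>folds</sub> −2 log L<sub>test</sub>).
4. **Staging & validation** — maximum-likelihood subtype/stage per scan
   with the stage-0 "normal appearing" rule, longitudinal subtype
   stability and stage progression, pathology-by-subtype χ² enrichment,
   regional and laterality-index comparisons.
5. **Synthetic cohorts** — a generator with known ground truth (default:
   252 controls, 135 cases, two subtypes, 1-year follow-ups) standing in
   for the study's non-public MRI data, so the whole pipeline is testable
   offline.

Intended users: researchers in disease-progression modelling and
neuroimaging statistics who want an auditable, seedable implementation of
the full volumes-to-validation chain.

## Worked example

The `analysis/` scripts run the whole study on the default synthetic
cohort; each stage reads its predecessor's output under `results/`.

```sh
Rscript analysis/01_simulate.R    # cohort with ground truth
Rscript analysis/02_harmonize.R   # covariate adjustment + z-scores
Rscript analysis/03_fit.R         # CVIC + 2-subtype model + MCMC  (~20 min)
Rscript analysis/04_assign.R      # ML subtype/stage per scan
Rscript analysis/05_validate.R    # longitudinal + enrichment report
```

Output from a run of stages 1–2:

```
cohort: 252 controls, 135 baseline cases, 120 follow-up scans from 68 cases
latent subtypes: 63 / 72
selected 19 of 24 regions at |d| >= 0.6
control z-scores: |mean| <= 1.2e-15, |sd - 1| <= 1.1e-16
```

252/135 are the default cohort sizes; "19 of 24" is the effect-size
screen keeping the regions that carry the generator's atrophy signal
(the five no-signal regions fall below d = 0.6); control z-scores are
standardized by construction.

Stages 3–5 print the fitted model and its validation:

```
CVIC by number of subtypes:
       C1        C2
11857.881  8368.129
selected C = 2
subtype mixture model: C = 2 subtypes over 57 events
fractions: 0.539, 0.461
MCMC acceptance rate: 0.45
baseline: 1/135 normal appearing (1%)
subtype 1: 73 scans, mean subtype probability 0.99
subtype 2: 61 scans, mean subtype probability 1.00
subtype stability: 120/120 (100.0%) of subtypable follow-ups
stage progression over 120 follow-up comparisons:
    outcome  n proportion
1  advanced 74  0.6166667
2      same 15  0.1250000
3 regressed 31  0.2583333
chi-squared = 17.636, df = 3, p = 0.000523
regions differing between subtypes after Bonferroni: 13/24
```

Read: CVIC strongly prefers two subtypes over one; the fitted mixture
splits 54/46 against a 46/54 ground truth (label order is arbitrary);
the assignment is near-certain on this well-separated cohort; every
subtypable follow-up keeps its baseline subtype; and pathology labels
are strongly enriched across subtypes. A quarter of follow-ups regress
by a stage or two: the generator advances the latent stage by
Poisson(1.5) draws per visit, which on a 57-stage model is small
relative to the staging noise at σ = 1 — on noise-free data (the
acceptance checks) regressions are exactly 0%.

In code, the same pipeline is one call:

```r
library(sustainz)
res <- run_pipeline(list(out_dir = "run1", seed = 7,
                         cohort = list(n_controls = 120, n_cases = 150),
                         n_subtypes = 2,
                         fit = list(n_starts = 5, mcmc_iter = 2000)))
res$stability; res$enrichment
```

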