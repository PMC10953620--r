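---
title: "Methods: subtyping longitudinal brain atrophy from mixed-effects GMV-loss rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtyping longitudinal brain atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Parkinson's disease progresses heterogeneously: some patients deteriorate
slowly over many years while others decline rapidly across motor, cognitive
and autonomic domains. One hypothesis is that this heterogeneity is visible
in structural MRI as distinct *rates* of regional gray-matter-volume (GMV)
loss. `atrophyclust` implements a complete analysis pipeline for testing that
hypothesis on longitudinal ROI-level GMV tables: estimate each patient's
annual rate of GMV loss per region, cluster patients on those rates, check
that the clusters are stable under resampling, and ask whether the resulting
subtypes differ in clinical progression.

The pipeline consumes tidy long-format tables (one row per
subject x visit x ROI) as produced by any VBM/parcellation tool; image
processing is out of scope.

## Models

### Per-ROI rate estimation (rate model)

For each ROI, GMV is modelled with a Gaussian linear mixed-effects model
with random intercept and random follow-up-time slope per participant:

    GMV ~ 1 + age + sex + race + education + site + TIV + time + (1 + time | subject)

fitted by REML (ML available). A patient's atrophy rate for that ROI is the
fixed time coefficient plus the BLUP (conditional mean) of their slope
deviation, `subject_slopes()`. Rates are z-standardized per ROI across the
patient population (sample SD, n-1) by `standardize()`; the standardized
matrix is the clustering feature space. Two points deserve emphasis:

* *Shrinkage.* BLUPs shrink noisy per-subject slopes toward the population
  mean by the factor tau^2 / (tau^2 + sigma^2/Sxx). Subjects with few visits
  or a short span carry little slope information and are pulled to the mean,
  which is why the pipeline applies the usual inclusion rule (at least two
  scans spanning at least ~3 years) before fitting.
* *Standardization population.* The z-scoring population is the patients
  only (the clustering population); controls enter only the group-contrast
  models. A flag (`patients_only = FALSE`) includes controls for
  sensitivity analyses.

### Group contrasts (differential progression)

Differences in atrophy rates between groups (control vs subtype, subtype vs
subtype) are tested per ROI with the same model plus `time x group`; the
interaction coefficient is the difference in annual loss rates. Clinical
progression uses the same structure per score without TIV:

    score ~ 1 + age + sex + race + education + site + time x group + (1 + time | subject)

### Wald inference and degrees of freedom

Fixed effects are tested with Wald t statistics. Degrees of freedom follow a
between-within split: coefficients of subject-level covariates (age, sex,
group, ...) use `n_subjects - #(subject-level coefficients)`; coefficients
on time and on time-by-subject-level interactions — the progression
contrasts — use `n_subjects - #(slope coefficients)`; purely within-subject
terms use residual df. In a balanced random-slope design the slope contrast
is exactly a two-sample t on per-subject slopes with `n_subjects - 2` df, so
this choice makes the interaction test exactly calibrated there, while a
residual-df approximation (n_obs - rank) overstates the information in
repeated measures and is anticonservative for slope contrasts. Satterthwaite
or Kenward-Roger corrections are deliberately out of scope; at the cohort
sizes this pipeline targets (about 100 subjects) the difference is in the
third decimal of p.

### Clustering and model selection

Patients are clustered on the standardized rate matrix with Ward's
minimum-variance agglomeration on Euclidean distances over *all* ROI
dimensions (`hclust`, `ward.D2`, which squares distances as Ward's criterion
requires). The number of clusters is chosen by maximizing the
Calinski-Harabasz index over candidate k (default 2-10; the upper end is
arbitrary but CH at large k is never competitive on data of this type). A
partition with zero within-cluster dispersion returns `Inf` as a
perfect-separation sentinel. Subtype ids are assigned by descending cluster
size — subtype 1 is always the largest — with ties broken by smallest
subject id, so labels are reproducible.

The solution is validated two ways:

* `kmeans_pc_validation()` reruns the partition with k-means (50 restarts,
  seeded) on the first two principal components of the rate matrix (centered
  but not rescaled — the features are already z-scores) and reports Cohen's
  kappa after aligning labels by the maximum-trace permutation (ties toward
  identity).
* `run_jackknife()` / `run_kfold()` drop one subject (or one fold) at a
  time, recluster at the reference k, match perturbed clusters to reference
  clusters by the permutation maximizing total Dice overlap (equivalent to
  optimal assignment; enumerated, k <= 7), and record per-subtype Dice plus
  the Pearson correlation between perturbed and reference cluster-mean
  atrophy patterns. Dice is scored on reference memberships restricted to
  retained subjects (the dropped subject cannot count against agreement);
  `restrict_to_retained = FALSE` scores against full reference sets.
  Correlation p-values are Benjamini-Hochberg adjusted across all
  resamples x subtypes.

### Multiple testing

All families use Benjamini-Hochberg (`fdr_adjust()`, a validating wrapper
over `p.adjust`). Families are: per-ROI contrasts within each group pair;
clinical progression across the score battery; per-visit contrasts across
visits within each score. The choice of family is configurable because
reasonable analysts draw these boundaries differently.

## The synthetic cohort generator

Real cohorts of this kind (e.g. PPMI) are access-restricted, so the
generator is a first-class module: every downstream stage is tested against
planted truth. `ppmi_like_spec()` encodes the study conditions this package
targets:

* 161 controls and 107 patients in two latent subtypes of 63 and 44;
* 254 ROIs (200 cortical parcels tagged by lobe + 54 subcortical);
* baseline plus annual visits to year 5, visit times jittered uniformly by
  +/-0.1 y; dropout is absorbing and starts at year 4 with per-visit hazard
  0.35, emulating a cohort that already passed the minimum-follow-up
  inclusion rule (every subject retains visits 0-3) with mean follow-up of
  about 4 years;
* GMV trajectories `intercept + b0 + covariates + (rate + b1 + g) t + noise`
  with per-ROI subject deviations (intercept SD 0.3 cm^3, slope SD
  0.004 cm^3/y, correlation -0.2), a per-subject *global* slope factor `g`
  (SD 0.004 cm^3/y) shared across ROIs, and residual SD 0.05 cm^3. The
  global factor reflects a robust feature of real morphometry — atrophy
  rates correlate strongly across regions within subject — and makes
  per-ROI test statistics positively dependent, as they are in real data
  (Benjamini-Hochberg remains valid under this positive dependence);
* subtype 1 loses ~0.020 cm^3/y in prefrontal and lateral temporal parcels
  and ~0.008 cm^3/y elsewhere; subtype 2 is 0.025 cm^3/y faster everywhere
  with an extra 0.020 cm^3/y in the lateral temporal lobe and 0.010 cm^3/y
  in medial temporal, hippocampal and thalamic parcels; controls lose
  0.003 cm^3/y. Per-ROI magnitudes are order-of-magnitude choices (reported
  atrophy maps are color-coded, not numeric); the *separation* between
  subtypes (>= 3x the total random-slope SD of 0.0057) is the condition the
  recovery tests exercise.
* clinical scores follow per-group linear trajectories. Intercepts and
  annual slopes are set to the reference study's baseline characteristics
  and longitudinal-change table (e.g. MDS-UPDRS-I slopes 0.63 vs 1.26
  points/year). Noise is calibrated so that a per-group slope SE at n = 63
  over the full schedule matches the reported SE: with reported SE s, the
  between-subject slope SD is `s * sqrt(63/2)` and the residual SD is
  `s * sqrt(63 * Sxx / 2)` (Sxx = 17.5 for visits 0..5), splitting the slope
  information evenly between slope heterogeneity and measurement noise. The
  reported ESS SEs (0.01) are internally inconsistent with the reported
  non-significant p for that score; ESS noise is calibrated from an SE of
  0.15, interpolated from same-scale scores. Scores are generated
  independently of GMV given the subtype.

What the generator does **not** emulate: spatial autocorrelation beyond the
single global factor, non-linear trajectories, floor/ceiling effects in
bounded scores, missing-not-at-random dropout, site-by-time interactions,
and measurement-batch effects. Passing tests therefore demonstrate that the
machinery is correct and calibrated under a realistic linear data-generating
process, not that two subtypes exist in any particular real cohort.

## Numerical choices

* **Fitting.** Single models go through `lme4::lmer` (REML default). If the
  optimizer reports non-convergence the fit is retried from perturbed
  starting values (up to 3 times) and otherwise returned with
  `converged = FALSE`; a boundary (singular) fit is legitimate and flagged,
  in which case every subject's rate equals the fixed slope.
* **Batch fitting.** Per-ROI models share one fixed design, so the package
  builds lme4's deviance function once and swaps the response vector
  between ROIs (modular API), optimizing the 3 relative-covariance
  parameters with BOBYQA (xtol/ftol 1e-6) from the default start (unit
  variances, zero correlation) for every column — warm starts from a
  neighbouring ROI's optimum can stall on the variance boundary. Agreement
  with full `lmer` fits is tested (|delta logLik| < 1e-5 at test tolerance).
* **Rank deficiency.** `fit_lme` refuses rank-deficient fixed designs and
  names the aliased columns. Covariates constant over the modelled subset
  (e.g. a single site) are dropped by the pipeline wrappers before fitting.
* **Degenerate inputs.** Zero-variance ROI columns abort standardization
  with the ROI named; identical observations abort clustering (zero total
  dispersion); k = n partitions are rejected for the CH index; an empty
  cluster at a resampling cut marks that resample failed rather than
  propagating NaNs.
* **Seeds.** Everything stochastic (generator, k-means restarts, fold
  assignment) takes an explicit integer seed; the global RNG state is
  saved and restored, and reruns are bit-identical.

## Simulation sizes used by the test suite

The acceptance-style checks run at these operating points, chosen to finish
comfortably on a single CPU while keeping the study-scale structure:

* end-to-end recovery: 50 replicates of a 107-patient x 254-ROI cohort;
* slope recovery: 200 subjects x 5 visits, 200 replicates;
* interaction-test calibration: groups of 63 and 44, 5 visits, 1000 null
  replicates and 500 power replicates at the MDS-UPDRS-I operating point
  (slopes 0.63 vs 1.26, noise calibrated to a slope SE of 0.10 at n = 63);
* null FDR calibration: 250 replicates of a 16+16-subject, 254-ROI
  global-null cohort, scored as the false-discovery proportion of the
  per-ROI contrast table.

## Known limitations

* Wald p-values with between-within df are exact only in balanced designs;
  heavily unbalanced real cohorts may warrant Satterthwaite df (out of
  scope).
* The per-ROI models are fit independently; no spatial regularization or
  joint multivariate model is attempted, matching the target analysis.
* k-means/PCA validation uses exactly two principal components by design;
  with more than two well-separated subtypes this understates agreement.
* Cohen's d is reported on raw group values (a covariate-residualized
  variant exists behind a flag); it is an effect-size descriptor, not an
  adjusted test.
* The CSV interface assumes one ROI set shared by all subjects; atlases
  with subject-specific missing parcels must be harmonized upstream.
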