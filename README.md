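# atrophyclust

Data-driven subtyping of longitudinal brain atrophy. `atrophyclust` takes
long-format regional gray-matter-volume (GMV) tables — one row per
subject × visit × ROI, as produced by any VBM/parcellation pipeline — and
asks whether patients fall into subtypes with distinct *rates* of GMV loss,
and whether those subtypes progress differently on clinical scales. It is
aimed at neuroimaging and biostatistics groups analyzing longitudinal
cohorts (e.g. Parkinson's disease progression studies).

## What it computes

1. **Per-ROI atrophy rates.** For each region, a linear mixed-effects model

   `GMV ~ 1 + age + sex + race + education + site + TIV + t + (1 + t | subject)`

   is fit by REML; patient *i*'s rate for ROI *j* is the fixed time slope
   plus the BLUP of the subject's slope deviation,
   `β_t + b_1ij` (volume/year). Rates are z-standardized per ROI across
   patients.

2. **Subtyping.** Ward hierarchical clustering (Euclidean distance over all
   ROI dimensions) on the standardized rate matrix; the number of clusters
   maximizes the Calinski–Harabasz index
   `CH(k) = [B/(k−1)] / [W/(n−k)]`; the solution is cross-checked with
   k-means on the first two principal components via Cohen's κ.

3. **Stability.** Leave-one-out jackknife and 5-fold resampling: recluster,
   match clusters to the reference by maximum-Dice permutation, report
   per-subtype Dice `2|A∩B|/(|A|+|B|)` and spatial correlations of
   cluster-mean atrophy patterns (FDR-adjusted).

4. **Phenotype comparison.** Per-ROI `group × t` contrasts between HC and
   subtypes (difference in annual loss rates), clinical progression
   contrasts per score (`score ~ covariates + t × group + (1 + t | subject)`),
   covariate-adjusted baseline comparisons with χ² for sex, per-visit
   cross-sectional contrasts, and Cohen's d effect sizes — all with
   Benjamini–Hochberg FDR control.

A seeded synthetic-cohort generator (`ppmi_like_spec()`, `generate_cohort()`)
with planted subtype structure stands in for access-restricted clinical
data and drives the test suite.

## Worked example

```r
library(atrophyclust)

spec   <- ppmi_like_spec(seed = 20)          # 161 HC + 63/44 patients, 254 ROIs
cohort <- generate_cohort(spec)
res    <- run_pipeline(cohort$gmv, cohort$clinical, pipeline_config(seed = 21))

res$solution
#> cluster_solution: k = 2, sizes 63/44 (CH = 70.49)
res$rate_matrix
#> rate_matrix: 107 subjects x 254 ROIs (254 converged, 0 boundary)
res$kmeans_validation$kappa
#> [1] 1
res$jackknife
#> stability_report (jackknife): 107 resamples, 0 failed
#>   subtype dice_mean dice_sd cor_mean  cor_sd all_q_below_05
#> 1       1         1       0    0.993 0.00613           TRUE
#> 2       2         1       0    0.995 0.00589           TRUE
```

The clustering recovers the two planted subtypes (63 and 44 patients,
κ = 1 against k-means, Dice = 1 under the jackknife), and the clinical
progression table shows the faster-declining subtype 2:

```r
cc <- res$clinical_contrasts
cc[cc$target %in% c("updrs1", "updrs2", "gds", "hvlt_ret"),
   c("target", "slope1", "slope1_se", "slope2", "slope2_se", "beta", "q")]
#>     target slope1 slope1_se slope2 slope2_se    beta        q
#> 1   updrs1 0.8009   0.10469  1.259   0.12488  0.4579 3.57e-02
#> 2   updrs2 0.4626   0.11987  1.757   0.14311  1.2944 5.17e-09
#> 3      gds 0.0308   0.07460  0.197   0.08911  0.1661 1.95e-01
#> 4 hvlt_ret 0.0045   0.00485 -0.014   0.00579 -0.0185 4.58e-02
```

`slope1`/`slope2` are each subtype's annual rate of change in score points
per year (here e.g. MDS-UPDRS-I rising ~0.8 vs ~1.3 points/year), `beta` is
the group × time interaction (the difference in those rates), and `q` its
FDR-adjusted p-value across the score battery.

With `output_dir` set in `pipeline_config()`, every artifact is written as
tidy CSV (rate matrix, labels, CH profile, dendrogram merge table, stability
reports, contrast tables, a per-ROI t-value map for brain rendering) plus a
JSON run log capturing config, seed and versions.

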