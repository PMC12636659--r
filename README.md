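# hdphenotype

Two-tier metabolic phenotyping of maintenance hemodialysis patients in R.

Maintenance hemodialysis populations are clinically heterogeneous: dialysis
adequacy, inflammation, iron handling, mineral metabolism and intradialytic
electrolyte shifts vary widely between patients who receive nominally
identical prescriptions. `hdphenotype` implements a complete, tested
pipeline for discovering *metabolic phenotypes* — contemporaneous patient
states defined by multidimensional biomarker patterns — and for deploying
them with routine monitoring data. It is aimed at nephrology researchers
and biostatisticians working with dialysis-unit laboratory panels.

## What the package computes

**Composite indicators.** Five mechanistically motivated composites extend
the 17 routinely measured indicators to a 22-indicator panel:

- calcium–phosphorus product, Ca × P (mmol²/L²);
- inflammation–nutrition ratio, CRP (mg/L) / albumin (g/L);
- ferritin–hemoglobin ratio, ferritin (ng/mL) / hemoglobin (g/L),
  a functional-iron-deficiency signal;
- Middle-Small Molecule Clearance Index (MSMCI),
  β₂-microglobulin reduction ratio (%) × Kt/V;
- Electrolyte Disturbance Index (EDI), |ΔNa| + |ΔK| + |ΔHCO₃| (mmol/L).

**Tier 2 (discovery).** Median imputation, Yeo–Johnson transformation of
skewed variables (λ by maximum likelihood), median/IQR robust scaling,
near-zero-variance and VIF screening; Isolation Forest outlier exclusion at
a 5% contamination level; native K-means++/Lloyd clustering over k = 2…10
scored by inertia, silhouette, Calinski–Harabasz and Davies–Bouldin, with a
transparent, logged k-selection policy; bootstrap and cross-validated
stability (Rand index, adjusted Rand index); phenotype characterization by
one-way ANOVA / Kruskal–Wallis, η² effect sizes
(η² = SS_between / SS_total, banded at 0.06 and 0.14) and Z-score profiles.

**Tier 1 (deployment).** A six-parameter supervised classifier (Kt/V,
β₂M reduction rate, hemoglobin, ferritin, ferritin–hemoglobin ratio, MSMCI)
trained on the tier-2 labels via random forest, gradient boosting or SVM,
plus a hand-calculable linear scoring surrogate (re-derived weights,
rounded to two decimals).

**Synthetic cohorts.** Because no patient-level data are distributed, a
parametric generator reproduces the published per-phenotype means and SDs
of all 17 base indicators in a 236/294/677 three-component mixture
(n = 1,207), with moment-matched lognormal marginals for right-skewed labs,
truncated normals for bounded quantities, MCAR missingness and injected
6-SD contaminants. Every stage of the pipeline is exercised and tested
against this generator; see the methods vignette for what that does and
does not demonstrate about real cohorts.

## Worked example

Effect sizes can be audited straight from printed summary tables — for the
dialysis-dose row (group means 1.18/2.00/1.52, SDs 0.31/0.25/0.17, sizes
236/294/677):

```r
library(hdphenotype)
eta_squared_summary(c(1.18, 2.00, 1.52), c(0.31, 0.25, 0.17), c(236, 294, 677))
#> [1] 0.6034122
```

A full run on the default synthetic cohort, fixing k = 3 (the clinically
motivated choice; see the vignette for how the automatic policy behaves on
synthetic data):

```r
cfg <- pipeline_config(seed = 1, k_policy = list(type = "fixed", k = 3),
                       bootstrap_B = 50, cv_folds = 10)
run <- run_pipeline(cfg, out_dir = "demo_run")
cat(make_report(run), sep = "\n")
#> # Phenotyping run summary
#>
#> - Input records: 1271; excluded by outlier screening: 64; analysis cohort: 1207
#> - Chosen k = 3 (fixed-k policy)
#> - Phenotypes:
#>   - intermediate-stable: n = 710 (58.8%)
#>   - high retention-inflammatory: n = 169 (14.0%)
#>   - optimal clearance: n = 328 (27.2%)
#> - Stability: bootstrap mean ARI 0.641 (B = 50); cross-validated pooled ARI 0.925
#> - Largest effect sizes (eta-squared):
#>   - msmci: 0.798 (large)
#>   - b2m_rr: 0.629 (large)
#>   - ktv: 0.621 (large)
#>   - ferritin_hb_ratio: 0.041 (small)
#>   - ferritin: 0.036 (small)
#> - Tier-1 classifier (forest): accuracy 0.959, macro AUC 0.995, Rand concordance 0.933
```

Reading the output: 64 of 1,271 records (5.04%) are excluded by the
Isolation Forest screen, leaving the 1,207-record analysis cohort. The
three phenotypes are named deterministically by their mean MSMCI (lowest →
high retention-inflammatory, highest → optimal clearance). Clearance
indicators dominate the discrimination (large η² for MSMCI, β₂M reduction
rate and Kt/V), iron-axis indicators contribute small effects — the same
ordering reported for real cohorts. The tier-1 six-parameter classifier
reproduces the tier-2 labels on held-out records with 96% accuracy.

The run directory contains the cluster-metrics table, the serialized
phenotype model, the stability report, a publication-shaped phenotype
profile CSV, the classifier report, the HPCS weight table and a manifest;
rerunning the same configuration reproduces every artifact bit-for-bit.

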