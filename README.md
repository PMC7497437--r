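# ctqpr

Stenosis-related quantitative perfusion ratio (QPR) from dynamic CT
myocardial perfusion and coronary CT angiography, in R.

Absolute myocardial blood flow (CT-MBF, mL/g/min) estimated from dynamic
contrast-enhanced cardiac CT varies widely between individuals even in normal
myocardium, so no universal MBF cutoff reliably identifies hemodynamically
significant coronary artery disease (invasive fractional flow reserve,
FFR ≤ 0.80). The QPR normalizes each voxel's MBF by a reference MBF taken
from the same heart,

> QPR(v) = MBF(v) / MBF_ref,

so global per-patient factors cancel. Allocating every left-ventricular (LV)
voxel to its spatially nearest coronary branch (a Voronoi partition of the
myocardium by the CTA-derived coronary tree) and averaging over the
myocardium *distal to a stenosis seed point* yields the **stenosis-related
CT-MBF and CT-QPR** — vessel-specific indices that can be evaluated against
FFR with the usual diagnostic machinery (ROC/Youden, sensitivity/specificity
with CIs, correlated-AUC comparison).

The package implements the full chain as tested, reusable components:

| stage | functions |
|---|---|
| synthetic phantoms & cohort tables | `make_phantom()`, `simulate_dynamic_ctp()`, `simulate_aif()`, `simulate_tissue_curve()`, `simulate_vessel_table()` |
| voxel-wise MBF by truncated-SVD deconvolution | `compute_mbf_map()`, `deconvolve_voxel()`, `baseline_correct()`, `temporal_smooth()` |
| coronary territories | `voronoi_territories()`, `distal_subtree()`, `stenosis_territory()`, `select_culprit()`, `classify_cta()` |
| reference MBF & QPR | `reference_mbf()`, `qpr_from_mbf()`, `stenosis_related_values()`, `qpr_analysis()` |
| diagnostics vs FFR | `roc_auc()`, `youden_cutoff()`, `diagnostic_metrics()`, `compare_auc_paired()`, `icc_two_rater()`, `cv_percent()`, `binormal_auc()`, `ctqpr_evaluate()` |
| pipeline & I/O | `ctqpr_full_run()`, `ctqpr_simulate()`, NIfTI/CSV/JSON readers and writers, `inst/cli/ctqpr.R` |

No patient data are distributed; the synthetic module generates phantoms and
vessel tables with the documented two-group statistical structure
(significant vessels: MBF 1.38 ± 0.27 mL/g/min, QPR 0.71 ± 0.08;
non-significant: 1.74 ± 0.35 and 0.86 ± 0.07; prevalence 20/39), which makes
every downstream stage testable end to end. See the methods vignette
(`vignettes/ctqpr-methods.Rmd`) for the models, parameter choices and their
rationale.

## Worked example

A complete synthetic study — phantom, dynamic acquisition with CT noise,
deconvolution, territories, QPR, and the vessel-level evaluation:

```r
library(ctqpr)
run <- ctqpr_full_run(ctqpr_config(seed = 2), verbose = FALSE)

run$phantom$truth_vessel_table[, c("vessel_id", "vessel", "ffr", "true_qpr")]
#>   vessel_id vessel       ffr  true_qpr
#> 1      V001    LAD 0.5504156 0.7941419
#> 2      V002    LCX 0.9666898 1.0000000
#> 3      V003    RCA 0.8936037 1.0000000

run$qpr
#> <qpr_result> reference MBF 2.169 mL/g/min
#>   seed branch vessel stenosis_mbf stenosis_qpr territory_volume_ml
#> 1    1      1    LAD         1.86        0.855                6.29
#> 2    2      3    LCX         2.26        1.041                5.23
#> 3    3      4    RCA         2.26        1.042                5.74
```

The phantom's one FFR-positive vessel (LAD, FFR 0.55, true distal perfusion
ratio 0.79) is recovered as the clear minimum stenosis-related QPR (0.855,
pulled toward 1 by CT noise), while the FFR-negative territories sit at ~1.04.
The reference MBF (2.17) exceeds the true normal level (1.95) by the
deconvolution's systematic residue-peak overshoot — which cancels in the QPR
column; the vignette discusses this calibration in detail.

The vessel-level diagnostic report on a simulated 39-vessel cohort
(20 FFR-positive, as in the emulated study):

```r
run$report
#> <ctqpr_report> 39 vessels, 20 FFR-positive (51.3%), cutoff FFR <= 0.80
#>   MBF: AUC 0.65 (0.47-0.83), Youden cutoff 1.59, Spearman r(FFR) 0.55
#>        sens 75% (56-94), spec 58% (36-80), CV 17.8%
#>   QPR: AUC 0.93 (0.86-1.00), Youden cutoff 0.776, Spearman r(FFR) 0.82
#>        sens 80% (62-98), spec 95% (85-100), CV 11.0%
#>   paired AUC difference (MBF - QPR): -0.287, p = 0.00106
```

The ratio index correlates more strongly with FFR than absolute MBF, has the
smaller coefficient of variation, and wins the paired DeLong comparison —
with a Youden cutoff near 0.8, the same scale as FFR itself.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/ctqpr.R full-run --seed 2 --out run_out
Rscript inst/cli/ctqpr.R evaluate --table vessel_table.csv --out eval_out
```

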