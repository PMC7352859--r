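# bioperturb

Systemic biochemical perturbation profiling of case–control biomarker
panels, built around the analysis chain used in pediatric hepatic-steatosis
studies: overweight adolescents with and without ultrasound-diagnosed
steatosis, ~25 routine biochemical/hematological markers plus immunoassayed
proteins (TGF-β, HO-1), and the question of whether blood chemistry alone
can identify steatosis and quantify how disturbed a patient's biochemistry
is.

The package implements, as tested R functions:

* **Synthetic cohorts** — multivariate log-normal marker panels with
  group-specific location shifts, ordinal severity-grade slopes and
  group-specific correlation structure (`default_study_config()`,
  `generate_cohort()`); the study's patient-level data are not deposited,
  so all validation runs on these cohorts.
* **Univariate screening** — Mann–Whitney (exact ≤ 12 tie-free
  observations, corrected normal approximation otherwise), Kruskal–Wallis +
  Dunn, a Cuzick-type nonparametric linear trend test, Pearson chi-square,
  Holm–Bonferroni control, and median-ratio fold differences.
* **Ward clustering** with feature-resampling bootstrap support, and
  severity-grade profile matrices.
* **Spearman correlation networks** per clinical group with the p < 0.05
  edge rule, participant-bootstrap edge support and node-degree tables.
* **The Degree of Biochemical Perturbation (DBP)**: per-sample mean
  absolute z-deviation from the no-steatosis reference
  (z = (x − mean_ref)/sd_ref on log10 concentrations), with the
  "> reference mean + 2 SD" perturbed rule.
* **A sparse canonical-correlation discriminant**: rank-1 penalized matrix
  decomposition of XᵀY (alternating soft-thresholded updates under
  ‖u‖₂ ≤ 1, ‖u‖₁ ≤ c), canonical-coefficient ranking, resubstitution and
  leave-one-out ROC.
* **Association**: p < 0.2 univariate entry, covariate-adjusted logistic
  odds ratios per 1-log10 with separation detection, and single-marker ROC
  with DeLong CI and Youden-optimal cutoff in native units.

## Worked example

The numbered scripts under `analysis/` run the whole study chain on a
simulated default cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_univariate.R
Rscript analysis/04_perturbation.R
Rscript analysis/05_discriminant.R
```

which prints, for the shipped seed:

```
simulated 72 participants (36 control, 36 case; 18 mild, 18 moderate/severe)
median TGF-β control 23.5 vs case 53.4 pg/mL

9 of 25 markers differ after Holm adjustment:
  ...
  ALT                    fold 2.47  adj p 9.2e-10
  GGT                    fold 1.34  adj p 0.0095
  TGF-β                  fold 2.27  adj p 6.1e-09
ALT: Kruskal-Wallis p 5e-11, linear-trend z 6.80 (p 1.1e-11)

DBP score: control median 0.79, case median 1.09 (Mann-Whitney p 8.4e-09)
perturbed (> 1.06): 1/36 controls, 19/36 cases

top canonical coefficients:
        marker weight
           ALT  0.594
         TGF-β  0.538
    Hemoglobin  0.282
discriminant AUC: resubstitution 0.995 (95% CI 0.99-1.00), leave-one-out 0.992
```

Read: the case group's hallmark elevations (ALT, GGT, TGF-β) survive
familywise correction; ALT rises monotonically with ultrasound grade; cases
sit on average 1.09 reference-SDs away from the control biochemistry versus
0.79 for controls themselves (the √(2/π) baseline of a standard normal),
with 19/36 cases past the 2-SD perturbed threshold; and a sparse canonical
combination dominated by ALT and TGF-β separates the groups almost
perfectly on this cohort.

The same chain is available as one call:

```r
library(bioperturb)
report <- run_pipeline(run_config(seed = 42, output_dir = "results/run"))
report   # headline summary; per-stage CSV/JSON/GraphML/Newick + manifest.json
```

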