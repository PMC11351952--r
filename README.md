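# metabocv

Cross-validated OPLS-DA profiling of ¹H-NMR plasma metabolomes.

`metabocv` is an R package for metabolomics studies with a 2 × 2 factorial
design (e.g. genotype × diet in rodent cohorts, with groups WT/CD, WT/WD,
KO/CD, KO/WD). It implements, as tested code, the full analysis chain that
such studies typically run by hand across several tools:

1. **Spectral preprocessing** — chemical-shift referencing to the CH₃-lactate
   doublet at δ = 1.33 ppm, fixed-width 0.02-ppm binning over 0.5–9.0 ppm
   (water region 4.5–5.0 ppm excluded), total-sum normalization and Pareto
   scaling.
2. **Multivariate modelling** — PCA and two-class OPLS-DA written from
   scratch, with VIP (variable importance in projection) scores on the
   predictive component.
3. **Significance by design** — a repeated external cross-validation scheme:
   per pairwise comparison, 8 stratified external folds × 100 random
   repetitions = 800 models, each with Pareto scaling and 7-fold internal
   cross-validation (orthogonal-component selection) confined to its training
   split; an equally sized permutation-null arm (labels reshuffled each
   repetition); and a one-sided two-sample Kolmogorov–Smirnov test of the two
   accuracy distributions at α = 0.001.
4. **Metabolite profiling** — union of bins with mean VIP > 1.5 in at least
   one comparison, region integration into metabolite levels, percent-of-
   control normalization, heatmap tables.
5. **Univariate layer and assays** — Shapiro–Wilk, two-way (genotype × diet)
   ANOVA with Type II sums of squares and Tukey HSD, pooled/Welch and
   one-sample t-tests, OGTT area-under-curve normalized to basal glucose, and
   comparative-Ct (2^−ΔΔCt) expression folds.
6. **Synthetic cohorts** — a simulator that generates plasma-CPMG-like
   spectra (Lorentzian multiplets, amplitude variability, shift jitter,
   baseline noise) with a known genotype × diet effect structure and ground
   truth, so every stage is testable without instrument data.

## The model in brief

For a two-class comparison with Pareto-scaled bin matrix `X` and centered
±1 response `y`, each orthogonal component removes class-unrelated variation:

    w  ∝ Xᵀy,  t = Xw,  p = Xᵀt/(tᵀt)
    w⊥ = p − (wᵀp)w  (normalized),  t⊥ = Xw⊥,  p⊥ = Xᵀt⊥/(t⊥ᵀt⊥)
    X  ← X − t⊥p⊥ᵀ

then a single predictive PLS component is fitted on the residual; a sample is
assigned to the class on its side of the midpoint of the class-mean predicted
scores. VIPⱼ = √J·|w_pred,j| / ‖w_pred‖, so ΣVIP² = J (the bin count).

Model significance is never judged on the training data: every accuracy is
computed on a held-out external fold, and the distribution of 800 true-model
accuracies is compared with 800 permutation-null accuracies by a one-sided
KS test (`p = exp(−2D²mn/(m+n))`).

## Worked example

```r
library(metabocv)

cohort     <- simulate_cohort(cohort_config(seed = 7))      # 4 groups x 7 animals
referenced <- lapply(cohort$spectra, reference_to_lactate)
normalized <- total_sum_normalize(bin_cohort(referenced))
normalized
#> <bin_matrix> 28 samples x 400 bins, state: normalized

sel    <- cohort$design$group %in% c("WT/CD", "KO/WD")
report <- validate_comparison(normalized$values[sel, ], cohort$design$group[sel],
                              cv_config(seed = 8), comparison = "WT/CD vs KO/WD")
report
#> <validation_report> WT/CD vs KO/WD
#>   models: 800 true + 800 permuted
#>   accuracy 1.000 (perm 0.466), sens 1.000, spec 1.000
#>   KS D = 0.705, p = 2.07e-173 -> significant

panel <- normalize_to_control(integrate_regions(normalized), cohort$design, "WT/CD")
round(heatmap_table(panel, group_order = c("WT/CD","WT/WD","KO/CD","KO/WD"))[,
      c("lipid_ch2","vldl","lactate","alanine","valine","glucose")], 1)
#>       lipid_ch2  vldl lactate alanine valine glucose
#> WT/CD     100.0 100.0   100.0   100.0  100.0   100.0
#> WT/WD     111.1 110.0    96.4    65.0   76.2    84.5
#> KO/CD     107.0 110.3    90.4    64.7   77.3    88.5
#> KO/WD     118.8 129.2    84.4    47.9   69.1    49.1

two_way_anova(panel$values[, "lactate"], cohort$design$genotype, cohort$design$diet)
#>        effect df df_residual         F           p
#> 1    genotype  1          24 9.9214677 0.004335476
#> 2        diet  1          24 1.9371551 0.176743455
#> 3 interaction  1          24 0.1186381 0.733516186
```

Reading the output: the cross-validated OPLS-DA separates the control group
from the knockout-on-Western-diet group perfectly (held-out accuracy 1.00)
while the permutation arm stays at chance (0.47), so the KS call is
significant. The heatmap table shows the injected effect structure recovered
from the spectra — lipids/VLDL highest and lactate/alanine/valine/glucose
lowest in KO/WD, with the control column pinned at 100% — and the two-way
ANOVA attributes the lactate change to genotype on this draw.

`run_pipeline(run_config(seed = 1))` runs the whole chain (simulation →
preprocessing → all four pairwise comparisons → VIP selection → metabolite
panel → per-metabolite ANOVA) and returns a JSON-ready report.

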