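---
title: "Methods: cross-validated OPLS-DA profiling of plasma NMR metabolomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-validated OPLS-DA profiling of plasma NMR metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metabocv` implements a complete ¹H-NMR plasma metabolomics analysis for
2 × 2 factorial cohorts (genotype × diet), from spectra to significance
calls and metabolite tables. This vignette explains the statistical model,
the defaults and why they are set as they are, what the synthetic-cohort
generator does and does not emulate, and the numerical conventions a
maintainer should know.

## 1. Preprocessing model

A spectrum is a nonnegative intensity trace on a strictly increasing ppm
grid. Phasing and baseline correction are assumed done upstream (for
synthetic spectra they are perfect by construction). Preprocessing is a
fixed four-step chain with explicit state tracking:

1. **Referencing.** The spectrum is translated along the grid so that the
   midpoint of the CH₃-lactate doublet sits at δ = 1.33 ppm. The doublet is
   searched in 1.20–1.45 ppm. Because plasma CPMG spectra carry broad lipid
   CH₂ and VLDL resonances in the same window, picking simply the two
   tallest maxima reliably finds lipid humps, not lactate; candidates must
   therefore (a) rise above the window's median absolute intensity and
   (b) have an apex curvature above 4 × `mad(diff(intensity))`. Curvature
   scales as height/FWHM², so narrow lactate lines exceed the threshold by
   an order of magnitude while broad lipid humps fall short regardless of
   height. The doublet is then the two tallest qualifying maxima. Shifts are
   applied as whole-gridpoint translations with zero padding; with the
   default 0.002-ppm grid the residual error is below the default shift
   jitter. Fewer than two qualifying maxima (e.g. a flat trace) is an error,
   never a silent no-op.
2. **Binning.** Half-open bins `[lo, lo + width)` of constant width
   (default 0.02 ppm) anchored at the range minimum (default 0.5–9.0 ppm);
   the last partial bin is dropped. The bin value is the exact integral of
   the piecewise-linear trace over the bin interval (cumulative trapezoid
   at grid points plus closed-form partial segments), so bin integrals over
   a gapless range sum exactly to the whole-range trapezoidal integral, and
   binning is linear in the spectrum. Bins overlapping the water exclusion
   window (default 4.5–5.0 ppm) are dropped: residual water is
   analytically meaningless and would otherwise contribute a nuisance bin
   to the normalization sum. The defaults give 400 usable bins.
3. **Total-sum normalization.** Each row is divided by its own sum,
   removing dilution and receiver-gain differences. Zero-sum rows are an
   error naming the sample.
4. **Pareto scaling.** Each bin is centered at its mean and divided by the
   square root of its sample (n − 1) standard deviation — the usual
   compromise that tempers the dominance of intense lipid bins without
   blowing up pure-noise bins as unit-variance scaling would. Constant bins
   are centered and left unscaled.

The processing state (`raw` → `normalized` → `pareto`) is recorded on the
matrix and every step validates it: applying a step to a matrix in the
wrong state raises an error rather than silently re-applying.

A note on scaling and data leakage: the one-shot `pareto_scale()` freezes
cohort-level statistics on the returned object, but the cross-validation
machinery never uses them — inside validation, centering and scaling
statistics are recomputed from each training split and applied to its
held-out fold (and likewise inside the internal folds). Leak-free scaling
is the stricter and defensible choice, and the no-leakage property is
asserted by instrumentation in the test suite.

## 2. OPLS-DA, prediction and VIP

For a two-class comparison the response is coded +1/−1 (first-listed class
positive) and centered. Each of `n_orth` orthogonal components is extracted
by computing the PLS weight/loading pair, taking the part of the loading
orthogonal to the weight, and deflating its variation from X; one
predictive PLS component is then fitted on the residual. Exactly one
predictive component is used — the standard for binary discrimination,
where a single latent direction carries all between-class information.

The decision threshold is the midpoint of the two class-mean predicted
training scores, which stays sensible when a training split is mildly
unbalanced; exact ties go to the first-listed class. Prediction removes the
stored orthogonal components from new data before projecting, and refuses
data whose bins do not match the training bins.

VIP is computed on the predictive component only:
`VIP_j = sqrt(J) |w_j| / ||w||`, hence `sum(VIP^2) = J`. A variant that
includes orthogonal variation ("VIP_total") was considered and rejected:
orthogonal components are by construction class-unrelated, so their
loadings describe what the model *discards*, and folding them into a
feature-importance score for *discrimination* muddles the interpretation
that the VIP > 1.5 selection rule depends on.

Reductions used as correctness anchors (and asserted in the tests): with
`n_orth = 0` the model is exactly a one-component PLS1 regression; on
noiseless rank-(1 + n_orth) data its training predictions match a
(1 + n_orth)-component PLS; training predictions are invariant to rescaling
the orthogonal loading.

## 3. The validation scheme

Per pairwise comparison and repetition, samples are partitioned into 8
stratified external folds: class members are shuffled and dealt round-robin
with a counter continuing across classes, so fold sizes differ by at most
one and every training split keeps both classes even with 7 + 7 samples in
8 folds. 100 repetitions × 8 folds = 800 models. Should a degenerate
partition still arise (possible only for tiny inputs), the fold assignment
is re-randomized up to 10 times before erroring. The repetition count is
the model budget divided by the fold count; only the product is contractual.

Within each training split, the orthogonal-component count is chosen from
{0, 1, 2} by 7-fold internal cross-validation on pooled internal-fold
accuracy, ties resolved toward fewer components (parsimony). Two orthogonal
components are enough at n = 14: each component costs a sample-size-scarce
degree of freedom, and the internal folds (training splits of ~10 samples)
cannot support more. The selected model is refitted on the full training
split and scored on the held-out fold; per-model accuracy, sensitivity and
specificity (first-named group positive) are recorded, with fold-level
sensitivity/specificity undefined (NA) when the fold lacks a class, and
aggregation is the mean over all 800 models with NAs removed.

The permutation arm repeats the identical scheme with labels shuffled once
per repetition before fold assignment. Significance compares the 800 true
with the 800 permuted accuracies by a one-sided two-sample KS test (true
stochastically greater): `D = sup(ECDF_perm − ECDF_true)` over the pooled
support, `p = exp(−2D²mn/(m+n))`, significant at α = 0.001. The asymptotic
formula was checked against exhaustive label-permutation enumeration on
10-point samples; its error there is below 0.02 and it shrinks with sample
size, which is ample slack at m = n = 800 against α = 0.001.

Two empirical facts about this scheme worth knowing:

* On *null* data the true-arm accuracy does not center exactly at 0.5: the
  800 models share one small dataset, so dataset-level means spread widely
  and sit slightly below chance (the anti-learning behaviour of
  cross-validation at n = 14). The tests therefore assert the absence of
  positive skill and the absence of false KS calls, not a binomial
  concentration around 0.5.
* The permutation arm, which re-randomizes labels every repetition, *does*
  concentrate near 0.5 on cohort-like inputs (measured 0.48–0.52 across
  seeds). Extreme artificial inputs (one bin separating classes by 10 sd)
  can push the permuted mean a few points below 0.45 by the same
  anti-learning mechanism.

The four factorial comparisons (diet within each genotype, genotype within
each diet) run with deterministic per-comparison seeds derived from the
master seed, so a full report is reproducible from one integer.

## 4. Profiling

Bins with mean VIP (across the 800 true models) above 1.5 in at least one
comparison form the discriminating set. Metabolite levels are sums of
normalized bin integrals whose bin *midpoint* lies in the metabolite's ppm
intervals — midpoint membership avoids double counting where intervals
abut. Levels are expressed as percent of the control-group (WT/CD) mean, so
the control column of the group × metabolite heatmap table is exactly 100.
The default region table mirrors the simulator's chemical-shift table so
that recovery tests close the loop; for real data it is a plain list the
user overrides. Because levels are ratios of sums of normalized bins, the
percent panel is invariant to global intensity rescaling of the spectra.

## 5. Univariate layer and assays

The univariate layer wraps the standard implementations behind a validated
interface: Shapiro–Wilk via the Royston AS R94 approximation (3 ≤ n ≤ 2000,
constant input is an error), two-way ANOVA with Type II sums of squares
(classical decomposition when balanced, well-defined at the 6–8 per group
sizes these cohorts have), Tukey–Kramer studentized-range comparisons with
explicit q statistics, and pooled-variance Student t-tests (Welch behind a
flag) plus the one-sample t against 100% used for control-normalized data.
Degenerate zero-residual ANOVA input (an exact deterministic effect) cannot
be handled by the standard fitter; the package falls back to explicit
Type II model comparisons and reports F = 0, p = 1 for zero-SS effects and
F = ∞, p = 0 otherwise, so the noiseless closed-form cases remain exact.

OGTT glucose tolerance is summarized as the trapezoidal AUC over the 0, 5,
15, 30 min samples divided by the basal (t = 0) glucose — "normalized to
basal levels" read as a ratio, making the result a pure time quantity
(minutes) invariant to unit rescaling; the incremental variant (area above
baseline) is available behind a flag for users who prefer excursion-only
AUC. qPCR tables go through the comparative-Ct method: ΔCt against the
arithmetic mean of the reference-gene Ct values (equivalently the geometric
mean of reference expression), ΔΔCt against the mean control-group ΔCt,
fold = 2^−ΔΔCt. Folds are invariant to a global cycle shift, and the
control group's folds have geometric mean 1.

## 6. The synthetic cohort generator

The generator exists so that every downstream stage has ground truth. It
emulates: four groups of n = 7; Lorentzian multiplets (Gaussian optional)
at the conventional plasma chemical shifts — lipid CH₃ 0.86, VLDL
0.885/1.255, lipid CH₂ 1.285, unsaturated lipid 5.32, the lactate doublet
at 1.33, alanine 1.48, valine 0.99/1.04, isoleucine 0.94/1.01, glucose ring
protons 3.2–3.9 plus the anomeric doublet 5.23 ppm; per-sample,
per-metabolite amplitude variability (CV 0.12); chemical-shift jitter
(sd 0.002 ppm); Gaussian baseline noise (sd 0.05 intensity units against
peak heights of ~2–16, i.e. a high-SNR CPMG-like regime); and intensity
clipping at zero. Effects are multiplicative per factor: lipids/VLDL
×1.3 per factor (×1.69 combined), lactate/alanine/valine/isoleucine ×0.7
per factor, and a knockout-by-diet interaction confined to unsaturated
lipid (×1.5) and glucose (×0.6) in the KO/WD cell only — i.e. 30–50%
group-level changes with additive structure on the log scale. The water
region is left empty, matching its exclusion downstream.

Ground truth records the true mean amplitude per metabolite × group and the
default-grid bins overlapping each line's FWHM interval
`[center − fwhm/2, center + fwhm/2]` — the conventional definition of a
peak's extent, and the region where a line's group contrast is strong
enough that a recovery claim about those bins is falsifiable.

What it does *not* emulate: phase and baseline artefacts, peak-shape
distortions, ridge-like pH-dependent shift drifts (jitter is rigid per
sample), J-coupling fine structure beyond simple multiplets,
macromolecule background, and between-metabolite correlation beyond the
built-in closure effect of total-sum normalization. Passing tests therefore
demonstrate that the *analysis machinery* is correct and calibrated under a
realistic signal/noise structure — not that any particular real cohort
would yield the same accuracies.

One RNG stream is seeded per cohort and samples are drawn in a fixed,
documented order (groups as configured, samples within group in index
order), so identical seed and configuration give a bit-identical cohort.

## 7. Numerical conventions and problem sizes

* PCA is computed by SVD with a deterministic sign convention (each
  loading's largest-magnitude element positive); explained fractions are
  σ²ᵢ/Σσ².
* An orthogonal weight with norm below 1e−12 means the residual has no
  orthogonal variation left; fitting errors in the user-facing API, and the
  internal model-selection path carries the last valid candidate forward.
* Internal contracts are asserted at tight tolerances: normalized rows sum
  to 1 and Pareto columns are mean-zero within 1e−9; `w_pred`/`w_orth` are
  unit-norm and mutually orthogonal within 1e−8; ΣVIP² = J within 1e−8;
  noiseless ΔΔCt and effect recovery within 1e−9/1e−6.
* The test suite and the acceptance script run at the full default sizes
  where the contract is about those sizes (800 models per arm, a
  28 × 400 cohort matrix, 1000-replicate ANOVA calibration, 10-seed VIP
  recovery) and at reduced sizes (4–5 folds, 3–25 repetitions) where only
  the mechanism is under test.

## 8. Known limitations

* The referencing heuristic assumes the lactate doublet is present and
  resolved; spectra without it (or with extreme lipid dominance *and*
  suppressed lactate) are rejected rather than guessed at.
* Accuracy-based model selection with fold sizes of 1–2 is coarse; the
  internal CV pools correct counts over folds to soften this, but with very
  small cohorts the chosen `n_orth` remains noisy (ties go to the simpler
  model by design).
* The asymptotic KS p-value is anti-conservative by up to ~1e−2 at tiny arm
  sizes; at the default 800 + 800 this is irrelevant, but callers reducing
  the scheme drastically should not read borderline p-values literally.
* Type II ANOVA is the right default for mild unbalance; strongly
  unbalanced or empty-cell designs are errors, not silently refitted.
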