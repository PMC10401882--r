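---
title: "Dual-projection ICA harmonization: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-projection ICA harmonization: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmodp)
```

## The problem

Voxelwise fMRI summary measures — the amplitude of low-frequency
fluctuations (ALFF) and regional homogeneity (ReHo) — are routinely pooled
across acquisition sites to gain statistical power. Different scanners
impose systematic measurement biases ("site effects") that can dwarf the
biological effects of interest (age, sex, diagnosis) and, worse, are often
*confounded* with them: in the 16-site autism cohort whose structure this
package emulates, the sites differ enormously in age range and in their
ASD/control and male/female composition. `harmodp` implements and compares
three harmonization strategies on a subjects-by-features matrix `Y`:

1. **ComBat**: a per-feature location/scale model
   `Y = alpha + X beta + gamma_site + delta_site * eps`, with the naive
   per-site additive (`gamma`) and multiplicative (`delta`) estimates
   shrunk by parametric empirical Bayes (normal prior on `gamma`,
   inverse-gamma on `delta`, hyperparameters by method of moments across
   features), then removed in standardized space and the intercept and
   signal effects restored.
2. **Single-projection ICA (ICA-SP)**: spatial ICA `Y - mean = A S`;
   mixing courses (columns of `A`) significantly associated *only* with
   the site label are regressed out of `Y`.
3. **Dual-projection ICA (ICA-DP)**: additionally takes the *mixed*
   courses (associated with both site and signal variables), removes
   their signal-explainable part by regressing them on the signal design
   (`A' = A_mixed - X pinv(X) A_mixed`), and regresses `[A_sites, A']`
   out of `Y`. This removes the site-related share of mixed variance
   while leaving the signal span untouched — the mechanism by which
   masked biological associations can *strengthen* after denoising.

## Component classification

Each mixing course is tested with a Pearson correlation against each
signal variable (point-biserial for the binary ones) and a one-way ANOVA
F-test across sites, with a single Bonferroni family of size
`components x (signal variables + 1)` at family-wise level 0.05.
Significant-for-signal-only components are labeled `signal`, site-only
`noise`, both `mixed`, neither `unclassified`. Unclassified components are
**retained** by both denoisers: they carry unexplained structure and
removing variance that no test attributes to the scanner would risk
discarding biology. The classification is monotone in the level: tightening
alpha can only move components toward `unclassified`.

## Projection conventions

The projection equations as literally written would also strip any mean
component of `Y` that the courses share. By default every removal basis is
augmented with the all-ones column, the projection is removed, and the
per-feature means are added back, so harmonized data keeps its original
grand mean and is directly comparable to ComBat's restored output. The
literal equations are available with `intercept = FALSE`. Pseudo-inverses
are realized as minimum-norm least squares with a singular-value cutoff of
`1e-10` relative to the largest singular value, so rank-deficient or
duplicated courses are handled without error. The signal design used for
purging includes an intercept, preventing the mixed-course means from
leaking into the purged courses.

The ICA itself is fixed-point ICA on PCA-whitened data (logcosh contrast,
symmetric decorrelation, tolerance `1e-6`, at most 1000 iterations,
seed-controlled random orthogonal initialization), with components ordered
by explained variance and sign-fixed by the largest map value. Any valid
ICA of the same model order spans essentially the same removal subspace
once classification is applied; tests therefore quotient out permutation
and sign by maximal-|correlation| matching, never by index.
Non-convergence is a warning, not an error: the partially converged
rotation still yields a usable basis, and the model records it.

## Feature extraction

ALFF sums one-sided FFT amplitudes `2|F_k|/t` over the closed band
0.01-0.1 Hz, excluding the DC bin even when the band starts at 0. Series
are linearly detrended first (the default for real, drifting data; note
that detrending a *pure* sinusoid redistributes about 1% of its amplitude
across bins, so exact single-bin identities hold on the raw spectrum via
`detrend = FALSE`). The statistic is toggleable
(`sum_amplitude`/`mean_amplitude`/`sum_power`); downstream harmonization
is indifferent to this choice, which only rescales features.

ReHo is Kendall's coefficient of concordance `W` between a voxel's series
and its available in-mask neighbors (7, 19 or 27-voxel neighborhoods;
boundary voxels use whatever neighbors exist, with the neighbor count `K`
entering the formula), with mid-ranks and the tie-corrected denominator.
Isolated voxels get `W = 0` and are counted. Smoothing order follows the
field's convention: ALFF smooths each frame *before* the spectral
calculation, ReHo smooths the concordance map *after*. Gaussian smoothing
uses a separable kernel (`sigma = FWHM / 2.355` per axis in voxel units,
truncated at 4 sigma, normalized to unit sum) with mask-aware
renormalization.

## The synthetic cohort

`abide_like_spec()` fixes the study conditions: 16 sites with the real
per-site subject counts (795 total), per-site ages Normal(mean, sd) from
the published per-site demographics truncated at 5 years, and sex/diagnosis
proportions from the published counts. `confound_strength` interpolates the
per-site covariate distributions between the pooled cohort distribution (0,
site-independent covariates) and the fully site-specific one (towards 1);
the default 0.9 reproduces cohort-level confounding (site-age ANOVA p-values
are vanishingly small across seeds).

Effect sizes were chosen once, from the structure the real cohort
displays, and are not tuned per analysis:

- residual noise sd 1 (the unit of all effects);
- site additive effects `gamma[s, v] = g_s + N(0, 0.5^2)` with a global
  per-site shift `g_s ~ N(0, 0.5^2)`. The global shift is what a scanner
  amplitude bias does: it survives median summaries and is what masks the
  age trend in whole-brain plots;
- mild multiplicative effects `delta = exp(N(0, 0.1^2))`;
- a negative age effect of 0.03 per year on a contiguous half of the
  features (strong enough that, once site offsets are removed, the
  whole-brain median tracks age clearly), and sex/diagnosis effects of
  0.15 on 10% blobs — sparse spatial blobs so that "which regions carry
  the effect" has a localized ground truth.

What the generator does *not* emulate: spatial autocorrelation of real
maps, motion and hemodynamic artifacts, registration error, non-Gaussian
residuals, and site effects that interact with the biology. Passing tests
on this generator therefore demonstrate the *algebra and statistics* of the
pipeline — not that real scanner effects are this well-behaved.

## Evaluation

Residual site effects are quantified per feature by the partial F-test of
the site factor in a GLM adjusting for diagnosis, age and sex (extra sum of
squares, Bonferroni FWE across features by default; a max-statistic
permutation FWE is available). Signal preservation uses (a) the same
machinery per signal variable — continuous age enters as a linear term with
one numerator df, since a literal one-way ANOVA on a continuous factor is
undefined — with direction taken from the coefficient sign, and (b) the
whole-brain summary: per subject, the median within each of 100 contiguous
equal-size feature blocks (the real atlas behind "100 ROIs" is not
specified in the source literature, so the parcellation is synthetic),
then the median across blocks, correlated with age. The
median-of-ROI-medians reading is the default; the pooled median is a flag.
t-SNE embeddings with silhouette scores per labeling are diagnostics, not
acceptance surfaces.

## Problem sizes and numerical choices

The shipped simulations use 795 subjects x 500 features with 20 ICA
components and 25 replicate seeds — large enough that the 15-dimensional
site subspace is comfortably identifiable, small enough to iterate on a
laptop. ComBat's EB iteration stops on a relative-change criterion
(default `1e-8`, 500 iterations max; tests that compare against an
external reference run both at that reference's stopping rule).
Degenerate inputs are rejected early: sites with fewer than 2 subjects,
rank-deficient designs (reported with the offending columns), unseen site
labels at apply time, masks that do not match the grid.

## Known limitations

- When site and signal variables are almost collinear (first canonical
  correlation above 0.95 between site indicators and the signal design),
  no method can separate the shared variance; the pipeline warns and the
  dual projection deliberately leaves the signal-explainable part of the
  mixed courses in the data — intersection effects are not removed.
- SP/DP are linear projections: purely multiplicative (variance) site
  effects are not corrected by them, only by ComBat.
- Component classification inherits the usual caveats of
  significance-based selection: at very small model orders a single
  component can mix site and signal so thoroughly that purging leaves
  little site variance removable.
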