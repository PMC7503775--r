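---
title: "Methods: from UPLC-PDA traces to drought-effect categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from UPLC-PDA traces to drought-effect categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolomics)
```

## The problem

Designed stress experiments on crop plants produce large collections of
liquid-chromatography UV traces: here, phenolic metabolite profiles of
barley leaves recorded by UPLC with photodiode-array detection at 280 and
330 nm, under a factorial design of 8 varieties x moisture-deficit
treatments (drought at the seedling stage, at the flag leaf stage, or
both) x sampling days (3, 6, 10; day 1 additionally under the combined
treatment) x 4 replicates, each with a matched well-watered control.
Turning those traces into per-metabolite drought-effect statements
requires (i) a chromatographic preprocessing chain that makes peaks
comparable across hundreds of injections, (ii) a factorial ANOVA
classification of how the drought effect is modified by variety and
time, and (iii) downstream analytics: effect-profile clustering,
category-table tests, phenotype links, and neutral-loss arithmetic for
structural annotation of the responding compounds. This package
implements all three layers, together with a synthetic-data generator
that emulates the design with known ground truth, so that every stage is
testable end to end without instrument data.

## Preprocessing model

Each chromatogram is a vector of intensities on a shared retention-time
grid. The chain applies, in order:

1. **Mass normalization** - intensities are divided by the weighed-in
   leaf mass (mg), `normalize_by_mass()`.
2. **Baseline removal by differentiation** - the first finite-difference
   derivative w.r.t. the grid index,
   `remove_baseline_by_differentiation()`. No baseline is estimated:
   constant baselines vanish and smooth drifts become near-constant
   offsets that the later concavity analysis ignores. All subsequent
   stages operate on this differentiated signal.
3. **Correlation optimized warping (COW)** - `cow_align()` aligns each
   differentiated trace to the pointwise median trace of its wavelength.
   The signal is divided into segments (default length ~N/100, about 100
   points on a 10,000-point grid); each boundary node may shift by at
   most `slack` points (default 15); dynamic programming maximizes the
   summed per-segment Pearson correlation over all monotone, endpoint-
   fixed piecewise-linear warps. Constant segments score 0 rather than
   erroring, and ties are broken toward the identity warp. The inner
   loop is compiled (Rcpp); the test suite checks it against exhaustive
   path enumeration on short signals.
4. **Peak detection** - `smooth_second_derivative()` fits a cubic
   smoothing spline with 520 knots (the default, suited to ~10,000-point
   grids; tests on 2,000-point grids use proportionally fewer) to the
   differentiated signal and differentiates it analytically, giving a
   smoothed second derivative of the original trace. Peaks are maximal
   negative (concave) runs, `detect_peaks()`. Runs of length 1 and runs
   whose maximum absolute differentiated intensity stays below the
   tolerance 0.0005 are discarded as irrelevant.
5. **Common peaks** - per-sample intervals are merged across
   chromatograms by interval union (transitive closure of overlap),
   `build_common_peaks()`; a merged peak must be supported by at least
   `c1` chromatograms (default: half of them - the study never prints
   its value, so the default is chosen to be robust and is
   configuration-exposed).
6. **Integration** - per sample and common peak, the trapezoidal
   integral of the rectified differentiated signal over the interval
   (`integrate_peaks()`), which equals the rise from baseline to apex
   for a clean peak and is monotone in peak area at fixed shape; it
   needs no baseline model by construction.
7. **Dual-wavelength merging** - `merge_wavelengths()` sums variables
   that carry the same metabolite name at 280 and 330 nm (metabolites
   with two absorption maxima), keeps multi-name labels for co-eluting
   peaks, and passes unnamed peaks through.

Interpretation choices that the published description leaves open, and
how this implementation resolves them: the derivative order for baseline
removal is first; differentiation precedes warping (the published
flowchart order); peak regions on the second derivative are
negative-concavity runs (standard second-derivative peak picking); the
"intensity within the peak" filter is the maximum absolute
differentiated-signal value, since filtering happens after
differentiation and warping; the COW reference is the per-wavelength
pointwise median of the normalized, differentiated traces (robust to
outlying samples; a specific reference sample can be configured).
Intervals are half-open `[start, end)` and 1-based.

## Statistical model

Integrated values are transformed by `log2(1e9 * v)`
(`log_transform()`), so multiplicative effects on peak area become
additive. Per treatment, `classify_effects()` fits the full fixed-
effects factorial model variety x time x drought (V\*T\*D) to every
metabolite and computes F-tests for all seven terms. The published
analysis fits REML ANOVA with Wald-F tests but contains only fixed
effects on a balanced design, where ordinary least-squares F-tests
coincide; the implementation therefore uses OLS, computed for all
metabolites at once through a single QR decomposition of the shared
model matrix (balanced designs make sequential sums of squares
order-invariant). Within each effect family - D, VD, TD, VTD,
independently - significance is Bonferroni-controlled at
`p < 0.05 / m` across the `m` metabolites, holding the family-wise
error rate below 0.05 per family. Categories follow the precedence VTD
> VD&TD > TD > VD > D > NoEffect, mirroring the mutually exclusive
category columns of the published count table.

Treatment effects are drought-minus-control cell means on the log2
scale (`compute_effects()`), with marginal profiles by day
(`effect_time_profiles()`) and by variety (`effect_by_variety()`).
Time profiles of time-modified metabolites are clustered into k = 4
groups by the maximum between-group sum-of-squares criterion
(`cluster_time_profiles()`): exhaustive enumeration of all 4-part
partitions up to 12 profiles, k-means with multiple restarts beyond
that (the two coincide on every small instance in the test suite).
Cluster labels A-D are ordered by descending first-day mean, a
determinism convention. Mahalanobis distances between cluster means use
the pooled within-cluster covariance with a small ridge
(`1e-8 * trace(S)/p`) only when singular.

Category counts per treatment form a contingency table
(`category_table()`) tested for independence by a Pearson chi-square
statistic with a Monte-Carlo permutation p-value over fixed-margin
tables (Patefield sampling; `permutation_chisq()`), `p = (1 + #{X2 >=
obs}) / (1 + n_perm)`.

Phenotype traits (15 maturity traits) are classified per treatment by
the two-way V\*D model at p < 0.01 (`classify_trait_effects()`): VD
when the interaction is significant, else D when the main drought
effect is. Effects are reported raw and as percent of the control mean
(`trait_effects()`). Biplots of variety x trait effect matrices use the
rank-2 SVD of the column-centered matrix with scores carrying the
singular values (`biplot_coords()`; symmetric scaling by option).
`correlate_effects()` computes Pearson correlations of variety-specific
metabolite and trait effects with two-sided t-based p-values (n - 2
df), flagged at 0.01 and 0.05; with 8 varieties the 0.01 threshold sits
at |r| ~ 0.834. Because the published text does not say which day's
metabolite effect enters the correlations, the default is the
day-averaged effect, with the final-day effect available
(`day = "last"`); and because the inclusion rule for the correlation
screen is not stated, the pipeline screens metabolites with
variety-specific categories (VD, VD_TD, VTD).

## Neutral-loss annotation

MSn spectra of flavonoid glycoconjugates are annotated by integer mass
arithmetic on nominal residue masses (`residue_table()`): O-glycosidic
losses (hexose 162, deoxyhexose 146, pentose 132), C-glycoside
cross-ring fragments (120/90), hydroxycinnamoyl residues (feruloyl 176,
hydroxyferuloyl 192, sinapoyl 206, sinapic acid 224, coumaroyl 146) and
malonyl chemistry (CO2 44, ketene 42, ketene+hexose 204).
`decompose_loss()` enumerates every residue multiset explaining a mass
difference (bounded DFS, deterministic order);
`annotate_spectrum()` chains decompositions along a fragment ladder,
matches the terminal ion against the aglycone library directly or via
the C-glycosylflavone marker [Agly+(42-18)-H]-, and ranks paths by
fewest residues then lexicographically (a determinism convention). The
146-amu deoxyhexose/coumaroyl ambiguity is deliberately preserved -
resolving it requires elution-order evidence, which is outside the mass
arithmetic. Nominal integer masses match the amu bookkeeping of the
source spectra; this is not a tool for high-resolution mass accuracy.

## What the generator emulates - and what it does not

`simulate_experiment()` plants each metabolite as a chromatographic
peak at a fixed latent retention time, present at both wavelengths with
independent response factors. Drought samples multiply peak areas by
`2^effect`, where the (variety, day) effect matrix follows the planted
category: D constant, VD varying by variety only, TD by day only, VD_TD
additive in both, VTD a product (non-additive) pattern - these
semantics make the categories identifiable by the factorial ANOVA. Each
sample receives a smooth monotone piecewise-linear retention-time warp
(the same warp at both wavelengths, as both channels come from one
injection), a random polynomial baseline, and iid Gaussian noise.

Default generator conditions: category proportions per treatment equal
the published per-treatment category frequencies (counts/104), so the
default run emulates the study's observed mix; peaks are Gaussians (an
exponentially modified Gaussian tail is available) of width 0.05 min
with amplitudes 1-3 AU; noise is 0.02 AU (signal-to-noise 50-150);
warps displace peaks by up to 0.02 min; baselines are low-order
polynomials of ~0.5 AU; the grid has 10,000 points over 0-25 min. The
study reports none of these instrument-level quantities, so they were
chosen once as plausible UPLC-PDA values and are configuration
arguments, not tuned constants. Test and benchmark runs use 1,200- to
2,000-point grids, 2-4 varieties and 2 replicates so the whole suite
runs in minutes; the statistical simulations (family-wise error, power,
correlation recovery) use the full 8-variety, 4-replicate,
3-day single-treatment design (192 samples) with 104 metabolites.

The generator does **not** emulate: full-spectrum PDA data or spectral
deconvolution, ion chromatograms or mzML, heteroscedastic or correlated
detector noise, intensity drift between batches, co-elution beyond what
random peak placement produces, or missing samples. Passing tests
therefore demonstrate correctness of the algorithms under the stated
model, not robustness to every artifact of real instrument data.

## Numerical choices and degenerate inputs

* COW: constant segments score 0; ties prefer the identity warp; a
  trailing remainder shorter than 2 points merges into the last
  segment; `slack = 0` returns the input unchanged; `slack >=
  segment_len` is rejected before any computation.
* Peak detection: zeros are handled by the negative-run definition
  (strictly below 0); empty results are legal everywhere downstream.
* `log_transform()` replaces zeros by half the variable's smallest
  positive value (with a warning) - the published analysis is silent on
  zeros; negative values are an error.
* ANOVA requires a balanced design and errors on empty cells or rank
  deficiency (naming the aliased term); this matches the balanced
  factorial the design generator produces.
* Clustering breaks label ties deterministically; the exhaustive path
  guarantees the global optimum for small instances.
* `permutation_chisq()` drops all-zero rows/columns before sampling and
  adds one to numerator and denominator of the p-value, keeping it
  valid and never exactly zero.

## Problem sizes used by the shipped checks

The test suite and the acceptance script were sized to run on a single
CPU in well under their time budgets: recovery benchmarks use 20
metabolites on 2,000-point grids across 24 chromatograms per
wavelength; the family-wise-error simulation uses 500 null datasets of
104 metabolites on the 192-sample design; category-recovery power uses
60 simulated datasets; correlation recovery uses 200 phenotype
simulations; clustering oracles enumerate up to 4^9 assignments; the
permutation test uses 1e5 fixed-margin tables. These sizes are the
package's own benchmark definitions and can all be scaled up through
the exported configuration arguments.

## Known limitations

* The preprocessing quantifies the rectified-derivative rise, not the
  literal peak area; the two are proportional only at fixed peak shape,
  which is the planted situation and approximately true for real peaks
  of similar width.
* Common peaks are unions of intervals: heavily overlapping metabolites
  merge into one variable (the co-elution situation the multi-name
  labels exist for), and no deconvolution is attempted.
* The ANOVA layer has no missing-data handling beyond cell exclusion in
  effect computation, and no FDR alternative to Bonferroni.
* Replication blocks are not modelled (the published analysis never
  reports block effects); the design is treated as completely
  randomized.
* Nominal masses cannot distinguish isobaric residues (deoxyhexose vs
  coumaroyl, hexose vs C-glycosyl full loss); annotation returns all
  consistent multisets rather than guessing.
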