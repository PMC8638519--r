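---
title: "Methods: case-control FTIR fingerprinting of blood plasma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control FTIR fingerprinting of blood plasma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imfp)
```

## The measurement and its artifacts

Transmission FTIR spectroscopy of liquid blood plasma records absorbance on
a uniform wavenumber grid (here 950–3050 cm⁻¹ at 4 cm⁻¹ spacing).
Because absorbance is reconstructed against a pure-water reference, and
plasma contains *less* water per volume than pure water, the raw spectra
carry a systematic residual-water artifact: a tilted — and sometimes
negative — baseline. Plasma is known to have no significant absorption in
the 2000–2300 cm⁻¹ window, so any slope there is an artifact. The
compensation implemented in `fit_water_coefficient()` adds a per-sample
multiple $c$ of a measured water absorption spectrum $W(\nu)$ and chooses
$c$ to minimize the *average slope* over that window.

**Operationalization of "average slope".** We define it as the
ordinary-least-squares slope of absorbance against wavenumber over the
window. This makes the minimizer closed-form,

$$c = -\,\mathrm{slope}(s)\,/\,\mathrm{slope}(W),$$

is robust to point noise (each point contributes, none dominates), and
reproduces the intended "flat baseline" semantics: after correction the OLS
slope is exactly zero in exact arithmetic whenever the water reference
itself has a nonzero slope. A water reference that is flat over the window
(slope below $10^{-12}$ absorbance/cm⁻¹) cannot inform the fit and is
rejected with an explicit error rather than silently returning $c = 0$.
One scalar per spectrum is fitted — the artifact is a deficit of a single
physical component (water), so a single additive multiple of its spectrum
is the physically appropriate model; no separate offset correction is
applied, and no wavenumber-dependent scaling.

After correction, spectra are truncated to 1000–3000 cm⁻¹ and the *silent
region* 1800–2800 cm⁻¹ is excised (`excise_regions()`): biological samples
show negligible absorption there, so it contributes noise and the
water-compensation diagnostic but no signal. Excision is pure column
subsetting — values are never interpolated — and the resulting grid is
flagged non-contiguous; all downstream run/area computations respect the
gap. Finally `l2_normalize()` scales each spectrum to unit Euclidean norm,
removing effective-pathlength and total-concentration variation. The chain
order is fixed as **correct → excise → normalize**: normalizing before
excision would let silent-region content leak into the normalization
constant of the retained windows (the test suite demonstrates that the two
orders genuinely differ). Normalization is a flag because the
non-normalized variant is a legitimate sensitivity analysis: vector
normalization reduces measurement-scale bias, which matters most at small
sample size, but discards overall-absorbance information.

Pooled-plasma QC measurements interleaved after every 5 samples are
summarized by `qc_drift()` as the per-wavenumber coefficient of variation,
the mean pairwise RMS difference, and the OLS slope of mean absorbance
against acquisition index (with standard error) — a campaign-level drift
alarm, not a correction.

## Matching

Observational case–control comparisons confound disease status with
covariates; here age and BMI. `match_controls()` selects one control per
case by greedy 1:1 nearest-neighbour matching without replacement in
standardized covariate space (z-scores computed on the pooled cases +
candidates, $n-1$ sd). Determinism is built in: cases are processed in
descending distance from the candidate centroid (hardest-to-match first,
ties by id) and candidate ties resolve to the lexicographically lower id,
so identical inputs always give identical pairs. Optimal-assignment
matching (minimum total distance, via `clue`) is available as
`method = "optimal"` but is off by default: greedy with the stated ordering
is simpler to reason about, reproducible, and in our simulations optimal
assignment improves the achieved balance only marginally. No caliper is
applied by default, so the matched-control count always equals the case
count; a caliper would instead drop cases.

Balance is reported as the standardized mean difference
$\mathrm{SMD} = (\bar{x}_1 - \bar{x}_0)/\sqrt{(s_1^2 + s_0^2)/2}$ per
covariate, before and after matching. Two notes on what matching can and
cannot do. First, when one covariate starts nearly balanced, bivariate
matching may drift it by a few hundredths of an SMD while dramatically
improving the badly imbalanced one, so the guaranteed property (and what the
tests assert) is that the *worst* covariate imbalance never increases — not
each covariate separately. Second, 1:1 matching without replacement cannot
manufacture overlap: if the candidate pool's mean sits about one case-sd
below the cases (as under this package's default simulated accrual, chosen
deliberately harsh), no selection of distinct controls can close the gap,
and the post-match SMD plateaus well above the conventional 0.25 threshold.
The balance report exists precisely to make that residual confounding
visible rather than hidden.

## Per-wavenumber statistics

Given matched groups on the post-excision grid, `differential_fingerprint()`
computes per wavenumber:

- the differential fingerprint $\Delta(\nu) = \bar{A}_{case} - \bar{A}_{ref}$;
- the reference-group sd $s_{ref}(\nu)$ and the effect size
  $d(\nu) = \Delta(\nu)/s_{ref}(\nu)$ — Glass's delta, standardizing by the
  reference group only, on the rationale that the reference group defines
  the "healthy" variability against which a deviation should be judged
  (cases may have inflated variance for reasons of their own);
- two-sided t-test p-values, Student's pooled-variance variant by default —
  it matches the equal-means hypothesis framing and is the common default —
  with Welch available by flag;
- the Mann–Whitney $U$ (ties counted 0.5, i.e. midranks) and the
  per-wavenumber $\mathrm{AUC} = U/(n_1 n_2)$, oriented as the probability
  that a random case exceeds a random reference. Midrank handling keeps the
  AUC in $[0,1]$ and makes the identity
  $\mathrm{AUC}(A,B) + \mathrm{AUC}(B,A) = 1$ exact under ties.

All sds use the $n-1$ denominator throughout. Raw per-wavenumber p-values
are reported as primary (the per-wavenumber map is a descriptive screen, not
a confirmatory family of hypotheses); a Benjamini–Hochberg column `p_bh` is
emitted additionally and clearly labelled as an extension.

`significant_regions()` reports maximal runs of consecutive retained grid
points with $|d| \ge d_0$ (default $d_0 = 1$: the one-reference-sd line;
a p-value threshold is optional and off by default). Runs never bridge the
excised gap. `enclosed_area()` integrates $|\Delta(\nu)|$ by the trapezoid
rule within each contiguous block; `stage_stratified()` repeats the whole
analysis for non-metastatic (M0, stages I–III) and metastatic (M1,
stage IV) cases against the same references and reports the M1:M0
enclosed-area ratio, a one-number summary of how disease progression
amplifies the fingerprint difference.

Degenerate inputs are defined, not improvised: zero reference sd with zero
delta gives effect 0; zero reference sd with nonzero delta gives `NA` plus a
warning; zero pooled variance gives `NA` p-values with a warning; an
all-ties comparison gives AUC 0.5 exactly.

## Classification

`repeated_cv_svm()` evaluates a linear SVM (`e1071::svm`, $C = 1$, no
internal rescaling, no class weights, no tuning — the deliberately plain
protocol for a small-cohort feasibility analysis; $C$ is config-exposed)
under repeated stratified 10-fold cross-validation (10 × 10 by default).
Stratification deals each class round-robin into folds after a seeded
shuffle, so per-fold class counts deviate by at most one sample. Held-out
samples are scored with the *signed decision value* — not the predicted
label — because ROC analysis needs a ranking score. Each fold yields an
empirical ROC and its AUC (computed by midrank pair-counting, identical to
the per-wavenumber statistic); the result is the distribution of
$k \times \mathrm{repeats}$ AUCs, summarized as mean ± sd (the mean of fold
AUCs, not the AUC of pooled scores, which would mix incomparable decision
scales across folds). The mean ROC is the *vertical average* of fold ROC
staircases on a fixed FPR grid (step 0.01): simple, and monotone by
construction. No per-fold feature standardization is applied beyond the
pipeline's vector normalization, so the cross-validation measures exactly
the preprocessing variant under study.

## The synthetic cohort generator

`simulate_cohort()` emulates the data-generating process the analysis
assumes, with known ground truth. A spectrum is

$$A(\nu) = g \sum_i a_i\,(1 + \delta_i e)\, e^{-(\nu - c_i)^2/2w_i^2}
  + b\,W(\nu) + \varepsilon_{smooth}(\nu) + \varepsilon_{white}(\nu),$$

with $g$ a lognormal per-subject concentration factor, $e$ the effect scale
(0 for references, 1 for M0 cases, $\kappa$ — the stage multiplier — for M1
cases), $b$ a per-sample residual-water coefficient, and $W$ the
generator's deterministic water curve (a smooth monotone ramp through
1900–2400 cm⁻¹ plus broad bending-mode and OH-stretch features).

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| grid | 950–3050 cm⁻¹, step 4 | typical liquid-plasma FTIR acquisition range/resolution |
| bands | 8 Gaussians (1080…2960 cm⁻¹) | mimic carbohydrate, amide II (1545), amide I (1650), ester carbonyl and CH-stretch features; amplitudes give amide-dominated plasma-like curves |
| effect bands | ±0.6–1.2% amplitude shifts on 4 bands | per-wavenumber effect sizes of order one reference-sd after normalization — a detectable but not trivial contrast |
| `stage_multiplier` | 2.5 | metastatic disease leaves a several-fold stronger fingerprint than early-stage disease |
| `frac_m1` | 10/26 | an accrual in which a large minority of newly diagnosed cases is metastatic |
| `noise_sd` | 0.0015 | white instrument noise, ~0.3% of the amide I amplitude |
| `smooth_noise_sd`, `corr_len` | 0.004, 30 cm⁻¹ | band-scale compositional variation between subjects; correlated noise is what stresses per-wavenumber statistics realistically |
| `subject_noise_sd` | 0.05 | ~5% total-concentration variation between subjects (removed by L2 normalization) |
| `water_mismatch_range` | ±0.3 | residual-water coefficients of the order the compensation step must fix |
| covariates | cases 49 ± 9 y, BMI 29 ± 6; candidates 40 ± 8 y, BMI 26 ± 5 | a deliberately imbalanced screening pool, so matching has real work to do |
| `qc_every` | 5 | pooled-QC cadence of a disciplined campaign |

**Envelope-modulated noise.** The smooth (correlated) component is white
noise convolved with a Gaussian kernel of width `corr_len`, then multiplied
by the relative absorbance envelope $A(\nu)/\max A$. Compositional
variation between subjects can only manifest where molecules absorb; an
unmodulated smooth noise would place biological variance into the silent
region — a region *defined* by the absence of absorption — where it would
masquerade as baseline tilt and corrupt the water-coefficient fit with
spurious contributions. With the envelope in place, the silent region
carries only white instrument noise and the water fit recovers constructed
coefficients to machine precision.

**Calibrated benchmarks.** `theoretical_feature_auc()` gives the closed-form
per-wavenumber AUC of the generator,
$\Phi\!\left(\Delta(\nu) / (\sigma(\nu)\sqrt{2})\right)$, and
`calibrate_effect()` rescales the contrast so its maximum hits a chosen
target. `single_contrast_config()` packages the canonical benchmark: one
amide-II contrast, concentration and water-mismatch variation off, best
single-feature AUC calibrated to 0.80. Two anchors follow. At the study's
scale (26 + 26), the cross-validated SVM should sit *near* 0.80: a linear
classifier on ~250 correlated features, 52 samples, gains a little from the
band's width and loses a little to finite-sample weight estimation. At
large $n$ the finite-sample loss vanishes, and the proper ceiling is not the
single-feature optimum but the multivariate Gaussian Bayes AUC
$\Phi(\sqrt{s^\top \Sigma^{-1} s / 2})$ (signal vector $s$, noise covariance
$\Sigma$), which exceeds 0.80 because the contrast band spans several grid
points; the test suite computes this ceiling in closed form and asserts the
cross-validated AUC lies between the two anchors. An individual simulated
cohort of 52 subjects carries substantial sampling variance (roughly ±0.09
in mean AUC from cohort draw alone), which is why benchmark quantities are
averaged over 10 seeded cohorts.

**What the generator does not emulate.** No instrument line-shape, no
interferogram-level effects, no Mie or other scatter artifacts, no
water-vapor/CO₂ gas lines, no batch or storage-time structure, no
covariate–spectrum coupling (age does not shift bands), and disease effects
are pure band-amplitude rescalings. Passing tests therefore demonstrate
correctness of the statistical machinery under a plausible generative
model — not that measured plasma spectra satisfy that model.

## Determinism and numerical choices

- Every stochastic entry point takes a seed; `run_pipeline()` fans its
  global seed out deterministically (simulation uses `seed`,
  cross-validation `seed + 1`), so stages rerun standalone reproduce the
  pipeline exactly, and the manifest written with every run suffices to
  reproduce it.
- Grids must be strictly increasing and uniform within contiguous blocks to
  a relative tolerance of 1e-9; gaps must be whole multiples of the step
  (anything else is a malformed file, not an excision).
- Spectral CSVs are written with 17 significant digits and read back with a
  correctly rounding parser, so write∘read is value-identical.
- Normalized outputs satisfy $\lVert a \rVert_2 = 1$ to 1e-12;
  normalization is idempotent.
- Matching distance ties are broken by id; all orderings are lexicographic
  and documented, making the whole pipeline bit-reproducible.

## Problem sizes used by the test suite

Unit tests run on toy grids (tens of points) with exact hand-computed or
brute-force oracles; statistical properties use the study-scale cohort
(26 cases, 67 candidates, 526-point grid): 10 seeded cohorts for the
classification benchmark, 200 null cohorts for p-value/AUC calibration,
100 cohorts for the stage-ratio property, 200 for matching behaviour, and
1000 random small instances for the exact U/AUC cross-check. These sizes
were chosen so each property is measured at the scale the package targets
while the whole suite stays comfortably interactive.

## Known limitations

- The water compensation assumes the artifact is exactly proportional to
  one fixed water spectrum; temperature-dependent changes of water
  absorption are not modelled.
- Greedy matching is order-dependent by design (deterministic), and no
  caliper means every case is matched even when no good control exists —
  inspect `balance_after` before trusting downstream contrasts.
- Per-wavenumber p-values are descriptive; neighbouring wavenumbers are
  strongly correlated and no spatial model is applied.
- The SVM protocol is deliberately untuned; it measures feasibility, not
  attainable performance.
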