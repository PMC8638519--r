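# imfp — infrared molecular fingerprinting of blood plasma

`imfp` is an R package for case–control analysis of Fourier-transform
infrared (FTIR) absorbance spectra of liquid blood plasma — "infrared
molecular fingerprints". It is aimed at spectroscopists and biostatisticians
running observational disease-detection studies in which a group of patients
is compared against matched reference individuals, wavenumber by wavenumber
and by whole-spectrum classification.

The package covers the full analysis chain:

1. **Spectral preprocessing.** Liquid-sample absorbance reconstructed against
   a pure-water reference under-represents water, tilting the baseline in the
   2000–2300 cm⁻¹ window where plasma shows no significant absorption. A
   multiple *c* of a measured water spectrum is added per sample so that the
   ordinary-least-squares slope of absorbance vs wavenumber over that window
   is minimized — the closed form is *c* = −slope(s)/slope(water). Spectra
   are then truncated to 1000–3000 cm⁻¹ with the silent region
   (1800–2800 cm⁻¹) excised, and optionally scaled to unit Euclidean norm
   (L2 vector normalization). Pooled-plasma QC spectra, interleaved after
   every 5 samples of a campaign, yield drift diagnostics (per-wavenumber CV,
   pairwise RMSD, trend slope).
2. **Covariate matching.** Greedy 1:1 nearest-neighbour matching without
   replacement in standardized (z-score) covariate space selects one control
   per case from a candidate pool, with standardized-mean-difference (SMD)
   balance diagnostics before and after:
   SMD = (m̄₁ − m̄₀)/√((s₁² + s₀²)/2).
3. **Differential fingerprint statistics**, per wavenumber ν:
   - Δ(ν) = mean case absorbance − mean reference absorbance,
   - effect size d(ν) = Δ(ν)/s_ref(ν) (Glass's delta, standardized by the
     reference group's sd),
   - two-sided Student t-test p-values (Welch optional), plus a clearly
     labelled Benjamini–Hochberg column,
   - Mann–Whitney U and the per-wavenumber AUC = U/(n₁·n₂) — the probability
     that a random case exceeds a random reference,
   - contiguous significant regions (|d| ≥ d₀, optionally p ≤ p₀), the
     enclosed area ∫|Δ(ν)|dν, and tumor-stage-stratified comparisons
     (non-metastatic M0 vs metastatic M1) with their enclosed-area ratio.
4. **Classification.** A linear support-vector machine on the preprocessed
   spectra, evaluated by repeated stratified 10-fold cross-validation;
   held-out decision values give per-fold ROC curves and AUCs, summarised as
   mean ± sd and a vertically averaged mean ROC.
5. **Synthetic cohorts.** A seeded generator of FTIR-like plasma campaigns
   (Gaussian absorption bands, envelope-modulated correlated noise,
   residual-water artifacts, stage-scaled disease effects, imbalanced
   age/BMI covariates, interleaved QC spectra) with known ground truth, so
   the whole pipeline is testable without measured data.

## Worked example

```r
library(imfp)
res <- run_pipeline(pipeline_config(seed = 1))
print(res)
```

```
== infrared fingerprint pipeline report ==
seed: 1 | input: simulation | normalization: L2 vector norm
cohort: 26 cases, 67 candidates -> 26 matched controls
-- covariate balance (SMD before -> after) --
  age: +1.371 -> +0.593
  bmi: +0.677 -> +0.139
QC: 18 pooled spectra | median CV 1.39% | trend -1.39e-07 absorbance/index
-- significant regions (|effect| criterion) --
  1074-1074 cm-1 (max |d| = 1.02)
  1106-1110 cm-1 (max |d| = 1.14)
  1506-1582 cm-1 (max |d| = 2.31)
  1618-1674 cm-1 (max |d| = 2.65)
  1682-1682 cm-1 (max |d| = 1.25)
  2906-2906 cm-1 (max |d| = 1.06)
  2938-2938 cm-1 (max |d| = 1.27)
  2950-2950 cm-1 (max |d| = 1.35)
  2966-2966 cm-1 (max |d| = 1.20)
stage strata: M0 n=16, M1 n=10 | enclosed-area ratio M1:M0 = 2.33
classification (normalized spectra): AUC = 0.945 +- 0.120 (10-fold x 10 repeats, linear SVM C = 1)
```

Reading the report: 26 simulated cancer cases were matched 1:1 against 67
screening candidates; matching pulled the age imbalance from 1.37 to 0.59
SMD and BMI into good balance. The interleaved QC spectra show sub-percent
to percent-level variation and no acquisition trend. Effect sizes exceed one
reference-standard-deviation across the amide I/II region (1500–1700 cm⁻¹)
and at carbohydrate and CH-stretch bands; the metastatic stratum encloses
2.3× the differential-fingerprint area of the non-metastatic stratum; and
the repeated-CV linear SVM separates cases from matched references with a
mean AUC of 0.95 under the default (signal-rich) generator settings.

Every stage is also exposed as a data-frame-first function
(`preprocess_spectra()`, `match_controls()`, `differential_fingerprint()`,
`repeated_cv_svm()`, `simulate_cohort()`, …) with `tidy()`/`glance()` and
`autoplot()` methods, so the pipeline can be driven piecewise.

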