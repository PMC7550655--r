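---
title: "Quantitative MRI assessment of tumor treatment response: models, fitting and statistics"
author: "tumorQMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI assessment of tumor treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorQMRI)
```

## The problem

Longitudinal quantitative MRI is used in preclinical oncology to monitor
how a subcutaneous tumor xenograft responds to treatment without
sacrificing the animal. Two acquisitions carry most of the information:

* **Multi-b-value diffusion-weighted imaging (DWI)**, analysed with the
  intravoxel incoherent motion (IVIM) model. Water diffusing through tissue
  and blood flowing through randomly oriented capillaries both attenuate the
  diffusion-weighted signal, but at very different rates, so the decay over
  the diffusion weighting b is bi-exponential:
  \[ SI(b) = S_0\left[(1-f)\,e^{-bD} + f\,e^{-bD^*}\right] \]
  with \(D\) the true (tissue) diffusion coefficient, \(D^*\) the
  pseudo-diffusion coefficient of the vascular compartment
  (\(D^* \gg D\)), and \(f\) the perfusion fraction. Rising \(D\) reflects
  falling cellularity (necrosis, apoptosis); \(f\) and \(D^*\) track
  microvascular perfusion.

* **Multi-echo gradient-echo (BOLD-sensitive) imaging**, analysed by R2\*
  relaxometry. The signal decays mono-exponentially with echo time,
  \(SI(TE) = S_0 e^{-R_2^* TE}\), and \(R_2^* = 1/T_2^*\) increases with
  paramagnetic deoxyhemoglobin, making it a surrogate of tumor hypoxia.

Around the voxelwise models sits a standard animal-study analysis: caliper
tumor volumes \(V = a^2 b/2\), inhibition rates of treated versus control
groups, group-by-timepoint summary tables, one-way ANOVA with
Student–Newman–Keuls (SNK) post hoc comparisons, and Pearson correlations
between imaging and histology. This package implements the whole chain,
along with a synthetic phantom and study generator so that every stage is
testable without scanner data.

The default acquisition schedules are those of the reference study at
1.5 T: thirteen b-values (0, 25, 50, 75, 100, 150, 200, 400, 600, 800,
1000, 1200, 1500 s/mm²) and sixteen echo times (3.4–92.1 ms, TR 160 ms).

## Segmented IVIM fitting

A joint four-parameter fit of the bi-exponential is notoriously unstable at
clinical SNR, so the field's standard estimator — and the one used here —
is *segmented*:

1. **Step 1 (diffusion).** For b above a boundary (default 200 s/mm²) the
   vascular compartment has decayed to a negligible level
   (\(e^{-bD^*} < 10^{-3}\) for \(b \ge 400\), \(D^* \approx 8.5\times
   10^{-3}\) mm²/s), so \(\ln SI\) is linear in b. Ordinary least squares
   gives \(D\) (slope) and \(\ln[S_0(1-f)]\) (intercept).
2. **Step 2 (perfusion).** The full bi-exponential is then fitted with
   \(D\) frozen, over all b-values (default) — using every point stabilises
   the scale and leaves \(f\) and \(D^*\) identified by the low-b
   curvature. The scale \(S_0\) is profiled out: for any candidate
   \((f, D^*)\) its least-squares value is available in closed form, so the
   numerical search (box-constrained L-BFGS-B with a coarse \(D^*\)
   multi-start) runs over \((f, D^*)\) only. A pure-diffusion candidate
   (\(f = 0\)) is always evaluated too, so zero perfusion is recovered
   exactly rather than being approached asymptotically.

Design choices that were genuinely open:

* **Step order.** Descriptions of the segmented method sometimes narrate
  the low-b perfusion fit first. Without \(D\) the low-b bi-exponential is
  underdetermined, so the canonical order — \(D\) first from high b, then
  \(f, D^*\) with \(D\) fixed — is used; the narration order is treated as
  expository.
* **Membership of the boundary b-value.** The high-b segment is taken as
  b *strictly above* 200 s/mm² (six points of the default protocol). At
  b = 200 the perfusion term still contributes a few percent of signal;
  including it contaminates the slope and roughly quadruples the noiseless
  bias of \(D\) (about 4% versus about 1% at the default tissue
  parameters). `fitConfig(highb_inclusive = TRUE)` restores the inclusive
  variant.
* **Step-2 range.** Restricting step 2 to b < 200 only (available as
  `step2_all_b = FALSE`) matches the narrowest reading of the segmented
  recipe but is dramatically noisier — with only six low-b points and three
  free parameters the perfusion estimates destabilise under measurement
  noise — so all b-values are used by default.
* **Bounds and start.** \(D \in [10^{-5}, 5\times10^{-3}]\),
  \(D^* \in (D, 0.5]\) mm²/s, \(f \in [0, 1]\);
  \(f_0 = 1 - e^{\mathrm{intercept}}/SI(0)\) clipped to \([0.01, 0.5]\),
  \(D^*_0 = 10D\). Units are mm²/s internally everywhere; the display
  conversion to the tables' \(10^{-3}\) mm²/s and percent lives in one
  place (`displayUnits()`).

Failures (all-zero signal, fewer than two positive high-b points) return a
flagged result rather than an error, so map fitting never aborts on a bad
voxel; voxels outside the mask carry NaN.

### What precision to expect

Noiseless, the segmented estimator recovers the baseline tumor parameters
(D = 0.556×10⁻³ mm²/s, D* = 8.53×10⁻³ mm²/s, f = 16.75%) to within a few
percent — the only distortion is the ~1% residual perfusion contamination
of the high-b segment. Under Rician noise at b = 0 SNR 50, precision is
limited by information, not by the optimizer: the high-b log-linear slope
carries roughly 8% relative standard deviation (near the Cramér–Rao bound
for any estimator confined to that segment), so voxelwise median relative
errors settle around 6% for \(D\), 14% for \(f\) and 25% for \(D^*\) —
\(D^*\) being, as always in IVIM, the least stable parameter. ROI means
are far tighter because the scatter averages out over hundreds of voxels.
The acceptance script computes these numbers explicitly.

## R2\* relaxometry

Voxelwise \(R_2^*\) is estimated by ordinary least squares of
\(\ln SI\) on TE: slope \(-R_2^*\), intercept \(\ln S_0\). Echo times are
declared in ms (as printed on protocols) and rates reported in 1/s; the
factor 1000 appears in exactly one internal constant. Choices:

* **Noise floor.** Late echoes can sit near the Rician noise floor, which
  biases a log-linear fit downward. Echoes at or below a configurable
  absolute floor (recommended: about 3 background SDs) are excluded before
  the log transform; raising the floor never increases the number of
  echoes used. The default floor is 0 (keep all positive echoes), which is
  adequate for the tumor parameter range here (minimum tumor echo signal
  ≈ 5σ at SNR 50).
* **Weighting.** Unweighted OLS matches the stated "linear fit of
  ln(signal)" convention and is the default; a signal-squared-weighted
  variant (variance-stabilising for additive noise carried through the log)
  and an echo-train truncation are available behind `r2starConfig()`.
* Negative slopes (non-decaying voxels) are clamped to \(R_2^* = 0\) and
  flagged degenerate; constant signal reports \(R^2 = 0\) with the same
  flag.

## The synthetic phantom and study generator

The generators define the study conditions; they are first-class, tested
code, not test scaffolding.

* **Phantom geometry.** A 24×24×12 voxel grid with an ellipsoidal "tumor"
  of semi-axes (6, 6, 4) voxels — about 600 tumor voxels, comparable to an
  8–10 mm xenograft at preclinical DWI resolution. Voxelwise truth
  parameters are drawn from independent normals per region; the tumor means
  are the baseline tumor values of the reference study (D 0.556×10⁻³,
  D* 8.53×10⁻³ mm²/s, f 16.75%, R2* 24.74 /s) with the corresponding
  baseline SDs as voxelwise heterogeneity, and the background emulates
  non-tumor soft tissue. Draws are clipped to the physical ranges
  (redraw up to 100 times, then clamp with a warning); \(D^* > D\) is
  enforced by redrawing \(D^*\).
* **Noise.** Magnitude MRI noise is Rician:
  \(\sqrt{(s+\varepsilon_1)^2 + \varepsilon_2^2}\) with i.i.d.
  \(N(0, \sigma^2)\) channel noise. The default σ = 20 puts the tumor
  b = 0 SNR at 50, a typical preclinical DWI operating point. Gaussian and
  noiseless modes exist for controlled tests.
* **Determinism.** Every generator is a pure function of its specification
  and an integer seed: one seeded RNG stream per generated object, with a
  fixed voxel ordering. (A per-voxel hashed substream scheme — which would
  additionally keep existing draws stable when the grid grows — was
  considered and dropped as complexity without a consumer: no supported
  workflow edits a phantom's grid in place.)
* **Study tables.** One value per animal × time point × quantity, drawn
  from Normal(cell mean, cell SD) with the packaged reference cells as the
  default targets (4 groups × 4 time points, n = 8; pathology only at the
  final time point, since those animals are sacrificed). Mean ± SD with a
  subsequent ANOVA is exactly the normality-justified summary the original
  analysis used, which motivates the normal draw; the paper reports no
  per-animal raw values, so normality is an assumption of the generator,
  stated rather than inferred.

What the phantom does **not** emulate: anatomical realism, partial-volume
mixing at the tumor rim, motion, EPI distortion, spatially correlated
noise, coil inhomogeneity, and between-animal variance components beyond
the per-cell normal draw. Passing recovery tests on this phantom therefore
demonstrates correctness of the estimators under the stated signal and
noise models — not robustness to every artefact of in-vivo data.

## The statistical layer

* **Normality screening** uses the Kolmogorov–Smirnov statistic with mean
  and SD estimated from the sample — i.e. the Lilliefors-corrected test
  (via the published approximation in `nortest`). Testing against a fully
  specified normal is almost never what a mean/SD screening step does.
* **One-way ANOVA** comes in two forms. `anovaOneway()` is the classical
  decomposition on raw samples (through `stats::aov`).
  `anovaFromSummary()` recovers the *identical* F from per-group
  mean/SD/n alone — \(SS_B = \sum_i n_i(m_i - \bar m)^2\) with \(\bar m\)
  the weighted grand mean, \(MS_W = \sum_i (n_i-1)s_i^2 / \sum_i (n_i-1)\)
  — which is what lets the printed cells of published tables be re-analysed
  directly. The two paths are verified against each other exactly.
  Comparisons across time points treat repeated measures on the same
  animals as independent groups; this mirrors the original analysis and is
  a documented statistical caveat, not something this package "fixes".
  Zero within-group variance with unequal means yields a flagged infinite
  F rather than an error.
* **SNK post hoc**: means sorted, each pair tested with the studentized
  range critical value for its span (from `qtukey` at the ANOVA error df —
  computed from the distribution, not a lookup table), and the standard
  stepwise protection: a non-rejected pair blocks every pair it encloses.
  Two groups reduce exactly to the pooled t test (\(q = t\sqrt2\)).
  Unequal group sizes use the harmonic-mean standard error; ties in means
  compare in stable sort order.
* **Pearson correlation** with the study's strength convention:
  \(|r| > 0.8\) high, \(0.5 \le |r| \le 0.8\) moderate, else weak.
  Pathology is assumed measured on all n = 8 animals per group at
  sacrifice. The published imaging–pathology correlation table itself is
  not reproducible from summary data (raw pairs are not printed), so only
  the correlation machinery is validated, on synthetic data.

## Reproducing the reference tables

The printed summary tables travel with the package as plain-text fixtures
(checksummed at load). `reproduceTables()` recomputes every printed
one-way F value from the mean ± SD cells with n = 8, and the week-3
inhibition rates from the week-3 volume means:

```{r}
rep <- reproduceTables()
subset(rep, statistic == "inhibition_rate")
summary(subset(rep, statistic == "F")$rel_dev)
```

The inhibition rates agree exactly at the printed precision, and most F
values agree to a few tenths of a percent. A handful of rows deviate by
1–3%: their printed SDs carry only two significant digits, and a half-ulp
perturbation of the inputs spans the printed F, so agreement beyond that
is not attainable from the published numbers. The near-null
perfusion-fraction row (F = 0.479) is the extreme case — a small F divides
two similar mean squares, amplifying input rounding.

## Problem sizes and runtime choices

The validation suite uses the default phantom (≈600 tumor voxels, 13
b-values / 16 echoes), 20 voxels for the brute-force grid-search
cross-check of the optimizer (a 200×101 lattice with one local zoom), 2000
replicates for ANOVA type-I calibration, and 100 replicate synthetic
studies for the end-to-end treatment-response pattern. These sizes give
Monte-Carlo error comfortably below each assertion's tolerance while
keeping the whole suite to a few minutes on one CPU.

## Limitations

* The segmented estimator is the standard practical choice, but its \(D\)
  inherits a small perfusion-contamination bias and its \(D^*\) remains
  noisy at routine SNR; Bayesian or joint fitting is out of scope.
* The vendor workstation software used for the original maps is
  undocumented; equivalence is claimed with the stated equations, not with
  that implementation.
* The ROI convention is a mask on the largest cross-section slice; 3D
  masks are accepted but summarised the same way (no volumetry from MRI).
* Repeated-measures correlation within animals is ignored by design (see
  above); no multiple-testing correction is applied across quantities,
  matching the original analysis.
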