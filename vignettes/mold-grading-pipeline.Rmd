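---
title: "Grading maize mold severity from two-sensor hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading maize mold severity from two-sensor hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizemold)
```

## The problem

Maize kernels mold readily during storage — the embryo is large, the
moisture content high — and *Aspergillus flavus* contamination brings the
carcinogenic aflatoxin B1 with it. The practical question this package
addresses is whether two line-scan hyperspectral imagers with complementary
ranges — a visible/shortwave near-infrared camera (Vis-SWNIR, working range
399–1001 nm after trimming noisy edge bands, 389 variables) and a longwave
near-infrared camera (LWNIR, 1005–1701 nm, 112 variables) — can grade
kernels into four mold severities (healthy, mild, moderate, severe) when
their spectral and textural information is fused.

Severity itself is defined biochemically. Catalase (CAT) is a metabolite of
fungal growth, and its activity tracks mold load; it is measured by
permanganate titration and expressed as

$$\mathrm{CAT} = \frac{V_1 - V_2}{M \times T} \quad \text{mL/(h·g)},$$

with $V_1, V_2$ the titrated permanganate volumes of control and sample, $M$
the sample mass, $T$ the unit time (`cat_activity()`). Healthy (sterilized,
day-0) kernels titrate to exactly zero; the mild, moderate and severe groups
(days 2, 4, 6 of culture) have CAT activity near 1.57, 1.91 and 2.24
mL/(h·g) with SDs of 0.13, 0.09 and 0.12.

## Pipeline

Each stage is an exported function; `run_experiment()` chains them.

1. **Reflectance calibration** (`correct_image()`):
   $I_C = (I_O - I_B)/(I_W - I_B)$ against white (~99% reflectance Teflon)
   and dark-current reference frames.
2. **Segmentation** (`build_mask()`): threshold the gray band where
   kernel/background contrast peaks (849 nm Vis-SWNIR, 1098 nm LWNIR),
   fill holes, drop specks. The threshold defaults to Otsu's method — the
   original workflow says only "appropriate thresholds", and a
   parameter-free, reproducible default is preferable; a fixed threshold
   can be supplied, and both cleanup steps can be switched off.
3. **Mean spectrum** (`extract_mean_spectrum()`) over ROI pixels, then
   `trim_bands()` to the retained ranges.
4. **Texture** (`band_texture_matrix()`): per band, ROI gray values are
   min–max quantized into $N = 8$ levels, a gray-level co-occurrence matrix
   (GLCM) is accumulated at distance 1 for 0°/45°/90°/135°, and contrast,
   correlation, energy and homogeneity are computed per direction and then
   averaged — parameter values are averaged, not the matrices. Ordered
   pairs are counted (non-symmetric GLCM) and pairs touching background are
   excluded rather than zero-filled. An undefined correlation (zero
   marginal SD) maps to 0 so downstream matrices stay finite.
5. **Preprocessing** (`preprocess_chain()`): a 9-point moving-average
   smooth first, then optionally multiplicative scatter correction,
   detrending, or column mean-centering. The chain used downstream is
   smooth–detrend, which in the experiment grids gives the best balance of
   prediction accuracy against the calibration/prediction gap. Smoothing
   uses symmetric shrinking windows at the edges so the band count is
   preserved. MSC references and centering means are fitted on calibration
   rows and frozen for prediction rows — a leakage guard the original
   description leaves open; "center" is column-wise centering, the
   chemometric norm. Texture blocks are left untreated.
6. **Variable selection** (`vcpa()`, `iriv()`, `mvcpa_iriv()`): see below.
7. **Fusion** (`pixel_fuse()`, `feature_fuse()`): pixel-level fusion
   concatenates full blocks; feature-level fusion concatenates per-block
   selections. Every fused column carries provenance (sensor, block, band,
   wavelength). Columns are then min–max scaled to [0, 1] with ranges
   fitted on calibration rows (`fit_scaling()`) — raw reflectance (~0–1)
   and texture contrast (~0–3) would otherwise enter an RBF kernel at
   incomparable scales. Prediction values may fall outside [0, 1]; they
   are not clamped.
8. **Classification** (`train_svm()`, `train_rf()`, `train_knn()`): the
   3:1 per-class calibration/prediction split (`stratified_split()`; 60
   per level gives 45/15, so 180/60 overall), SVM-RBF with cost and kernel
   width searched over $2^{-8} \ldots 2^{8}$ in doubling steps by
   stratified 5-fold CV, random forest with 50 trees, KNN with $k \in
   \{1,3,\ldots,15\}$ and Euclidean or cityblock distance. Reports carry
   calibration and prediction accuracy, the overfitting gap, per-class
   accuracy, the confusion matrix in fixed healthy→severe order, and the
   moldy-as-healthy count — the safety-critical error mode.

## The wavelength selectors

All three selectors minimize the same fitness: the stratified 5-fold CV
misclassification rate of a PLS-DA evaluator restricted to a candidate
column set. PLS-DA is fitted by SIMPLS in compiled code (the selectors
score 10⁴–10⁵ candidate subsets per run); the component count is chosen by
CV up to `min(10, vars, n − 1)` in a single pass, since one SIMPLS fit
yields predictions for every component count. Classification inside the
evaluator is by nearest class centroid in score space: with four ordered
severities lying mostly along one latent direction, indicator-regression
argmax systematically loses the middle classes, while the centroid rule
does not. The final reported models use the SVM; PLS-DA is only the
selectors' internal objective, which keeps selection fast and matches how
these selectors are normally driven.

**VCPA** repeatedly draws `bms_runs` random variable combinations from the
current pool (binary matrix sampling, inclusion probability 0.5, at least
two variables per draw), scores them, and keeps each variable's inclusion
frequency among the best 10% of draws. The pool shrinks along an
exponentially decreasing schedule — pool size at iteration $i$ is
$\mathrm{round}(p\,e^{-i\ln(p/L)/n_{\mathrm{iter}}})$, reaching $L = 14$ at
the last iteration — and every nonempty subset of the final pool
($2^{14}-1$ of them) is evaluated exhaustively; ties break toward fewer
variables.

**IRIV** draws a random inclusion matrix each round, scores every row, and
for each variable compares fitness with the variable present against the
paired pseudo-population with it flipped out. Variables whose inclusion
lowers the mean CV error are retained (a rank-sum test splits them into
strongly/weakly informative, and the dropped ones into uninformative vs
interfering); rounds repeat until stable, then backward elimination removes
variables while removal strictly improves fitness. The fold assignment is
refreshed each round (deterministically from the seed): with a single
frozen split, noise variables that happen to flatter that split survive
indefinitely, and refreshing folds restores the intended pruning.

**mVCPA-IRIV** runs only VCPA's frequency-ranking phase down to an
intermediate pool of 50 variables, then hands that pool to IRIV; on blocks
already at or below 50 columns it is exactly IRIV.

Default budgets follow the selector literature (50 EDF iterations, 500 BMS
draws, 500 inclusion rows); the `"reduced"` preset (15 iterations, 100
draws/rows) is used in the routine experiment grids and benchmarks, where
it preserves selection behaviour at a fraction of the cost — on the planted
benchmark below both selectors recover a median 8–10 of 10 informative
variables under the reduced budget.

## The synthetic data generator

The instrument data behind the original study are not public, so the
package ships a generator with two fidelity levels, and it defines the
study conditions for every test.

**Full-fidelity scenes** (`generate_scene()`) are rendered cubes:
an elliptical kernel ROI on a dark (≈0.05) background; a smooth analytic
base reflectance curve per sensor (logistic rise to a peak near 820 nm then
a slow fall for Vis-SWNIR; Gaussian peaks near 1100/1300 nm and troughs
near 1192/1445 nm for LWNIR); a per-level reflectance scale
(1.00, 0.85, 0.72, 0.60) implementing "the moldier, the darker"; an embryo
patch (15% of ROI area) at 0.92 of the surrounding reflectance, with the
rest of the ROI compensated so the ROI mean is exactly base × scale — mold
concentrates in the embryo; and multiplicative per-pixel speckle whose SD
grows with level (0.01, 0.03, 0.05, 0.07). Acquisition is simulated as
`raw = black + (white − black) × R` with noisy white (0.99) and black
(0.02) frames. Under min–max quantization this construction makes rendered
GLCM contrast rise and energy fall monotonically with level. Rendering is
meant for small scene counts (the default 64 × 64 spatial size keeps a
full two-sensor gallery in tens of megabytes); 240 full Vis-SWNIR cubes
would run to gigabytes for no statistical gain.

**Fast-path feature tables** (`generate_feature_tables()`) synthesize the
240 × 389 and 240 × 112 spectra and texture matrices directly. Spectra are
base × scale × (1 + per-sample scatter gain, SD 0.06) plus additive band
noise (SD 0.004). Texture values come from frozen response curves — class
mean as a function of the level's speckle SD, linear for contrast
(1.22 + 22.2·SD) and exponentially decaying toward a noise floor for
correlation, energy and homogeneity — calibrated once against the full
imaging + texture pipeline on rendered default scenes, then multiplied by a
per-sample latent factor (SD 0.12, loading positive for contrast, negative
for the rest, shared across parameters) plus 4% band noise. The rendered
texture profile is flat across bands because per-band min–max quantization
removes each band's amplitude, so no band modulation is applied. A
round-trip test confirms fast-path class means track rendered class means
(same orderings, within Monte-Carlo distance).

The scatter SD and latent-texture SD were set once so that the default
end-to-end benchmark lands in a realistic 90%+ regime rather than being
trivially separable: class separation in spectra after smooth–detrend is
~2.5 within-class SDs between adjacent levels, texture adds a partially
independent channel, and healthy vs mild is far better separated in
texture than mid-levels are — so errors concentrate between mild, moderate
and severe while moldy kernels essentially never grade as healthy,
mirroring the error structure reported for the real instrument data.

CAT values are drawn per level from the table above, truncated at zero by
redrawing negatives — redrawing, not clipping, keeps the sample mean on
target. With the default distributions the mild/moderate and
moderate/severe means sit about 2.5 SD apart, so the midpoint grading cuts
(1.74 and 2.075 mL/(h·g), `assign_level()`, right-open intervals with ties
going to the more severe level) re-grade about 94% of generated samples to
their generating level; the remaining 6% are genuine distributional
overlap, not a defect. Modeling labels are the generating level — each
level group *is* a CAT grade by construction — and the per-sample
re-grading is exposed alongside.

What the generator does **not** emulate: instrument artifacts (spectral
smile, dead pixels, scatter between kernels in a dish), multi-kernel
petri-dish layouts, wavelength-dependent texture, chemically-driven band
shifts with mold progression, or any aflatoxin signal. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that
its statistical behaviour matches the designed structure — not that the
printed accuracies of any real-instrument study are reproduced.

## Numerical choices

* Calibration guard: `white − black` must exceed 10⁻⁶ everywhere, else an
  error names the offending pixel/band. Calibrated values outside
  [−0.1, 1.5] are counted in a warning but not clamped.
* Nearest-band lookup maps 849/1098 nm onto the instrument grid.
* Constant quantization bands map to a single level and are flagged.
* MSC slopes below 10⁻⁸ pass the row through unchanged (warned); detrend
  requires two distinct wavelengths; centering with supplied means
  validates the length.
* KNN vote ties go to the smaller class index; SVM/KNN grid ties go to the
  first (smallest) grid entry.
* Constant fused columns scale with range 1 (warned).
* All stochastic stages consume explicit integer seeds; identical seed and
  configuration reproduce every stage bitwise.

## Problem sizes

The shipped experiment drivers and tests use the full 240-sample fast-path
tables for modeling, rendered 32–64 px scenes (8–60 bands) for the imaging
and texture stages, the reduced selector budget, and 5 seeds for the
benchmark medians: the planted-recovery benchmark (10 informative among
200 columns, n = 240) and the cross-sensor fusion benchmark (VCPA + SVM,
median prediction accuracy with per-sensor spectra-only baselines). These
sizes were chosen so a complete run stays comfortable on a laptop while
keeping every statistical comparison at the study's native scale of 240
samples.

## Known limitations

* The spectra and texture class structure is essentially one-latent-factor
  per block; real mold chemistry moves individual absorption bands, which
  would reward wavelength selection more specifically than the synthetic
  benchmark can.
* The PLS-DA fitness uses one CV pass to pick the component count, which
  is mildly optimistic as an error estimate; it is used only to rank
  subsets, never reported as a performance figure.
* The ENVI reader supports the fields this package writes (BSQ/BIL/BIP,
  32/64-bit floats) — it is not a general ENVI implementation.
* Decision-level fusion is out of scope, as is any modeling of aflatoxin
  concentration.
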