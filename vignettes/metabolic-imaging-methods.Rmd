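---
title: "Methods: label-free metabolic imaging analysis for cardiomyocyte screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free metabolic imaging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxscreen)
```

## Scientific background

Two coenzymes dominate cellular autofluorescence: NAD(P)H (fluorescent in
its reduced form) and FAD (fluorescent in its oxidized form). Their
relative intensities track the balance between glycolysis and oxidative
phosphorylation, which makes them a label-free readout of metabolic state.
During cardiomyocyte differentiation and maturation, cells shift from a
glycolytic to an oxidative phenotype, and both of the readouts implemented
here are sensitive to that shift:

* the **optical redox ratio (ORR)** from widefield intensity imaging, and
* **NAD(P)H fluorescence lifetimes** from time-correlated single photon
  counting (TCSPC) FLIM, where the short component reflects free and the
  long component protein-bound NAD(P)H.

`redoxscreen` implements both analysis chains together with a
synthetic-data generator, so that every stage can be validated against
known ground truth without access to microscope data.

## The widefield ORR workflow

For each field of view (one gel, one day) the pipeline receives a
registered NAD(P)H / FAD image pair and computes:

1. **Illumination correction** of the NAD(P)H image by rolling-ball
   subtraction (`rolling_ball_subtract()`): the morphological background —
   a grayscale opening with a disc structuring element — is subtracted,
   removing vignetting and smooth substrate fluorescence while preserving
   cell-scale features. The opening runs in compiled code via a disc row
   decomposition with sliding-window extrema; windows are clamped at the
   image border so constant images map to zero exactly.
2. **Cell masking** (`make_cell_mask()`): Otsu thresholding of the
   corrected image (alternatives: fixed value, percentile), followed by
   removal of connected components below `min_object_px`.
3. **Intensity measurement** (`measure_masked_mean()`): the mask is
   applied to both **raw** channels — the corrected image is used only to
   find cells, never to quantify them, so channel intensities keep their
   native scaling. Saturated pixels are excluded.
4. **Background estimation** (`measure_background()`): mean intensity of
   three disjoint square cell-free regions per channel, selected
   deterministically (lowest mask overlap after a safety dilation, ties
   broken lexicographically). Manual ROI coordinates can be supplied
   instead, which is the faithful reproduction of protocols where an
   operator picks the background locations.
5. **Normalized ORR** (`normalized_orr()`):
   \[
   I_N = \frac{I_{cell,NAD(P)H}}{I_{bg,NAD(P)H)}},\qquad
   I_F = \frac{I_{cell,FAD}}{I_{bg,FAD}},\qquad
   \mathrm{ORR} = \frac{I_N}{I_N + I_F}.
   \]
   Because each channel is normalized to its own gel background, global
   gain factors (lamp drift, exposure changes, substrate autofluorescence
   level) cancel per channel; this invariance is tested to `1e-3` on
   noiseless synthetic pairs. Swapping channels maps ORR to 1 − ORR, and
   the value lies in (0, 1) for any positive intensities.

Analysis is per field of view, not per cell: the screen-level questions
(trajectories, group differences) operate on gel-level means, and
FOV-level analysis keeps the pipeline independent of any particular
segmentation tool.

### Parameter defaults

| parameter | default | rationale |
|---|---|---|
| `rolling_ball_radius` | 50 px | well above the cell scale (ellipse semi-axes 5–12 px in the generator), well below the field scale |
| `threshold_method` | Otsu | parameter-free, reliable for bimodal cell/background histograms |
| `min_object_px` | 64 | removes noise specks without deleting small cells |
| `n_background_rois`, `roi_size` | 3, 24 px | three cell-free regions per gel, large enough to average shot noise |

## The FLIM fitting engine

Per-pixel photon histograms \(d_k\) are modeled as a two-component decay
convolved with the instrument response function (IRF):
\[
m_k = A \sum_j \mathrm{irf}_j\,\bigl(\alpha_1 e^{-t_{k-j}/\tau_1}
      + \alpha_2 e^{-t_{k-j}/\tau_2}\bigr) + C,
\]
with \(\alpha_1 + \alpha_2 = 1\), short lifetime \(\tau_1\) (free
NAD(P)H), long lifetime \(\tau_2\) (protein-bound), and constant
background \(C\). The mean lifetime is
\(\tau_m = \alpha_1\tau_1 + \alpha_2\tau_2\); this identity holds to
machine precision on every valid pixel by construction, as does fraction
normalization.

The default time axis is 256 bins over 12.5 ns — the repetition period of
an 80 MHz laser — and the default IRF is a Gaussian of 240 ps FWHM, a
typical measured width for multiphoton TCSPC systems. The convolution is
evaluated by zero-padded FFT; a direct double-loop evaluation is kept as a
reference and the two agree to better than \(10^{-9}\) relative (tested
over random parameter draws).

### Fitting choices

* **Spatial binning**: decays are summed over 3×3 neighborhoods before
  fitting (`bin_3x3()`), and only pixels with more than 1000 binned
  photons are fitted — the standard photon criterion below which
  biexponential parameters are not reliably identifiable.
* **Objective**: the default is Poisson maximum likelihood, implemented as
  Levenberg–Marquardt on signed square-root deviance residuals. The
  classic data-weighted least squares (Neyman weights
  \(1/\max(d_k,1)\)) is available via `weighting = "neyman"`, but at the
  ~1000-photon operating point the 1/counts weighting over-weights
  downward fluctuations in the sparse decay tail, pulling the
  long-lifetime estimate down and deflating the reduced chi-square below
  its calibrated range; the MLE objective avoids both effects, and the
  test suite verifies its median recovery (within 10% of truth) and
  \(\chi^2_r\) calibration (median in \[0.8, 1.2\]) on simulated cubes.
  That comparison drove the default.
* **Initialization**: \(\tau_1 = 500\) ps, \(\tau_2 = 2500\) ps,
  \(\alpha_1 = 0.5\), offset from the mean of the first 10 (pre-rise)
  bins, amplitude from the peak. These are typical free/bound NAD(P)H
  values; the optimizer is insensitive to ±20% perturbations on noiseless
  data (recovery to 0.1%).
* **Bounds**: \(\tau_1 \in [50, 1500]\) ps, \(\tau_2 \in [1000, 8000]\)
  ps, \(\alpha_1 \in [0,1]\), \(A, C \ge 0\) — physiological NAD(P)H
  ranges that also discourage component swapping. After convergence
  components are re-ordered so \(\tau_1 \le \tau_2\), swapping fractions
  along with lifetimes.
* **IRF alignment**: an integer-bin shift between IRF and data is
  estimated once per cube by refitting the summed (high-count) decay at
  each candidate shift and keeping the lowest-objective one. A simple
  correlation-peak match was evaluated and rejected: it aligns the IRF to
  the decay *maximum* rather than its rise (a +4 bin error on synthetic
  data with zero true shift), which crushes \(\tau_1\) into its lower
  bound.
* **Convergence**: relative cost decrease below \(10^{-8}\) or 200
  iterations; non-convergence marks the pixel invalid (`NA` maps) rather
  than raising.
* **\(\chi^2_r\)**: minimized objective divided by `n_bins − 5` (five
  free parameters). On correctly specified Poisson simulations the median
  sits near 1 from ~1000 binned photons upward (tested band 0.8–1.2).

Cell or region masks are accepted as label images from any external
segmentation tool; `make_cell_mask()` offers a simple intensity-threshold
fallback. Per-label summaries come from `aggregate_flim()`, which uses
valid pixels only and emits `NA` rows for labels without valid pixels.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated.

* **Decay cubes** (`simulate_decay_cube()`): per-pixel Poisson counts
  around `photons_target × shape + offset_rate`, where `shape` is the
  IRF-convolved biexponential normalized over the window. Determinism is
  guaranteed for a fixed seed, and variance equals mean by construction
  (tested).
* **Widefield pairs** (`simulate_widefield_pair()`): expected image
  `vignette × (background + mask × (cell − background))` with Poisson
  shot noise plus Gaussian read noise (default SD 1% of background — a
  CMOS camera model). Cells are random non-overlapping ellipses
  (semi-axes 5–12 px); the pipeline is morphology-agnostic, so simple
  geometry suffices. Vignetting follows a radial cosine-fourth falloff
  scaled by `vignette_strength` (default 0.15). Gel background defaults
  to 30–50% of the cell signal (e.g. NAD(P)H 400 vs 1000), reflecting
  weakly autofluorescent synthetic hydrogels; both levels are
  configurable.
* **Plates** (`simulate_plate()`): one image pair per (formulation,
  replicate, day). Each efficiency group carries an ORR trajectory over
  days; per-FOV truth adds Gaussian replicate jitter (default SD 0.01).
  The reference trajectory (`default_orr_trajectory()`) rises from day 6
  to day 10, falls by day 16, and continues declining through days 30 and
  100 — the qualitative pattern of cardiomyocyte differentiation followed
  by metabolic maturation. Imaging-day grids mirror common screen
  schedules (6/8/10/16; every 3 days to 30; every 10 days after).

What the generator does *not* emulate: cell morphology beyond ellipses,
intra-cell intensity texture, spatially varying lifetimes within a cube,
photobleaching, stage drift, or segmentation errors from confluent
cultures. Passing tests therefore demonstrate correctness of the
computational chain under the stated noise models, not robustness to all
real-microscopy artifacts.

## Problem sizes used in validation

Validation runs use deliberately compact geometries chosen to exercise the
full chain at desk scale: 192×192 px fields of view (the algorithms are
resolution-agnostic; radii and object sizes are configurable for the
2044×2048 geometry of a real 10× system), 32×32 decay cubes with 256 time
bins, screens of 12 formulations × 3 replicates × 4–6 days, 20-seed
repetitions for sign-pattern statistics and 200-seed repetitions for
power estimates.

## Screen-level statistics

`aggregate_screen()` validates and sorts per-FOV records;
`trajectory_report()` produces descriptive per-formulation and per-group
day series; `percent_change()` reports
\(100 (\bar x_b - \bar x_a)/\bar x_a\) between two days; and
`compare_groups()` implements Welch's unequal-variance t-test from the
standard formulas with Welch–Satterthwaite degrees of freedom (verified
against closed-form evaluation and `stats::t.test`).

Two conventions exist for percent change — differencing per-day group
means versus averaging per-gel changes — and screens rarely say which is
meant; both are implemented (`method = "group_means"` is the default,
`"per_gel"` the alternative) and agree when all gels change
proportionally.

Omnibus multi-group procedures (repeated-measures ANOVA, Welch ANOVA with
Dunnett's T3, Tukey) are deliberately not re-implemented: they are
standard off-the-shelf statistics peripheral to the imaging pipeline. The
`screen_table` CSV exports directly into any statistics environment for
those analyses.

## Known limitations

* The rolling-ball radius, threshold method and background-ROI policy are
  documented defaults, not reconstructions of any specific lab's manual
  protocol; manual ROI override is the faithful path where an operator
  chose the background locations.
* FLIM fitting covers the two-component NAD(P)H model only — no phasor
  analysis, no triexponential models, no FAD lifetimes.
* The ±8-bin IRF shift search assumes the IRF and data share the same bin
  width and a modest misalignment.
* At very high cell confluence the automatic background-ROI search fails
  by design (with an instructive error) rather than silently measuring
  contaminated regions.
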