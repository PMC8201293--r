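---
title: "Methods: threshold-cycle analysis for camera-based qPCR"
author: "qpcrcam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-cycle analysis for camera-based qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrcam)
```

## The analysis problem

A camera-based real-time PCR instrument photographs the reaction chamber
once per thermal cycle and reads the mean grayscale value of a region of
interest (ROI) as the relative fluorescence. The camera is not a calibrated
fluorimeter: the absolute intensity scale depends on the optics and sensor
gain of the individual device ("set"), and the threshold that defines the
threshold cycle (Ct) has no canonical value. This package calibrates the
log threshold against a reference instrument's Ct values by distance
minimization, equalizes inter-set gain differences by their endpoint
brightness ratio, and converts residual Ct discrepancies into bounds on the
relative error of the estimated initial concentration.

## Processing model

Each run's processing pipeline is:

1. **ROI quantification** (image mode): each frame is converted to
   grayscale and the arithmetic mean over the ROI pixels, at full floating
   precision, is the per-cycle intensity.
2. **Baseline normalization**: subtract the mean of the first
   `nBaseline = 10` cycles, removing the pre-amplification fluorescence
   offset contributed by the master mix and the optics.
3. **Log transform**: positive normalized values map to their logarithm;
   zero or negative values (routine before amplification, where the
   baseline-subtracted signal fluctuates around zero) are *undefined* and
   treated as below every threshold. This deliberately prevents early-cycle
   noise from producing spurious crossings.
4. **Ct calling**: the fractional cycle at the first upward crossing of the
   log threshold, linearly interpolated between the bracketing cycles. If
   the first defined value already exceeds the threshold (or the crossing
   has no defined predecessor to interpolate against), the integer cycle is
   returned; a curve that never reaches the threshold is *undetermined*
   (`NA`, serialized as the string `"undetermined"`).

### Threshold optimization

With reference Ct vector $C$ (one value per concentration of the dilution
series) and the system's Ct vector $\hat C(s,e,t)$ for set $s$, experiment
$e$ at log threshold $t$, the per-experiment objective is
$d(s,e,t) = \lVert C - \hat C(s,e,t)\rVert$. Pooled scopes (one set, or all
sets) aggregate all in-scope Ct pairs. Three aggregation modes exist:

* `rms` (default): Euclidean norm divided by $\sqrt{n}$, i.e. the RMS
  difference *per Ct measurement*. This is the scale on which a distance
  can be compared to a per-measurement replication SD, and it is invariant
  to how many experiments are pooled.
* `euclidean`: the raw norm over all pooled pairs.
* `sum`: the sum over experiments of per-experiment Euclidean norms.

The minimization is an exhaustive grid search (default step 0.01 log units
over the span of defined log values), because the objective is piecewise
smooth with flat plateaus — a gradient method would stall, and the grid
makes results reproducible to the step size. Ties are broken toward the
smallest threshold. Undetermined Ct values are excluded pairwise and
counted per threshold (`naAction = "exclude"`); the strict mode invalidates
any threshold with an undetermined in-scope Ct. Thresholds where no pair is
comparable are undefined and can never be minimizers.

### Inter-set calibration

Two sets of the same design generally reach different plateau intensities.
The calibration factor is the ratio of *endpoint means* — the mean
normalized intensity over cycles 35–40 (1-based, inclusive) across all of a
set's curves — of the reference set to the target set. The target set's
normalized curves are multiplied by this ratio **before** the log transform,
and the threshold search is re-run on the rescaled grid. Choices made here:

* Calibration acts on *normalized* (baseline-subtracted) intensities, not
  raw ones: the gain gap multiplies the signal, while the additive camera
  baseline is already removed, so a pure multiplicative correction is the
  right model.
* The reference set defaults to the brighter one (the dim set is raised).
* The ratio is kept at full precision by default; a one-decimal rounding
  mode (`"1dp"`) exists for workflows that apply a printed ratio such as
  1.8 instead of the exact quotient.

### From Ct error to concentration error

Under amplification efficiency $E$ (fold-change per cycle; 2 = perfect
doubling), a Ct discrepancy of $\Delta C_t$ cycles corresponds to a
relative initial-concentration error of $E^{\Delta C_t} - 1$
(`foldErrorFromCtError()`), reported as an integer percent by
`percentErrorBound()`: 0.8 cycles at doubling is 74%, 0.4 cycles is 32%.
Efficiency is a parameter; 2 is the default assumption throughout.

## The synthetic-data generator

No public raw data exist for camera-based chip runs of this design, so the
generator is a first-class module that defines the study conditions for all
recovery tests:

* **Curve model**: 4-parameter logistic in linear intensity,
  $I(c) = b + gP\,\sigma(k(c - c_0))$ — the standard sigmoidal qPCR shape,
  chosen because its closed form supports exact oracles. Defaults:
  baseline $b = 30$ and plateau gain $P = 74$ grayscale units (a bright
  set's normalized plateau on an 8-bit scale), slope $k = 0.6$ per cycle,
  giving a 10–90% rise of ≈ 7.3 cycles, typical of qPCR exponential
  phases.
* **Ground-truth Cq**: defined as the cycle where the noiseless
  *normalized* curve crosses 10% of its normalized plateau
  (`ctFraction = 0.1`). The logistic center is solved (by `uniroot`, to
  1e-12) so this crossing happens exactly at the requested `trueCq`; the
  recorded truth is therefore self-consistent with threshold-based Ct
  calling, and `ctReferenceLevel()` returns the log threshold that recovers
  it.
* **Design**: 2 sets × 4 experiments × 3 concentrations (10-fold series:
  1, 0.1, 0.01) × 40 cycles; set gains (1, 1/1.8) reproduce a 1.8×
  endpoint-intensity gap. The top concentration's Cq defaults to 20, so the
  dilution series sits at 20, 23.3, 26.6 cycles and all plateaus are
  reached before the endpoint window.
* **Stochastic components**, all seeded: replicate jitter on the true Cq
  (sd 0.2 cycles) and on the gain (relative sd 2%), and additive Gaussian
  readout noise (sd 0.3 grayscale units on the ROI-mean scale; per pixel
  when frames are rendered).
* **Rendering**: frames hold the curve value inside the ROI and a flat
  background elsewhere, with optional per-pixel noise, clipped to the
  camera's bit range (with a warning). Grayscale is the default; the RGB
  option puts the signal in the green channel, matching a camera viewing
  fluorescein emission. File output is zero-padded `cycle_NN.png`/`.tif`.

What the generator does **not** emulate: bubbles and other chamber
artifacts, flat-field/vignetting structure, LED or filter spectra, drift of
the optics over the run, and non-logistic curve pathologies. Passing
recovery tests therefore demonstrates the correctness of the computational
pipeline under the stated statistical structure, not robustness to every
optical artifact of real chips.

## Numerical choices and degenerate inputs

* **Grayscale weights**: BT.601 luma (0.299, 0.587, 0.114) by default, with
  a green-channel-only option; the conversion is documented configuration,
  not hidden in an image library.
* **Coordinates**: ROI rectangles are 0-based, half-open
  `[x, x+w) × [y, y+h)`; pinned so pixel-exact tests are possible. Polygon
  ROIs keep pixels whose centers fall inside the polygon.
* **Log base**: natural log by default, configurable (10, 2). A bright
  set's normalized plateau of ≈ 74 gives ln ≈ 4.3, which places useful
  thresholds in the 1–3.5 range.
* **Interpolation granularity**: linear interpolation of the log curve
  between integer cycles reproduces a known Cq to better than 0.01 cycles
  at the default slope; this is the resolution floor of the Ct caller.
* **Fractional Ct**: sub-cycle resolution is kept everywhere; distances of
  a few hundredths of a cycle are meaningful only because of it.
* **Degenerate inputs**: curves shorter than the baseline window, ROIs
  outside the frame, gaps or duplicate cycles in an image directory,
  non-positive endpoint means (a set that failed to amplify), and searches
  whose objective is undefined everywhere all raise stage-named errors
  rather than propagating silent `NA`s.
* **Determinism**: every stochastic step draws from an explicit seed
  (`withr::with_seed`), and pipeline artifacts contain no timestamps, so a
  seed reproduces outputs byte-for-byte.

## Problem sizes

The test-suite and example runs use the default 24-run grid (2 × 4 × 3,
40 cycles), threshold grids of roughly 10³ points, rendered frames of
48 × 64 to 110 × 120 pixels, and a 20-seed replication of the
calibration-efficacy check — sizes chosen so the full suite completes in
about a minute while keeping every statistical check well-powered.

## Known limitations

* The threshold search assumes the reference and system measured the same
  dilution series; there is no modeling of pipetting error in the series
  itself.
* Calibration is set-level and purely multiplicative; per-experiment or
  additive drift corrections are out of scope.
* Ct calling is threshold-crossing only; second-derivative-maximum or
  fit-based Cq estimators are deliberately not provided.
* Absolute quantification (copies/µL) is not attempted — all concentration
  statements are relative, anchored to the dilution series.
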