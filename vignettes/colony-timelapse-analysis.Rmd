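---
title: "Quantifying colony growth and fluorescent expression from plate timelapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colony growth and fluorescent expression from plate timelapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluolapse)
```

## The measurement problem

A fixed camera images an agar plate at regular intervals while engineered
bacterial colonies grow and constitutively express fluorescent proteins.
Each RGB frame carries, per pixel, the mixed emission of whatever protein
the local colony expresses. From such a stack we want, per colony:

* the **areal growth curve** and the maximal specific growth rate,
* the **fluorescent expression rate** — the production rate of fluorophore
  per unit colony area, corrected for dilution by growth,
* the **strain identity**, read from the ratio between the red and green
  camera channels.

The plate is stationary and illumination is constant, so no registration
or flat-field model is attempted; the only radiometric correction is a
per-channel background subtraction.

## Models

### Colony area

Colony area (px²) is modeled logistically,

$$A(t) = \frac{A_{max}}{1 + e^{-\mu_{max}(t - t_0)}},$$

with plateau area $A_{max}$, maximal specific growth rate $\mu_{max}$
(h⁻¹), and half-maximum time $t_0$ (h). The specific growth rate
$\mu(t) = \frac{1}{A}\frac{dA}{dt}$ then has the closed form

$$\mu(t) = \frac{\mu_{max}}{e^{\mu_{max}(t - t_0)} + 1},$$

which decays from $\mu_{max}$ (early, unconstrained growth) through
$\mu_{max}/2$ at $t_0$ toward 0 at the plateau. Fitting the area model
and differentiating analytically avoids numerically differentiating noisy
area estimates; the per-frame radius estimates are noisy mainly early on,
when the colony spans only a few pixels.

### Expression rate

Let $F = I/A$ be the mean fluorescence intensity per unit colony area —
the channel-summed signal inside the colony mask divided by the mask's
pixel count, a proxy for per-cell fluorophore concentration. Growth
dilutes fluorophore at rate $\mu F$, so constitutive production at rate
$K_F$ implies $dF/dt = K_F - \mu F$, and the estimator inverts this:

$$K_F(t) = \frac{d(I/A)}{dt} + \mu(t)\,\frac{I}{A}.$$

$F(t)$ is smoothed with a cubic smoothing spline whose analytic first
derivative supplies $d(I/A)/dt$; $\mu(t)$ always comes from the fitted
closed form, never from differencing data.

### Strain signature

Assuming emission intensity is linear in protein amount, each protein
pins a fixed ratio between the red and green channel totals of a colony,
i.e. a line through the origin in the $(R_{total}, G_{total})$ plane. A
signature is the through-origin least-squares slope
$\sum RG / \sum R^2$ fitted over the colonies of a single-strain plate;
an unknown colony with direction $\arctan(G/R)$ is assigned to the
angularly closest signature line. Angular distance makes the rule
invariant to colony brightness — the ratio, not the magnitude, is the
protein's fingerprint. The blue channel is carried but unused by default:
with the three proteins this system targets, red and green already
separate the signatures cleanly, and the blue channel has the lowest
signal. Ties are broken to the lexicographically first label and flagged
with a zero runner-up margin.

## Pipeline and parameters

1. **Load and correct** (`load_timelapse`, `subtract_background`).
   Frames are promoted to doubles in digital levels; times are hours
   throughout, so rates carry h⁻¹. The default background estimator is
   the per-channel median of the first frame — colonies are absent or
   tiny there, and the median ignores the few bright pixels. A per-pixel
   temporal-minimum alternative also removes static spatial structure.
   Saturated frames warn rather than error.
2. **Project and detect** (`temporal_sum_projection`,
   `smooth_projection`, `detect_colonies`). Summing all channels over
   all frames makes every colony bright regardless of when it appeared.
   After Gaussian smoothing (default `sigma_smooth = 2` px), a
   scale-normalized Laplacian-of-Gaussian detector scans a logarithmic
   scale ladder (defaults `min_sigma = 3`, `max_sigma = 30` px, 10
   scales — a colony of 500–1000 µm spans tens of pixels at whole-plate
   magnification). Detection runs on the smoothed projection. The
   response threshold is relative to the image maximum (default 0.05);
   overlapping detections are suppressed keeping the stronger response,
   and labels are assigned row-major so identical inputs give identical
   labels. Peak scales are refined by parabolic interpolation on
   log-sigma, which removes most of the ladder-quantization error.
3. **Square ROIs** (`make_rois`). Half-width `= max(1, round(3·sigma))`:
   ±3σ contains essentially the entire blob.
4. **Per-frame radius** (`radius_series`). The detector reruns on each
   ROI crop; the blob nearest the ROI center gives the scale, converted
   as `radius = sigma·√2` because the scale-normalized LoG response of a
   uniform disc peaks when the disc edge lies at √2σ. One response
   threshold — relative to the brightest crop of the whole series — is
   shared across frames, so pre-appearance frames stay empty and yield
   missing radii. Missing radii are excluded from fitting, not imputed
   as zero, which would bias $t_0$.
5. **Growth fit** (`fit_growth_model`). Levenberg–Marquardt least
   squares with data-driven starts ($A_{max}^0$ = max area, $t_0^0$ =
   first crossing of half-max, $\mu_{max}^0 = 4A'(t_0^0)/A_{max}^0$ from
   the logistic midpoint-slope identity), positivity bounds on
   $A_{max}$ and $\mu_{max}$, and a tight convergence tolerance
   (`ftol = ptol = 1e-15`). A neutral fallback start covers degenerate
   initializations. Times are used exactly as supplied.
6. **Intensity and $K_F$** (`intensity_series`, `smooth_trace`,
   `expression_rate`). The colony mask is the disc of the *fitted*
   radius $r(t) = \sqrt{A_{fit}(t)/\pi}$, not the noisy per-frame
   radius. The spline's smoothing level is chosen so its residual sum of
   squares hits the target `smoothing_factor`; the default,
   `n · (median |ΔF|)²`, is a plug-in for `n·σ²` under white noise.
   `smoothing_factor = 0` interpolates. Evaluation outside the fitted
   time range is an error, never extrapolation.
7. **Classification** (`channel_totals`, `fit_signature`,
   `classify_colonies`). Channel totals default to the endpoint frame
   (the final image is where colonies are brightest); summing over all
   frames is available as `reference = "time_sum"`.

`analyze_plate` chains all stages in memory; `run_analysis` adds disk
I/O, CSV outputs, and a parameter log; `exec/fluolapse` wraps both for
the shell. The analysis path contains no randomness.

## The synthetic plate generator

`render_plate` draws each colony as a disc of radius
$\sqrt{A(t)/\pi}$ with the logistic $A(t)$, fills it with
$F(t)\,(e_R, e_G, e_B)$ where $F$ solves $dF/dt = K_F - \mu(t)F$ by
fixed-step fourth-order Runge–Kutta (step ≤ 0.01 h), antialiases disc
edges by a one-pixel linear coverage ramp, and adds per-channel
background plus seeded additive Gaussian noise before clipping to the
digital range. Emission vectors are normalized to channel-sum 1, so the
channel-summed estimator targets $K_F$ directly and recovery tests are
sharp.

Default scenario conditions: 8-bit frames at 0.5 h intervals, background
(12, 9, 6), noise σ = 2 digital levels, $\mu_{max} = 0.5$ h⁻¹, plateau
areas 1500–3000 px² (whole-plate scale) and half-max times of 8–12 h —
values typical of *E. coli* colonies imaged overnight at room
temperature on a low-cost RGB camera, where read noise of a few levels
on a 0–255 scale and colony diameters of tens of pixels are realistic.
Amplitudes stay below ~200 levels so the default scenarios never clip.

What the simulator deliberately omits: optics (lens PSF, vignetting,
filter spectra), Poisson photon statistics, colony morphology beyond
discs (no sectoring), colony–colony interactions, and photobleaching or
fluorophore maturation. Passing recovery tests therefore demonstrates
the estimators' correctness under the stated generative model, not
robustness to every artifact of real plates; on real data the background
model and the disc assumption are the first things to check.

## Numerical choices and edge cases

* Convolution is separable with a 4σ-truncated normalized kernel and
  symmetric-reflection boundary; the discrete Laplacian replicates edge
  values. Both choices make constant images fixed points, so uniform
  offsets (e.g. residual background) cannot fake border blobs.
* Positions are `(row, col)`, 0-based, pixel centers at integer
  coordinates, shared by every stage.
* Blank or constant images yield empty detection results, not errors;
  fewer than four usable frames is an error for both the growth fit and
  the spline.
* A colony whose `(R, G)` totals are both zero is reported as
  unclassifiable rather than assigned arbitrarily.
* Frames written to disk are integer-quantized by the image format;
  `render_plate(quantize = TRUE)` reproduces exactly what a written
  plate reads back as.

## Validation problem sizes

The bundled validation scenarios use a 512×512 plate with 12 colonies
for detection (precision = recall = 1 demanded, centers within 2 px), a
640×640 plate with 20 colonies for growth- and expression-rate recovery
(median $\hat\mu_{max}$ error ≤ 10%; mean $\hat K_F$ over
$t_0 \pm 2/\mu_{max}$ within 15% for ≥ 18/20), and three 10-colony
single-strain plates plus one 30-colony mixed plate for classification
(30/30), with channel ratios 2.5, 1.0 and 0.35. These sizes exercise
every stage at realistic colony densities while keeping a full run in
minutes on one core.

## Known limitations

* Fused or overlapping colonies are not split (no watershed); the
  simulator refuses to generate them unless explicitly allowed.
* The logistic is the only growth model offered; Gompertz-like
  asymmetries will bias $\mu_{max}$ slightly.
* Expression rates are channel-summed, not per-channel; co-expression
  within one colony is out of scope, as is spectral unmixing.
* The per-frame radius is unreliable below ~3 px; early-time areas rely
  on the model fit rather than direct measurement.
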