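# fluolapse

Quantitative analysis of timelapse RGB image stacks of agar plates
bearing fluorescent bacterial colonies — the kind produced by low-cost,
fixed-camera plate imagers. For microbiologists and synthetic biologists
who want per-colony growth kinetics, reporter expression rates, and
strain identities out of a directory of PNG/TIFF frames.

## What it computes

For every colony detected on the plate:

* **Logistic growth fit.** Colony area follows
  `A(t) = Amax / (1 + exp(-mu_max (t - t0)))`; the package estimates
  `Amax` (px²), the maximal specific growth rate `mu_max` (h⁻¹), and the
  half-maximum time `t0` (h) by nonlinear least squares on per-frame
  radius estimates from a multiscale Laplacian-of-Gaussian blob
  detector. The specific growth rate follows analytically:
  `mu(t) = mu_max / (exp(mu_max (t - t0)) + 1)`.
* **Dilution-corrected expression rate.** With `F = I/A` the mean
  fluorescence per unit colony area,
  `KF(t) = dF/dt + mu(t) F` — the `mu F` term restores what growth
  dilutes — using a smoothing spline's analytic derivative for `dF/dt`.
* **Strain classification.** Each fluorescent protein pins a
  characteristic ratio between the red and green channel totals; a
  colony is assigned to the strain whose through-origin line in the
  (R, G) plane is angularly closest to its own direction.

A fully seeded synthetic plate simulator (`plate_spec`, `render_plate`)
generates stacks with known ground truth for every quantity above and
backs the test suite.

## Worked example

Simulate a small plate, analyze it, and compare to ground truth:

```r
library(fluolapse)

co <- colony_spec(center_rc = c(60, 60), Amax = 2000, mu_max = 0.5,
                  t0 = 10, KF = 8, F0 = 0.5,
                  emission = c(0.25, 0.6, 0.15), label = "cyofp")
spec <- plate_spec(image_shape = c(128, 128), n_frames = 40,
                   frame_interval_h = 0.5, background = c(12, 9, 6),
                   noise_sigma = 2, bit_depth = 8, seed = 7,
                   colonies = list(co))
rp <- render_plate(spec)

st    <- subtract_background(rp$stack)
proj  <- smooth_projection(temporal_sum_projection(st), 2)
blobs <- detect_colonies(proj)
rois  <- make_rois(blobs, 3, dim(st$frames)[2:3])
fit   <- fit_growth_model(radius_series(st, rois[1, ]))
fit
#> growth_fit (colony 0): Amax = 2038 px^2, mu_max = 0.5056 /h, t0 = 9.976 h
#>   residual rms 10.1 px^2 over 36 points

it  <- intensity_series(st, rois[1, ], fit)
sm  <- smooth_trace(it)
win <- st$times[abs(st$times - fit$t0) <= 2 / fit$mu_max]
mean(expression_rate(sm, fit, win)$KF)
#> [1] 8.446925
```

The fit recovers the simulated `Amax = 2000` px², `mu_max = 0.5` h⁻¹ and
`t0 = 10` h to within a few percent from 36 usable frames, and the
time-averaged expression rate estimate (8.45 intensity px⁻¹ h⁻¹ against
a true `KF = 8`) lands within the 15% window the recovery tests demand.

For whole directories of frames, `run_analysis(analysis_config(...))`
writes `colonies.csv`, `timeseries.csv` and optionally
`classifications.csv`; the same is reachable from the shell via

```sh
Rscript exec/fluolapse analyze --input frames/ --interval 0.5 --out results/
Rscript exec/fluolapse simulate --spec plate.json --out frames/
Rscript exec/fluolapse fit-signatures --input gfp/,ofp/,rfp/ \
    --labels gfp,ofp,rfp --interval 0.5 --out signatures.csv
```

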