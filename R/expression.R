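# logical mask of ROI-crop pixels inside the circle of radius r around
# center (0-based global row/col); pixel centers at integer coordinates
roi_disc_mask <- function(roi, center_row, center_col, r) {
  rows <- roi$row0:(roi$row1 - 1)
  cols <- roi$col0:(roi$col1 - 1)
  dr2 <- outer((rows - center_row)^2, (cols - center_col)^2, `+`)
  dr2 <= r^2
}

#' Mean fluorescence intensity per unit colony area over time
#'
#' At every frame, the colony mask is the disc of the FITTED radius
#' `r(t) = sqrt(A_fit(t) / pi)` centered on the detected blob center,
#' intersected with the ROI. `total_I` sums the three channel values over
#' the mask, `n_pixels` is the mask size, and `mean_F = total_I / n_pixels`
#' is the mean intensity per unit area (the `I/A` entering the expression
#' rate). The fitted radius is used rather than the noisy per-frame radius
#' so the mask grows smoothly.
#'
#' @param stack background-subtracted [timelapse].
#' @param roi one ROI row from [make_rois()].
#' @param fit the colony's `growth_fit`.
#' @param blob_center optional `(row, col)` override of the mask center;
#'   defaults to the ROI's blob center.
#' @return An `intensity_trace` data.frame: `colony_id`, `time_h`,
#'   `total_I`, `n_pixels`, `mean_F`.
#' @export
intensity_series <- function(stack, roi, fit, blob_center = NULL) {
  stopifnot(inherits(stack, "timelapse"), inherits(fit, "growth_fit"))
  if (is.null(blob_center)) blob_center <- c(roi$row, roi$col)
  tt <- stack$times
  r_t <- predict(fit, tt, what = "radius")
  total_I <- numeric(length(tt))
  n_pixels <- integer(length(tt))
  for (t in seq_along(tt)) {
    mask <- roi_disc_mask(roi, blob_center[1], blob_center[2], r_t[t])
    n_pixels[t] <- sum(mask)
    if (n_pixels[t] > 0) {
      rows <- (roi$row0 + 1):roi$row1
      cols <- (roi$col0 + 1):roi$col1
      csum <- stack$frames[t, rows, cols, 1] +
        stack$frames[t, rows, cols, 2] + stack$frames[t, rows, cols, 3]
      total_I[t] <- sum(csum[mask])
    }
  }
  if (all(n_pixels == 0)) stop("empty colony mask at every frame")
  structure(
    data.frame(colony_id = roi$colony_id, time_h = tt, total_I = total_I,
               n_pixels = n_pixels,
               mean_F = ifelse(n_pixels > 0, total_I / n_pixels, NA_real_)),
    class = c("intensity_trace", "data.frame"))
}

# scipy-style smoothing target: pick the roughness penalty whose residual
# sum of squares matches `s` (RSS is monotone in the penalty), by bisection
# on log10(lambda).
fit_spline_rss <- function(t, y, s) {
  rss_of <- function(lambda) {
    f <- tryCatch(
      stats::smooth.spline(t, y, lambda = lambda, cv = FALSE,
                           all.knots = TRUE, keep.data = FALSE),
      error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    sum((stats::predict(f, t)$y - y)^2)
  }
  # shrink the bracket until smooth.spline accepts both endpoints
  lo <- -12; hi <- 12
  while (is.na(rss_of(10^lo)) && lo < 0) lo <- lo + 1
  while (is.na(rss_of(10^hi)) && hi > 0) hi <- hi - 1
  if (rss_of(10^hi) <= s) {
    lam <- 10^hi
  } else if (rss_of(10^lo) >= s) {
    lam <- 10^lo
  } else {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      r <- rss_of(10^mid)
      if (is.na(r) || r < s) lo <- mid else hi <- mid
    }
    lam <- 10^((lo + hi) / 2)
  }
  stats::smooth.spline(t, y, lambda = lam, cv = FALSE, all.knots = TRUE,
                       keep.data = FALSE)
}

#' Smooth an intensity trace with a differentiable spline
#'
#' Fits a cubic smoothing spline to `(time, mean_F)` whose residual sum of
#' squares is driven to `smoothing_factor`; the spline's first derivative
#' is available analytically. `smoothing_factor = 0` interpolates the data
#' (natural cubic spline). The default factor is
#' `n * noise_scale^2` with `noise_scale` the median absolute successive
#' difference of `mean_F` — a plug-in estimate of the per-point noise
#' variance times the number of points.
#'
#' @param trace an `intensity_trace` (rows with missing `mean_F` are
#'   dropped).
#' @param smoothing_factor target residual sum of squares; `NULL` for the
#'   default described above.
#' @return A `smoothed_trace` with elements `F` and `dF` (functions of time,
#'   defined only on the fitted range), `range`, `smoothing_factor`,
#'   `colony_id`.
#' @export
smooth_trace <- function(trace, smoothing_factor = NULL) {
  ok <- is.finite(trace$mean_F)
  t <- trace$time_h[ok]
  y <- trace$mean_F[ok]
  if (length(t) < 4) stop("insufficient points: need >= 4, have ", length(t))
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (is.null(smoothing_factor)) {
    noise_scale <- stats::median(abs(diff(y)))
    smoothing_factor <- length(y) * noise_scale^2
  }
  if (smoothing_factor < 0) stop("`smoothing_factor` must be >= 0")

  if (smoothing_factor == 0) {
    sf <- stats::splinefun(t, y, method = "natural")
    Ffun <- function(x) sf(x)
    dFfun <- function(x) sf(x, deriv = 1)
  } else {
    fit <- fit_spline_rss(t, y, smoothing_factor)
    Ffun <- function(x) stats::predict(fit, x)$y
    dFfun <- function(x) stats::predict(fit, x, deriv = 1)$y
  }
  rng <- range(t)
  guard <- function(f) function(x) {
    if (any(x < rng[1] - 1e-9) || any(x > rng[2] + 1e-9))
      stop("evaluation outside the fitted time range [",
           signif(rng[1], 6), ", ", signif(rng[2], 6), "]")
    f(x)
  }
  structure(list(F = guard(Ffun), dF = guard(dFfun), range = rng,
                 smoothing_factor = smoothing_factor,
                 colony_id = trace$colony_id[1]),
            class = "smoothed_trace")
}

#' Dilution-corrected fluorescent expression rate
#'
#' Estimates the per-area fluorescent protein expression rate
#' `KF(t) = d(I/A)/dt + mu(t) * (I/A)`: the first term is the apparent rate
#' of change of the mean intensity per area, and the `mu * (I/A)` term
#' restores what colony growth dilutes away. `I/A` and its derivative come
#' from the smoothing spline; `mu(t)` comes from the closed form of the
#' fitted logistic model, never from differentiating data.
#'
#' @param smoothed a `smoothed_trace`.
#' @param fit the colony's `growth_fit`.
#' @param times evaluation times, hours; must lie within the smoothed
#'   trace's range.
#' @return An `expression_rate_curve` data.frame: `colony_id`, `time_h`,
#'   `KF` (intensity px^-1 h^-1).
#' @export
expression_rate <- function(smoothed, fit, times) {
  stopifnot(inherits(smoothed, "smoothed_trace"), inherits(fit, "growth_fit"))
  Fv <- smoothed$F(times)
  dFv <- smoothed$dF(times)
  mu <- growth_rate_curve(fit, times)
  structure(
    data.frame(colony_id = smoothed$colony_id, time_h = times,
               KF = dFv + mu * Fv),
    class = c("expression_rate_curve", "data.frame"))
}
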