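#' Logistic colony area model
#'
#' `A(t) = Amax / (1 + exp(-mu_max * (t - t0)))`: the colony area saturates
#' at `Amax` (px^2), expands fastest around the half-maximum time `t0`
#' (hours), and `mu_max` (1/h) is the maximal specific growth rate. The
#' matching specific growth rate `(1/A) dA/dt` has the closed form
#' `mu(t) = mu_max / (exp(mu_max * (t - t0)) + 1)`.
#'
#' @param t time(s), hours.
#' @param Amax plateau area, px^2.
#' @param mu_max maximal specific growth rate, 1/h.
#' @param t0 half-maximum time, hours.
#' @return Area in px^2 (`logistic_area`) or specific growth rate in 1/h
#'   (`logistic_growth_rate`).
#' @export
logistic_area <- function(t, Amax, mu_max, t0) {
  Amax / (1 + exp(-mu_max * (t - t0)))
}

#' @rdname logistic_area
#' @export
logistic_growth_rate <- function(t, mu_max, t0) {
  mu_max / (exp(mu_max * (t - t0)) + 1)
}

#' Per-frame colony radius inside an ROI
#'
#' For every frame, the channel-summed ROI crop is lightly smoothed and the
#' blob detector is run on it; the blob nearest the ROI center gives the
#' colony's Gaussian scale, converted to a radius as
#' `radius = sigma * sqrt(2)` (the scale-normalized LoG response of a
#' uniform disc peaks when the disc edge sits at `sqrt(2) * sigma`). Frames
#' with no accepted detection yield a missing radius.
#'
#' @param stack background-subtracted [timelapse].
#' @param roi one row of the data.frame from [make_rois()].
#' @param min_sigma,max_sigma,n_scales,threshold detector parameters for the
#'   per-frame crops; `max_sigma = NULL` uses the ROI half-width / sqrt(2).
#' @param sigma_smooth pre-smoothing of each crop, pixels.
#' @param max_center_dist accept only blobs within this distance (pixels) of
#'   the ROI center.
#' @return A `growth_trace`: data.frame with `colony_id`, `time_h`,
#'   `radius_px`, `area_px2` (`area = pi * radius^2` where defined).
#' @export
radius_series <- function(stack, roi, min_sigma = 1.5, max_sigma = NULL,
                          n_scales = 14, threshold = 0.05,
                          sigma_smooth = 1, max_center_dist = NULL) {
  stopifnot(inherits(stack, "timelapse"))
  H <- dim(stack$frames)[2]; W <- dim(stack$frames)[3]
  if (roi$row0 < 0 || roi$col0 < 0 || roi$row1 > H || roi$col1 > W)
    stop("ROI outside image bounds")
  if (is.null(max_sigma)) max_sigma <- max(min_sigma * 2, roi$half_width / sqrt(2))
  if (is.null(max_center_dist)) max_center_dist <- roi$half_width / 2
  # ROI center in crop coordinates (0-based)
  c_row <- roi$row - roi$row0
  c_col <- roi$col - roi$col0

  # one response scale for the whole series: threshold relative to the
  # brightest smoothed crop, so noise-only frames before the colony
  # appears stay empty
  crops <- lapply(seq_len(n_frames(stack)), function(t)
    smooth_projection(crop_channel_sum(stack, roi, t), sigma_smooth))
  abs_thresh <- threshold * max(vapply(crops, max, numeric(1)))

  radius <- rep(NA_real_, n_frames(stack))
  for (t in seq_len(n_frames(stack))) {
    blobs <- detect_colonies(crops[[t]], min_sigma = min_sigma,
                             max_sigma = max_sigma, n_scales = n_scales,
                             threshold_abs = abs_thresh)
    if (nrow(blobs) == 0) next
    d <- sqrt((blobs$row - c_row)^2 + (blobs$col - c_col)^2)
    if (min(d) > max_center_dist) next
    radius[t] <- blobs$sigma[which.min(d)] * sqrt(2)
  }
  structure(
    data.frame(colony_id = roi$colony_id, time_h = stack$times,
               radius_px = radius, area_px2 = pi * radius^2),
    class = c("growth_trace", "data.frame"))
}

#' Fit the logistic area model to a growth trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `A(t) = Amax / (1 + exp(-mu_max (t - t0)))` to the frames with a defined
#' area. Starting values: `Amax0` = maximum observed area, `t00` = earliest
#' time the area reaches `Amax0 / 2`, and `mu_max0 = 4 A'(t00) / Amax0`
#' (the logistic midpoint-slope identity), with `A'` by finite difference.
#' `Amax` and `mu_max` are bounded below by 0.
#'
#' @param trace a `growth_trace` from [radius_series()], or any data.frame
#'   with `time_h` and `area_px2`.
#' @return A `growth_fit` list: `colony_id`, `Amax`, `mu_max`, `t0`,
#'   `residual_rms`, `n_points_used`, `convergence`.
#' @export
fit_growth_model <- function(trace) {
  ok <- is.finite(trace$area_px2)
  if (sum(ok) < 4)
    stop("insufficient points: need >= 4 frames with a defined area, have ",
         sum(ok))
  t <- trace$time_h[ok]
  A <- trace$area_px2[ok]

  Amax0 <- max(A)
  i0 <- which(A >= Amax0 / 2)[1]
  t00 <- t[i0]
  # midpoint slope by central (or one-sided) finite difference
  slope <- if (i0 > 1 && i0 < length(t)) {
    (A[i0 + 1] - A[i0 - 1]) / (t[i0 + 1] - t[i0 - 1])
  } else if (i0 < length(t)) {
    (A[i0 + 1] - A[i0]) / (t[i0 + 1] - t[i0])
  } else {
    (A[i0] - A[i0 - 1]) / (t[i0] - t[i0 - 1])
  }
  mu0 <- 4 * slope / Amax0
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- 1

  df <- data.frame(t = t, A = A)
  do_fit <- function(start) minpack.lm::nlsLM(
    A ~ Amax / (1 + exp(-mu_max * (t - t0))), data = df,
    start = start,
    lower = c(Amax = .Machine$double.eps, mu_max = .Machine$double.eps,
              t0 = -Inf),
    control = minpack.lm::nls.lm.control(
      ftol = 1e-15, ptol = 1e-15, maxiter = 500))
  fit <- tryCatch(
    do_fit(list(Amax = Amax0, mu_max = mu0, t0 = t00)),
    error = function(e) tryCatch(
      # fallback start if the data-driven one is degenerate
      do_fit(list(Amax = Amax0 * 1.2, mu_max = 1, t0 = stats::median(t))),
      error = function(e2) stop("growth model fit failed: ",
                                conditionMessage(e2))))
  p <- stats::coef(fit)
  structure(
    list(colony_id = trace$colony_id[1], Amax = unname(p["Amax"]),
         mu_max = unname(p["mu_max"]), t0 = unname(p["t0"]),
         residual_rms = sqrt(mean(stats::resid(fit)^2)),
         n_points_used = sum(ok),
         convergence = fit$convInfo$isConv %||% TRUE),
    class = "growth_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "growth_fit (colony %s): Amax = %.4g px^2, mu_max = %.4g /h, t0 = %.4g h\n",
    format(x$colony_id), x$Amax, x$mu_max, x$t0))
  cat(sprintf("  residual rms %.4g px^2 over %d points\n",
              x$residual_rms, x$n_points_used))
  invisible(x)
}

#' Evaluate a fitted growth model
#'
#' @param object a `growth_fit`.
#' @param times hours.
#' @param what `"area"` (px^2), `"radius"` (px, `sqrt(A/pi)`, the fitted
#'   radius curve used for masking), or `"mu"` (1/h).
#' @param ... unused.
#' @export
predict.growth_fit <- function(object, times, what = c("area", "radius", "mu"),
                               ...) {
  what <- match.arg(what)
  switch(what,
    area = logistic_area(times, object$Amax, object$mu_max, object$t0),
    radius = sqrt(logistic_area(times, object$Amax, object$mu_max,
                                object$t0) / pi),
    mu = logistic_growth_rate(times, object$mu_max, object$t0))
}

#' Specific growth-rate curve of a fitted colony
#'
#' Evaluates the closed-form specific growth rate
#' `mu(t) = mu_max / (exp(mu_max (t - t0)) + 1)` of the fitted logistic
#' model; values fall in `(0, mu_max)`, approaching `mu_max` long before
#' `t0` and 0 long after.
#'
#' @param fit a `growth_fit`.
#' @param times hours.
#' @return numeric vector of mu values, 1/h.
#' @export
growth_rate_curve <- function(fit, times) {
  stopifnot(inherits(fit, "growth_fit"))
  logistic_growth_rate(times, fit$mu_max, fit$t0)
}

#' Kymograph of an ROI's central row
#'
#' The channel-summed pixel signal along the ROI's central image row,
#' across all frames: a space-time picture of the colony's radial
#' expansion.
#'
#' @param stack a [timelapse].
#' @param roi one ROI row from [make_rois()].
#' @return A `kymograph` list: `values` (`T x W_roi` matrix), `times`,
#'   `colony_id`, `center_col` (0-based column of the ROI center within the
#'   crop).
#' @export
kymograph <- function(stack, roi) {
  stopifnot(inherits(stack, "timelapse"))
  r <- roi$row + 1                       # central row, 1-based
  cols <- (roi$col0 + 1):roi$col1
  vals <- stack$frames[, r, cols, 1] + stack$frames[, r, cols, 2] +
    stack$frames[, r, cols, 3]
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  structure(list(values = vals, times = stack$times,
                 colony_id = roi$colony_id,
                 center_col = roi$col - roi$col0),
            class = "kymograph")
}
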