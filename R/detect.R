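#' Temporal sum projection
#'
#' Sums all channels of all frames per pixel, collapsing the stack to a
#' single 2-D image in which every colony that appears at any time is
#' bright. This is the image colonies are detected on.
#'
#' @param stack a background-subtracted [timelapse].
#' @return An `H x W` numeric matrix.
#' @export
temporal_sum_projection <- function(stack) {
  stopifnot(inherits(stack, "timelapse"))
  apply(stack$frames, c(2, 3), sum)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# Separable convolution as banded-matrix products (BLAS-backed, exact
# w.r.t. the truncated normalized kernel). Boundary: symmetric reflection
# (edge pixel repeated), so constant images stay constant at the border
# and uniform offsets produce no edge response in the blob detector.
conv_sep <- function(image, kernel) {
  band <- function(n) {
    r <- (length(kernel) - 1L) / 2L
    B <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      while (any(j < 1 | j > n)) {
        j <- ifelse(j < 1, 1L - j, j)
        j <- ifelse(j > n, 2L * n + 1L - j, j)
      }
      B[cbind(i, j)] <- B[cbind(i, j)] + kernel[o + r + 1L]
    }
    B
  }
  band(nrow(image)) %*% image %*% t(band(ncol(image)))
}

#' Gaussian smoothing of a projection image
#'
#' Low-pass filters a 2-D image with a normalized, truncated (4 sigma)
#' Gaussian kernel applied separably; the boundary is handled by symmetric
#' reflection. `sigma_smooth = 0` returns the input unchanged.
#'
#' @param image 2-D numeric matrix.
#' @param sigma_smooth Gaussian standard deviation in pixels (>= 0).
#' @return The smoothed matrix, same shape.
#' @export
smooth_projection <- function(image, sigma_smooth) {
  stopifnot(is.matrix(image))
  if (sigma_smooth < 0) stop("`sigma_smooth` must be >= 0")
  if (sigma_smooth == 0) return(image)
  conv_sep(image, gaussian_kernel_1d(sigma_smooth))
}

# 5-point discrete Laplacian, replicate boundary (no spurious edge
# response on constant images or uniform offsets).
laplacian <- function(x) {
  H <- nrow(x); W <- ncol(x)
  up <- rbind(x[-1, , drop = FALSE], x[H, , drop = FALSE])
  down <- rbind(x[1, , drop = FALSE], x[-H, , drop = FALSE])
  left <- cbind(x[, -1, drop = FALSE], x[, W, drop = FALSE])
  right <- cbind(x[, 1, drop = FALSE], x[, -W, drop = FALSE])
  up + down + left + right - 4 * x
}

# Strict-interior local maxima of a 3-D response array (26-neighborhood),
# returned as an index matrix (row, col, scale).
local_maxima_3d <- function(resp, thresh) {
  d <- dim(resp)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- resp
  nb_max <- array(-Inf, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    nb <- pad[(2:(d[1] + 1)) + di, (2:(d[2] + 1)) + dj,
              (2:(d[3] + 1)) + dk, drop = FALSE]
    nb_max <- pmax(nb_max, nb)
  }
  which(resp >= nb_max & resp >= thresh & resp > 0, arr.ind = TRUE)
}

#' Detect colonies as multiscale Gaussian blobs
#'
#' Runs a scale-normalized Laplacian-of-Gaussian detector over a logarithmic
#' scale ladder from `min_sigma` to `max_sigma`. Bright, approximately
#' isotropic spots give positive response maxima in (row, col, scale) space.
#' The scale at the peak is refined by parabolic interpolation on log(sigma);
#' overlapping detections (center distance below the sum of the blob radii,
#' radius = sqrt(2) * sigma) are suppressed keeping the stronger response.
#' Blobs are labeled `0 .. n-1` in row-major order of their centers.
#'
#' @param image 2-D numeric matrix, typically the smoothed temporal sum
#'   projection.
#' @param min_sigma,max_sigma blob scale ladder bounds in pixels.
#' @param n_scales number of ladder steps.
#' @param threshold response threshold relative to the maximum of `image`;
#'   a blank or constant image yields an empty result.
#' @param threshold_abs optional absolute response threshold; overrides
#'   `threshold` (used when several images must share one response scale,
#'   as in the per-frame radius series).
#' @return A data.frame with columns `colony_id`, `row`, `col` (0-based pixel
#'   centers), `sigma`, `response`.
#' @export
detect_colonies <- function(image, min_sigma = 3, max_sigma = 30,
                            n_scales = 10, threshold = 0.05,
                            threshold_abs = NULL) {
  stopifnot(is.matrix(image))
  if (!(min_sigma > 0 && min_sigma < max_sigma))
    stop("need 0 < min_sigma < max_sigma")
  if (threshold < 0) stop("`threshold` must be >= 0")
  empty <- data.frame(colony_id = integer(), row = numeric(),
                      col = numeric(), sigma = numeric(),
                      response = numeric())
  if (max(image) <= 0) return(empty)

  sigmas <- exp(seq(log(min_sigma), log(max_sigma), length.out = n_scales))
  resp <- array(0, dim = c(nrow(image), ncol(image), n_scales))
  for (s in seq_along(sigmas)) {
    sm <- conv_sep(image, gaussian_kernel_1d(sigmas[s]))
    resp[, , s] <- -sigmas[s]^2 * laplacian(sm)
  }

  thresh <- if (!is.null(threshold_abs)) threshold_abs else
    threshold * max(image)
  peaks <- local_maxima_3d(resp, thresh = thresh)
  if (nrow(peaks) == 0) return(empty)

  sigma_hat <- numeric(nrow(peaks))
  value <- numeric(nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    i <- peaks[p, 1]; j <- peaks[p, 2]; s <- peaks[p, 3]
    value[p] <- resp[i, j, s]
    if (s > 1 && s < n_scales) {
      # parabola through the three log-scale samples around the peak
      y <- resp[i, j, (s - 1):(s + 1)]
      denom <- y[1] - 2 * y[2] + y[3]
      off <- if (denom < 0) 0.5 * (y[1] - y[3]) / denom else 0
      off <- max(-0.5, min(0.5, off))
      lstep <- log(sigmas[2]) - log(sigmas[1])
      sigma_hat[p] <- exp(log(sigmas[s]) + off * lstep)
    } else sigma_hat[p] <- sigmas[s]
  }

  blobs <- data.frame(row = peaks[, 1] - 1, col = peaks[, 2] - 1,
                      sigma = sigma_hat, response = value)
  blobs <- blobs[order(-blobs$response, blobs$row, blobs$col), , drop = FALSE]

  keep <- logical(nrow(blobs))
  for (p in seq_len(nrow(blobs))) {
    if (!any(keep)) { keep[p] <- TRUE; next }
    k <- which(keep)
    dist <- sqrt((blobs$row[p] - blobs$row[k])^2 +
                 (blobs$col[p] - blobs$col[k])^2)
    rad <- sqrt(2) * (blobs$sigma[p] + blobs$sigma[k])
    keep[p] <- all(dist >= rad)
  }
  blobs <- blobs[keep, , drop = FALSE]
  blobs <- blobs[order(blobs$row, blobs$col, -blobs$response), , drop = FALSE]
  rownames(blobs) <- NULL
  cbind(colony_id = seq_len(nrow(blobs)) - 1L, blobs)
}

#' Square regions of interest around detected blobs
#'
#' Each blob's square ROI is sized from its Gaussian scale:
#' `half_width = max(1, round(roi_scale * sigma))`, and the half-open pixel
#' ranges `[row0, row1)`, `[col0, col1)` (0-based) are clipped to the image.
#'
#' @param blobs data.frame from [detect_colonies()].
#' @param roi_scale multiple of sigma per half-width; the default 3 captures
#'   essentially the whole blob (3 sigma).
#' @param image_shape integer `(H, W)`.
#' @return data.frame with columns `colony_id`, `row`, `col`, `sigma`,
#'   `half_width`, `row0`, `row1`, `col0`, `col1`.
#' @export
make_rois <- function(blobs, roi_scale = 3, image_shape) {
  if (roi_scale <= 0) stop("`roi_scale` must be > 0")
  H <- image_shape[1]; W <- image_shape[2]
  hw <- pmax(1, round(roi_scale * blobs$sigma))
  data.frame(
    colony_id = blobs$colony_id,
    row = blobs$row, col = blobs$col, sigma = blobs$sigma,
    half_width = hw,
    row0 = pmax(0, blobs$row - hw),
    row1 = pmin(H, blobs$row + hw + 1),
    col0 = pmax(0, blobs$col - hw),
    col1 = pmin(W, blobs$col + hw + 1))
}

# 1-based matrix crop of one frame's channel sum inside an ROI row.
crop_channel_sum <- function(stack, roi, t) {
  rows <- (roi$row0 + 1):roi$row1
  cols <- (roi$col0 + 1):roi$col1
  stack$frames[t, rows, cols, 1] + stack$frames[t, rows, cols, 2] +
    stack$frames[t, rows, cols, 3]
}
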