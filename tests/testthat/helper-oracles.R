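# Brute-force oracles, deliberately independent of the package's
# vectorized implementations.

# direct (non-separable) 2-D convolution, zero padding
conv2d_loop <- function(image, kernel2d) {
  H <- nrow(image); W <- ncol(image)
  r <- (nrow(kernel2d) - 1) / 2
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) {
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + image[ii, jj] * kernel2d[a + r + 1, b + r + 1]
    }
    out[i, j] <- acc
  }
  out
}

# per-pixel loop over the fitted-radius mask: channel-summed intensity.
# Masked per-pixel values are collected in column-major order and summed
# with sum(), matching R's summation semantics so agreement can be exact.
intensity_loop_oracle <- function(stack, roi, fit, center) {
  tt <- stack$times
  out <- data.frame(total_I = numeric(length(tt)),
                    n_pixels = integer(length(tt)))
  for (t in seq_along(tt)) {
    r <- predict(fit, tt[t], "radius")
    vals <- numeric(0); n <- 0L
    for (j in roi$col0:(roi$col1 - 1)) for (i in roi$row0:(roi$row1 - 1)) {
      if ((i - center[1])^2 + (j - center[2])^2 <= r^2) {
        n <- n + 1L
        vals <- c(vals, stack$frames[t, i + 1, j + 1, 1] +
                    stack$frames[t, i + 1, j + 1, 2] +
                    stack$frames[t, i + 1, j + 1, 3])
      }
    }
    out$total_I[t] <- sum(vals); out$n_pixels[t] <- n
  }
  out
}

# per-pixel loop for the endpoint per-channel totals (column-major order)
channel_totals_loop_oracle <- function(stack, roi, fit, center) {
  tlast <- length(stack$times)
  r <- predict(fit, stack$times[tlast], "radius")
  vals <- list(numeric(0), numeric(0), numeric(0))
  for (j in roi$col0:(roi$col1 - 1)) for (i in roi$row0:(roi$row1 - 1)) {
    if ((i - center[1])^2 + (j - center[2])^2 <= r^2)
      for (ch in 1:3) vals[[ch]] <- c(vals[[ch]],
                                      stack$frames[tlast, i + 1, j + 1, ch])
  }
  vapply(vals, sum, numeric(1))
}
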