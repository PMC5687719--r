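#' Specify a simulated colony
#'
#' The generative twin of the analysis model: area follows the logistic
#' model, per-area fluorescence `F` obeys `dF/dt = KF - mu(t) F` (constant
#' production diluted by growth), and the protein distributes its emission
#' over the camera channels by a fixed vector `(e_R, e_G, e_B)` normalized
#' to sum 1 — so the channel-summed pixel value inside the colony equals
#' `F` directly.
#'
#' @param center_rc `(row, col)` center, 0-based pixels.
#' @param Amax plateau area, px^2.
#' @param mu_max maximal specific growth rate, 1/h.
#' @param t0 half-maximum time, hours.
#' @param KF true expression rate, intensity px^-1 h^-1.
#' @param F0 initial per-area fluorescence at the first frame.
#' @param emission non-negative `(e_R, e_G, e_B)`, summing to 1.
#' @param label strain name.
#' @return A `colony_spec` list.
#' @export
colony_spec <- function(center_rc, Amax, mu_max, t0, KF, F0 = 0,
                        emission = c(0, 1, 0), label = "strain") {
  stopifnot(length(center_rc) == 2, Amax > 0, mu_max > 0, KF >= 0, F0 >= 0,
            length(emission) == 3, all(emission >= 0))
  if (abs(sum(emission) - 1) > 1e-9)
    stop("`emission` must sum to 1 (got ", sum(emission), ")")
  structure(list(center_rc = as.numeric(center_rc), Amax = Amax,
                 mu_max = mu_max, t0 = t0, KF = KF, F0 = F0,
                 emission = as.numeric(emission),
                 label = as.character(label)),
            class = "colony_spec")
}

#' Specify a simulated plate
#'
#' @param image_shape `(H, W)` pixels.
#' @param n_frames number of frames.
#' @param frame_interval_h hours between frames.
#' @param background per-channel background level, length 3 (or scalar,
#'   recycled).
#' @param noise_sigma additive Gaussian noise standard deviation, digital
#'   levels.
#' @param bit_depth 8 or 16.
#' @param seed mandatory RNG seed; identical specs render bit-identical
#'   stacks.
#' @param colonies list of [colony_spec()]s, all within bounds.
#' @param allow_overlap if `FALSE` (default), colonies whose final discs
#'   overlap are an error; if `TRUE`, overlapping intensities sum.
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(image_shape, n_frames, frame_interval_h,
                       background = c(0, 0, 0), noise_sigma = 0,
                       bit_depth = 8, seed, colonies,
                       allow_overlap = FALSE) {
  stopifnot(length(image_shape) == 2, n_frames >= 1, frame_interval_h > 0,
            noise_sigma >= 0, bit_depth %in% c(8, 16))
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  if (length(background) == 1) background <- rep(background, 3)
  for (i in seq_along(colonies)) {
    co <- colonies[[i]]
    if (!inherits(co, "colony_spec")) stop("colony ", i, " is not a colony_spec")
    if (co$center_rc[1] < 0 || co$center_rc[1] >= image_shape[1] ||
        co$center_rc[2] < 0 || co$center_rc[2] >= image_shape[2])
      stop("colony ", i, " center out of bounds: (",
           paste(co$center_rc, collapse = ", "), ")")
  }
  structure(list(image_shape = as.integer(image_shape),
                 n_frames = as.integer(n_frames),
                 frame_interval_h = frame_interval_h,
                 background = as.numeric(background),
                 noise_sigma = noise_sigma,
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed), colonies = colonies,
                 allow_overlap = isTRUE(allow_overlap)),
            class = "plate_spec")
}

#' Integrate the fluorescence dynamics of a colony
#'
#' Solves `dF/dt = KF - mu(t) F` with `mu(t)` the colony's closed-form
#' specific growth rate, from `F(times[1]) = F0`, by classical fixed-step
#' fourth-order Runge-Kutta on a grid no coarser than 0.01 h.
#'
#' @param spec a [colony_spec()].
#' @param times increasing evaluation times, hours.
#' @return `F(t)` at each requested time.
#' @export
solve_fluorescence <- function(spec, times) {
  stopifnot(inherits(spec, "colony_spec"))
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("`times` must be increasing")
  if (length(times) == 1) return(spec$F0)
  fine <- seq(times[1], times[length(times)], by = 0.01)
  grid <- sort(unique(c(fine, times)))
  rhs <- function(t, y, parms) {
    mu <- logistic_growth_rate(t, spec$mu_max, spec$t0)
    list(spec$KF - mu * y)
  }
  sol <- deSolve::rk4(y = c(F = spec$F0), times = grid, func = rhs,
                      parms = NULL)
  sol[match(times, grid), "F"]
}

# fractional pixel coverage of a disc: 1 well inside, 0 well outside,
# linear ramp of one-pixel width across the edge (area-coverage
# approximation)
disc_coverage <- function(d, r) pmin(1, pmax(0, r - d + 0.5))

#' Render a simulated plate timelapse
#'
#' Draws every colony at each frame as a disc of radius
#' `r(t) = sqrt(A(t)/pi)` with one-pixel edge antialiasing, pixel values
#' `F(t) * e_ch` per channel, adds the background and seeded Gaussian
#' camera noise, and clips to the digital range. Set `quantize = TRUE` to
#' round to integer digital levels as the image files would store them.
#'
#' @param spec a [plate_spec()].
#' @param quantize round pixel values to integer levels (default `FALSE`,
#'   keeping the noise-free intensities exact for oracle tests).
#' @return list with `stack` (a [timelapse]) and `truth` (data.frame of the
#'   per-colony ground truth: `colony_id`, `label`, `row`, `col`, `Amax`,
#'   `mu_max`, `t0`, `KF`, `F0`, `eR`, `eG`, `eB`).
#' @export
render_plate <- function(spec, quantize = FALSE) {
  stopifnot(inherits(spec, "plate_spec"))
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  times <- (seq_len(spec$n_frames) - 1) * spec$frame_interval_h
  t_end <- times[length(times)]

  if (!spec$allow_overlap && length(spec$colonies) > 1) {
    ctr <- t(vapply(spec$colonies, `[[`, numeric(2), "center_rc"))
    r_end <- vapply(spec$colonies, function(co)
      sqrt(logistic_area(t_end, co$Amax, co$mu_max, co$t0) / pi), numeric(1))
    for (i in seq_len(length(spec$colonies) - 1))
      for (j in (i + 1):length(spec$colonies)) {
        d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
        if (d < r_end[i] + r_end[j])
          stop("colonies ", i - 1, " and ", j - 1,
               " overlap at the final frame; set allow_overlap")
      }
  }

  # precompute per-colony F(t) and r(t)
  Fmat <- vapply(spec$colonies, solve_fluorescence, numeric(length(times)),
                 times = times)
  Fmat <- matrix(Fmat, nrow = length(times))
  rmat <- vapply(spec$colonies, function(co)
    sqrt(logistic_area(times, co$Amax, co$mu_max, co$t0) / pi),
    numeric(length(times)))
  rmat <- matrix(rmat, nrow = length(times))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  vmax <- 2^spec$bit_depth - 1
  frames <- array(0, dim = c(length(times), H, W, 3L))
  for (t in seq_along(times)) {
    img <- array(rep(spec$background, each = H * W), dim = c(H, W, 3))
    for (k in seq_along(spec$colonies)) {
      co <- spec$colonies[[k]]
      r <- rmat[t, k]
      if (r <= 0) next
      r0 <- max(0, floor(co$center_rc[1] - r - 1))
      r1 <- min(H - 1, ceiling(co$center_rc[1] + r + 1))
      c0 <- max(0, floor(co$center_rc[2] - r - 1))
      c1 <- min(W - 1, ceiling(co$center_rc[2] + r + 1))
      rows <- r0:r1; cols <- c0:c1
      d <- sqrt(outer((rows - co$center_rc[1])^2,
                      (cols - co$center_rc[2])^2, `+`))
      cov <- disc_coverage(d, r)
      for (ch in 1:3)
        img[rows + 1, cols + 1, ch] <- img[rows + 1, cols + 1, ch] +
          Fmat[t, k] * co$emission[ch] * cov
    }
    if (spec$noise_sigma > 0)
      img <- img + stats::rnorm(length(img), sd = spec$noise_sigma)
    img[img < 0] <- 0
    img[img > vmax] <- vmax
    if (quantize) img <- round(img)
    frames[t, , , ] <- img
  }

  truth <- data.frame(
    colony_id = seq_along(spec$colonies) - 1L,
    label = vapply(spec$colonies, `[[`, character(1), "label"),
    row = vapply(spec$colonies, function(co) co$center_rc[1], numeric(1)),
    col = vapply(spec$colonies, function(co) co$center_rc[2], numeric(1)),
    Amax = vapply(spec$colonies, `[[`, numeric(1), "Amax"),
    mu_max = vapply(spec$colonies, `[[`, numeric(1), "mu_max"),
    t0 = vapply(spec$colonies, `[[`, numeric(1), "t0"),
    KF = vapply(spec$colonies, `[[`, numeric(1), "KF"),
    F0 = vapply(spec$colonies, `[[`, numeric(1), "F0"),
    eR = vapply(spec$colonies, function(co) co$emission[1], numeric(1)),
    eG = vapply(spec$colonies, function(co) co$emission[2], numeric(1)),
    eB = vapply(spec$colonies, function(co) co$emission[3], numeric(1)),
    stringsAsFactors = FALSE)

  list(stack = timelapse(frames, times, bit_depth = spec$bit_depth),
       truth = truth)
}

#' Write a rendered plate as image frames plus ground truth
#'
#' Frames are quantized to integer digital levels and written as
#' `img_0000.png`, ... (8-bit PNG) or `img_0000.tif`, ... (16-bit TIFF),
#' alongside `ground_truth.csv`; the sequence is readable by
#' [load_timelapse()].
#'
#' @param rendered the list returned by [render_plate()].
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_plate <- function(rendered, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  stack <- rendered$stack
  vmax <- 2^stack$bit_depth - 1
  ext <- if (stack$bit_depth == 8) "png" else "tif"
  for (t in seq_len(n_frames(stack))) {
    img <- round(stack$frames[t, , , ]) / vmax
    path <- file.path(directory, sprintf("img_%04d.%s", t - 1, ext))
    if (stack$bit_depth == 8) png::writePNG(img, path) else
      tiff::writeTIFF(img, path, bits.per.sample = 16L)
  }
  utils::write.csv(rendered$truth, file.path(directory, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(directory)
}

#' Serialize / load a plate specification as JSON
#'
#' @param spec a [plate_spec()].
#' @param path JSON file path.
#' @export
write_plate_spec <- function(spec, path) {
  stopifnot(inherits(spec, "plate_spec"))
  x <- unclass(spec)
  x$colonies <- lapply(spec$colonies, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plate_spec
#' @export
read_plate_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("image_shape", "n_frames", "frame_interval_h", "seed", "colonies")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("plate spec missing field(s): ",
                         paste(miss, collapse = ", "))
  cols <- x$colonies
  if (is.data.frame(cols)) cols <- split(cols, seq_len(nrow(cols)))
  colonies <- lapply(cols, function(co) {
    co <- as.list(co)
    colony_spec(center_rc = unlist(co$center_rc), Amax = co$Amax,
                mu_max = co$mu_max, t0 = co$t0, KF = co$KF,
                F0 = co$F0 %||% 0, emission = unlist(co$emission),
                label = co$label %||% "strain")
  })
  plate_spec(image_shape = unlist(x$image_shape), n_frames = x$n_frames,
             frame_interval_h = x$frame_interval_h,
             background = unlist(x$background %||% c(0, 0, 0)),
             noise_sigma = x$noise_sigma %||% 0,
             bit_depth = x$bit_depth %||% 8, seed = x$seed,
             colonies = colonies,
             allow_overlap = isTRUE(x$allow_overlap))
}
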