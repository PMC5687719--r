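#' Timelapse image stacks
#'
#' A `timelapse` holds a time-ordered stack of RGB plate images as a numeric
#' array `T x H x W x 3` (channel order red, green, blue) together with the
#' acquisition times in hours. Pixel values are kept in digital levels
#' (`0 .. 2^bit_depth - 1`) as doubles. Positions are `(row, col)`, 0-based,
#' with pixel centers at integer coordinates.
#'
#' @param frames numeric array `T x H x W x 3` of non-negative intensities.
#' @param times numeric vector of length `T`, strictly increasing, in hours.
#' @param bit_depth 8 or 16; the digital range of the source images.
#' @param background length-3 numeric, per-channel background already
#'   subtracted (0 if uncorrected).
#' @return An object of class `timelapse`.
#' @export
timelapse <- function(frames, times, bit_depth = 8, background = c(0, 0, 0)) {
  if (!is.array(frames) || length(dim(frames)) != 4L || dim(frames)[4] != 3L)
    stop("`frames` must be a T x H x W x 3 array")
  times <- as.numeric(times)
  if (length(times) != dim(frames)[1])
    stop("length(times) must equal the number of frames")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (!bit_depth %in% c(8, 16)) stop("`bit_depth` must be 8 or 16")
  if (any(frames < 0)) stop("frame intensities must be non-negative")
  structure(
    list(frames = frames, times = times, bit_depth = as.integer(bit_depth),
         background = as.numeric(background)),
    class = "timelapse")
}

#' @export
print.timelapse <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "timelapse: %d frames, %d x %d px, %d-bit, t = %.3g .. %.3g h\n",
    d[1], d[2], d[3], x$bit_depth, min(x$times), max(x$times)))
  cat(sprintf("background subtracted: (%s)\n",
              paste(signif(x$background, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.timelapse <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[1]

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(img, "bits.per.sample")
    depth <- if (!is.null(bps)) bps else 8L
  } else {
    stop("unsupported frame format: ", ext, " (expected png or tiff)")
  }
  if (length(dim(img)) != 3L)
    stop("grayscale frames are not supported; RGB input required: ", path)
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3] != 3L)
    stop("frame is not RGB (", dim(img)[3], " channels): ", path)
  # PNG/TIFF store integers; readers rescale to [0,1]. Restore digital levels.
  list(values = round(img * (2^depth - 1)), bit_depth = as.integer(depth))
}

#' Load a timelapse from a directory of image frames
#'
#' Frames (PNG or TIFF, 8- or 16-bit RGB) are collected with a filename glob,
#' sorted lexicographically into time order, and stacked. Times come either
#' from a fixed frame interval or from a two-column CSV (`frame_name`,
#' `time_h`). Values are promoted to doubles in digital levels; frames
#' containing saturated 8- or 16-bit pixels trigger a warning, not an error.
#'
#' @param directory path containing the frames.
#' @param pattern filename glob, e.g. `"img_*.png"`.
#' @param frame_interval_h positive frame spacing in hours. Exactly one of
#'   `frame_interval_h` and `timestamps_file` must be given.
#' @param timestamps_file path to a CSV with columns `frame_name`, `time_h`.
#' @return A [timelapse].
#' @export
load_timelapse <- function(directory, pattern = "*.png",
                           frame_interval_h = NULL, timestamps_file = NULL) {
  if (is.null(frame_interval_h) == is.null(timestamps_file))
    stop("give exactly one of `frame_interval_h` or `timestamps_file`")
  if (!dir.exists(directory)) stop("input directory not found: ", directory)
  files <- sort(list.files(directory, pattern = utils::glob2rx(pattern),
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no frames found in ", directory, " matching ", pattern)

  first <- read_frame_file(files[1])
  hw <- dim(first$values)[1:2]
  frames <- array(0, dim = c(length(files), hw[1], hw[2], 3L))
  frames[1, , , ] <- first$values
  if (length(files) > 1) for (i in 2:length(files)) {
    f <- read_frame_file(files[i])
    if (!identical(dim(f$values)[1:2], hw))
      stop(sprintf("frame shape mismatch: %s is %dx%d, expected %dx%d",
                   basename(files[i]), dim(f$values)[1], dim(f$values)[2],
                   hw[1], hw[2]))
    if (f$bit_depth != first$bit_depth)
      stop("mixed bit depths in frame stack")
    frames[i, , , ] <- f$values
  }

  if (!is.null(frame_interval_h)) {
    if (frame_interval_h <= 0) stop("`frame_interval_h` must be positive")
    times <- (seq_along(files) - 1) * frame_interval_h
  } else {
    ts <- utils::read.csv(timestamps_file, stringsAsFactors = FALSE)
    if (!all(c("frame_name", "time_h") %in% names(ts)))
      stop("timestamps file needs columns `frame_name`, `time_h`")
    idx <- match(basename(files), ts$frame_name)
    if (anyNA(idx)) stop("timestamps missing for some frames")
    times <- as.numeric(ts$time_h[idx])
    if (any(diff(times) <= 0)) stop("timestamps are not strictly increasing")
  }

  sat <- 2^first$bit_depth - 1
  sat_frames <- which(apply(frames, 1, function(f) any(f >= sat)))
  if (length(sat_frames))
    warning("saturated pixels in frame(s): ",
            paste(sat_frames, collapse = ", "))

  timelapse(frames, times, bit_depth = first$bit_depth)
}

#' Estimate and subtract the plate background
#'
#' `first_frame_median` takes the per-channel median of frame 1, robust when
#' colonies are absent or tiny at the start of the timelapse.
#' `per_pixel_temporal_min` subtracts each pixel's per-channel minimum over
#' time, which also removes static spatial structure. A precomputed estimate
#' can be supplied via `background` (a length-3 vector), in which case
#' `method` is ignored.
#'
#' @param stack a [timelapse].
#' @param method background estimator.
#' @param clip if `TRUE` (default), negative values after subtraction are set
#'   to 0.
#' @param background optional length-3 per-channel background to subtract
#'   directly.
#' @return A background-corrected [timelapse]; the per-channel estimate is
#'   accumulated in `$background`.
#' @export
subtract_background <- function(stack,
                                method = c("first_frame_median",
                                           "per_pixel_temporal_min"),
                                clip = TRUE, background = NULL) {
  stopifnot(inherits(stack, "timelapse"))
  frames <- stack$frames
  if (!is.null(background)) {
    stopifnot(length(background) == 3)
    est <- as.numeric(background)
    for (ch in 1:3) frames[, , , ch] <- frames[, , , ch] - est[ch]
  } else {
    method <- match.arg(method)
    if (method == "first_frame_median") {
      est <- vapply(1:3, function(ch) stats::median(stack$frames[1, , , ch]),
                    numeric(1))
      for (ch in 1:3) frames[, , , ch] <- frames[, , , ch] - est[ch]
    } else {
      if (n_frames(stack) < 2)
        warning("per_pixel_temporal_min with a single frame removes all signal")
      bg_map <- apply(stack$frames, c(2, 3, 4), min)
      est <- vapply(1:3, function(ch) stats::median(bg_map[, , ch]),
                    numeric(1))
      for (t in seq_len(n_frames(stack))) frames[t, , , ] <-
          frames[t, , , ] - bg_map
    }
  }
  if (clip) frames[frames < 0] <- 0
  out <- stack
  out$frames <- frames
  out$background <- stack$background + est
  out
}
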