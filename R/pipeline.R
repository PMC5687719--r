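#' Default analysis configuration
#'
#' Returns the full set of analysis parameters with their defaults; any
#' subset can be overridden via `...` or a JSON config file. Unknown keys
#' are rejected.
#'
#' @param ... named overrides of the defaults.
#' @param file optional JSON file of overrides (flags in `...` win).
#' @return A named list of parameters.
#' @export
analysis_config <- function(..., file = NULL) {
  defaults <- list(
    input_dir = NULL, pattern = "*.png",
    frame_interval_h = NULL, timestamps_file = NULL,
    background_method = "first_frame_median",
    sigma_smooth = 2,
    min_sigma = 3, max_sigma = 30, n_scales = 10, threshold = 0.05,
    roi_scale = 3,
    smoothing_factor = NULL,
    reference = "endpoint",
    signatures_file = NULL,
    out_dir = NULL)
  cfg <- defaults
  apply_over <- function(cfg, over, origin) {
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stop("unknown config key(s) from ", origin, ": ",
           paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(file)) cfg <- apply_over(cfg, jsonlite::read_json(
    file, simplifyVector = TRUE), file)
  over <- list(...)
  if (length(over)) cfg <- apply_over(cfg, over, "arguments")
  stopifnot(cfg$background_method %in% c("first_frame_median",
                                         "per_pixel_temporal_min"),
            cfg$reference %in% c("endpoint", "time_sum"),
            cfg$roi_scale > 0, cfg$threshold >= 0,
            cfg$min_sigma > 0, cfg$max_sigma > cfg$min_sigma)
  cfg
}

#' Full in-memory analysis of a loaded timelapse
#'
#' Runs background subtraction, temporal sum projection, smoothing, blob
#' detection, ROI definition, and the per-colony growth, intensity, and
#' expression-rate estimation. Colonies whose growth fit fails are kept in
#' `colonies` with `NA` parameters and skipped downstream (with a warning).
#'
#' @param stack a [timelapse] (raw; background is subtracted here).
#' @param config list from [analysis_config()].
#' @return list with `stack` (corrected), `blobs`, `rois`, `colonies`
#'   (per-colony parameter table), `timeseries` (long per-frame table),
#'   `totals` (channel totals), `fits` (list of `growth_fit`s).
#' @export
analyze_plate <- function(stack, config = analysis_config()) {
  stack <- subtract_background(stack, method = config$background_method)
  proj <- temporal_sum_projection(stack)
  proj_s <- smooth_projection(proj, config$sigma_smooth)
  blobs <- detect_colonies(proj_s, min_sigma = config$min_sigma,
                           max_sigma = config$max_sigma,
                           n_scales = config$n_scales,
                           threshold = config$threshold)
  rois <- make_rois(blobs, roi_scale = config$roi_scale,
                    image_shape = dim(stack$frames)[2:3])

  colonies <- cbind(rois[, c("colony_id", "row", "col", "sigma",
                             "half_width")],
                    Amax = NA_real_, mu_max = NA_real_, t0 = NA_real_,
                    residual_rms = NA_real_, n_points_used = NA_integer_)
  ts_list <- list()
  totals_list <- list()
  fits <- list()
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    trace <- radius_series(stack, roi)
    res <- tryCatch({
      fit <- fit_growth_model(trace)
      itrace <- intensity_series(stack, roi, fit)
      sm <- smooth_trace(itrace, smoothing_factor = config$smoothing_factor)
      kf <- expression_rate(sm, fit, stack$times)
      tot <- channel_totals(stack, roi, fit, reference = config$reference)
      list(fit = fit, itrace = itrace, kf = kf, tot = tot)
    }, error = function(e) {
      warning("colony ", roi$colony_id, " skipped: ", conditionMessage(e))
      NULL
    })
    ts <- data.frame(colony_id = roi$colony_id, time_h = stack$times,
                     radius_px = trace$radius_px,
                     area_px2 = trace$area_px2,
                     area_fit_px2 = NA_real_, mu_h = NA_real_,
                     mean_F = NA_real_, KF = NA_real_)
    if (!is.null(res)) {
      fit <- res$fit
      colonies[i, c("Amax", "mu_max", "t0", "residual_rms")] <-
        c(fit$Amax, fit$mu_max, fit$t0, fit$residual_rms)
      colonies[i, "n_points_used"] <- fit$n_points_used
      ts$area_fit_px2 <- predict(fit, stack$times, what = "area")
      ts$mu_h <- growth_rate_curve(fit, stack$times)
      ts$mean_F <- res$itrace$mean_F
      ts$KF <- res$kf$KF
      fits[[as.character(roi$colony_id)]] <- fit
      totals_list[[length(totals_list) + 1L]] <- res$tot
    }
    ts_list[[i]] <- ts
  }
  list(stack = stack, blobs = blobs, rois = rois, colonies = colonies,
       timeseries = do.call(rbind, ts_list),
       totals = if (length(totals_list)) do.call(rbind, totals_list) else
         NULL,
       fits = fits)
}

#' Run the full analysis from disk to disk
#'
#' Loads the frame stack named by the config, runs [analyze_plate()], and
#' writes `colonies.csv`, `timeseries.csv`, and (when a signatures file is
#' configured) `classifications.csv` into the output directory, together
#' with `analysis_log.txt` recording every parameter. The analysis path is
#' fully deterministic: identical configs give byte-identical outputs.
#'
#' @param config list from [analysis_config()]; `input_dir`, `out_dir`, and
#'   one of `frame_interval_h` / `timestamps_file` are required.
#' @return The [analyze_plate()] result, invisibly.
#' @export
run_analysis <- function(config) {
  if (is.null(config$input_dir)) stop("config: `input_dir` is required")
  if (is.null(config$out_dir)) stop("config: `out_dir` is required")
  stack <- load_timelapse(config$input_dir, pattern = config$pattern,
                          frame_interval_h = config$frame_interval_h,
                          timestamps_file = config$timestamps_file)
  res <- analyze_plate(stack, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$colonies, file.path(config$out_dir, "colonies.csv"),
                   row.names = FALSE)
  utils::write.csv(res$timeseries,
                   file.path(config$out_dir, "timeseries.csv"),
                   row.names = FALSE)
  if (!is.null(config$signatures_file)) {
    sig <- read_signatures(config$signatures_file)
    cls <- classify_colonies(res$totals, sig)
    utils::write.csv(cls, file.path(config$out_dir, "classifications.csv"),
                     row.names = FALSE)
  }
  log <- c(sprintf("fluolapse analysis %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           vapply(names(config), function(k)
             sprintf("%s = %s", k,
                     paste(format(config[[k]] %||% "NULL"), collapse = ",")),
             character(1)),
           sprintf("n_colonies_detected = %d", nrow(res$blobs)))
  writeLines(log, file.path(config$out_dir, "analysis_log.txt"))
  invisible(res)
}

#' Render a plate specification from JSON to image frames
#'
#' @param spec_file path to a plate-spec JSON ([write_plate_spec()]).
#' @param out output directory for frames + ground truth.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(spec_file, out) {
  spec <- read_plate_spec(spec_file)
  rendered <- render_plate(spec)
  write_plate(rendered, out)
  message("rendered ", spec$n_frames, " frames (seed ", spec$seed, ") to ",
          out)
  invisible(out)
}

#' Fit protein signatures from single-strain plates
#'
#' Runs the analysis on one plate per strain and fits each strain's
#' characteristic (R, G) line from its colonies' channel totals — the
#' workflow that calibrates signatures before classifying a mixed plate.
#'
#' @param input_dirs character vector of frame directories, one per strain.
#' @param labels strain labels, same length.
#' @param config base [analysis_config()] applied to every plate
#'   (`input_dir` is overridden per plate).
#' @return data.frame of signatures (one row per label).
#' @export
fit_signatures_from_plates <- function(input_dirs, labels,
                                       config = analysis_config()) {
  stopifnot(length(input_dirs) == length(labels))
  sigs <- lapply(seq_along(input_dirs), function(i) {
    stack <- load_timelapse(input_dirs[i], pattern = config$pattern,
                            frame_interval_h = config$frame_interval_h,
                            timestamps_file = config$timestamps_file)
    res <- analyze_plate(stack, config)
    if (is.null(res$totals)) stop("no usable colonies in ", input_dirs[i])
    fit_signature(res$totals, labels[i])
  })
  do.call(rbind, sigs)
}
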