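#' Per-channel signal totals of a colony
#'
#' Sums each channel (R, G, B) of the background-subtracted stack over the
#' colony mask. With `reference = "endpoint"` (default; the final image of
#' a timelapse) the mask is the disc of the fitted endpoint radius at the
#' last frame; `"time_sum"` accumulates the per-frame fitted-radius mask
#' over all frames.
#'
#' @param stack background-subtracted [timelapse].
#' @param roi one ROI row from [make_rois()].
#' @param fit the colony's `growth_fit`.
#' @param blob_center optional `(row, col)` mask center; defaults to the
#'   blob center stored in the ROI.
#' @param reference `"endpoint"` or `"time_sum"`.
#' @return A one-row data.frame: `colony_id`, `R_total`, `G_total`,
#'   `B_total`.
#' @export
channel_totals <- function(stack, roi, fit, blob_center = NULL,
                           reference = c("endpoint", "time_sum")) {
  stopifnot(inherits(stack, "timelapse"), inherits(fit, "growth_fit"))
  reference <- match.arg(reference)
  if (is.null(blob_center)) blob_center <- c(roi$row, roi$col)
  rows <- (roi$row0 + 1):roi$row1
  cols <- (roi$col0 + 1):roi$col1
  frames_used <- if (reference == "endpoint") n_frames(stack) else
    seq_len(n_frames(stack))
  tot <- c(0, 0, 0)
  n_any <- 0L
  for (t in frames_used) {
    r_t <- predict(fit, stack$times[t], what = "radius")
    mask <- roi_disc_mask(roi, blob_center[1], blob_center[2], r_t)
    n_any <- n_any + sum(mask)
    if (!any(mask)) next
    for (ch in 1:3) {
      plane <- stack$frames[t, rows, cols, ch]
      tot[ch] <- tot[ch] + sum(plane[mask])
    }
  }
  if (n_any == 0L) stop("empty colony mask")
  data.frame(colony_id = roi$colony_id, R_total = tot[1], G_total = tot[2],
             B_total = tot[3])
}

#' Fit a protein's characteristic line in the (R, G) plane
#'
#' Each fluorescent protein leaves a characteristic, fixed ratio between
#' the red and green camera channels, so the `(R_total, G_total)` points of
#' colonies expressing one protein fall on a line through the origin (zero
#' protein implies zero signal after background subtraction). The slope is
#' the through-origin least-squares estimate `sum(R G) / sum(R^2)`; the
#' signature's angle is `atan(slope)`.
#'
#' @param totals data.frame with columns `R_total`, `G_total` (one row per
#'   colony of a single-strain plate).
#' @param label strain / protein name.
#' @return A one-row `protein_signature` data.frame: `label`, `slope`,
#'   `angle`, `n_colonies`.
#' @export
fit_signature <- function(totals, label) {
  use <- totals$R_total + totals$G_total > 0
  if (sum(use) < 2)
    stop("insufficient colonies: need >= 2 with nonzero (R + G) signal")
  R <- totals$R_total[use]
  G <- totals$G_total[use]
  if (sum(R^2) == 0)
    stop("all red totals are zero; slope undefined")
  slope <- sum(R * G) / sum(R^2)
  structure(
    data.frame(label = as.character(label), slope = slope,
               angle = atan(slope), n_colonies = sum(use),
               stringsAsFactors = FALSE),
    class = c("protein_signature", "data.frame"))
}

#' Classify colonies by the closest characteristic line
#'
#' A colony's channel direction is `atan2(G_total, R_total)`; it is
#' assigned to the signature with the smallest absolute angular distance in
#' the (R, G) plane. Angular distance makes the rule invariant to colony
#' brightness — the channel ratio, not the magnitude, identifies the
#' protein. Exact ties go to the lexicographically first label and are
#' flagged by `runner_up_margin = 0`. Colonies with no signal in either
#' channel are unclassifiable (`NA` label).
#'
#' @param totals data.frame of colony channel totals ([channel_totals()]
#'   rows).
#' @param signatures data.frame of signatures ([fit_signature()] rows, or
#'   several rbind-ed); labels must be distinct.
#' @return data.frame: `colony_id`, `label`, `angular_distance_rad`,
#'   `runner_up_margin_rad`.
#' @export
classify_colonies <- function(totals, signatures) {
  if (nrow(signatures) < 1) stop("need at least one signature")
  if (anyDuplicated(signatures$label)) stop("signature labels must be distinct")
  sig <- signatures[order(signatures$label), , drop = FALSE]
  out <- data.frame(colony_id = totals$colony_id,
                    label = NA_character_,
                    angular_distance_rad = NA_real_,
                    runner_up_margin_rad = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(totals))) {
    R <- totals$R_total[i]; G <- totals$G_total[i]
    if (R == 0 && G == 0) next  # unclassifiable, reported with NA label
    a <- atan2(G, R)
    d <- abs(a - sig$angle)
    j <- which.min(d)          # first minimum = lexicographically first label
    out$label[i] <- sig$label[j]
    out$angular_distance_rad[i] <- d[j]
    out$runner_up_margin_rad[i] <-
      if (nrow(sig) > 1) min(d[-j]) - d[j] else Inf
  }
  out
}

#' Read and write signature tables
#'
#' Signatures fitted on single-strain plates can be written to CSV
#' (`label,slope,angle_rad,n_colonies`) and re-loaded to classify a mixed
#' plate.
#'
#' @param signatures data.frame of signatures.
#' @param path CSV path.
#' @export
write_signatures <- function(signatures, path) {
  df <- data.frame(label = signatures$label, slope = signatures$slope,
                   angle_rad = signatures$angle,
                   n_colonies = signatures$n_colonies)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "slope") %in% names(df)))
    stop("signature file needs columns `label`, `slope`")
  if (is.null(df$angle_rad)) df$angle_rad <- atan(df$slope)
  if (is.null(df$n_colonies)) df$n_colonies <- NA_integer_
  data.frame(label = df$label, slope = df$slope, angle = df$angle_rad,
             n_colonies = df$n_colonies, stringsAsFactors = FALSE)
}
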