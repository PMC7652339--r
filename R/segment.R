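#' Segmentation parameters
#'
#' Thresholds and gates for the transparent segmentation used on synthetic
#' frames: per-channel intensity thresholds (`NULL` = automatic Otsu
#' selection), the equivalent-diameter gate for effector identification
#' (5-15 um), a minimum circularity, and the red threshold used both for the
#' dead-area measurement and the red-exclusion of effectors.
#'
#' Equivalent diameter is `2 * sqrt(area / pi)` in microns; circularity is
#' `4 * pi * area / perimeter^2` (1 for an ideal disk; rasterized small disks
#' can exceed 1 because boundary-pixel perimeters underestimate length).
#'
#' @param green_threshold,red_threshold,phase_threshold Intensity thresholds;
#'   `NULL` selects them per frame by Otsu's method.
#' @param effector_diameter_range Equivalent-diameter bounds, um.
#' @param min_circularity Minimum circularity for effector objects.
#' @return A list of class `tk_seg_params`.
#' @export
seg_params <- function(green_threshold = NULL, red_threshold = NULL,
                       phase_threshold = NULL,
                       effector_diameter_range = c(5, 15),
                       min_circularity = 0.4) {
  if (length(effector_diameter_range) != 2 ||
      any(effector_diameter_range <= 0) ||
      effector_diameter_range[1] >= effector_diameter_range[2]) {
    abort_bad_arg("`effector_diameter_range` must be positive bounds, lower < upper.")
  }
  assert_scalar_num(min_circularity, "min_circularity", 0, 1)
  structure(list(green_threshold = green_threshold,
                 red_threshold = red_threshold,
                 phase_threshold = phase_threshold,
                 effector_diameter_range = effector_diameter_range,
                 min_circularity = min_circularity),
            class = "tk_seg_params")
}

# per-channel threshold: explicit value, else Otsu with a foreground guard.
# Otsu always splits the histogram, even when a channel holds only background
# noise (e.g. the red channel before any cell has died); in that case the two
# "classes" are both noise and nothing should pass. Foreground is declared only
# when the class separation clearly exceeds the background spread.
resolve_threshold <- function(channel, value) {
  if (!is.null(value)) return(value)
  rng <- range(channel)
  if (diff(rng) < .Machine$double.eps) return(rng[2] + 1)  # constant channel: nothing above
  thr <- EBImage::otsu(EBImage::Image(channel), range = rng)
  lo <- channel[channel < thr]
  hi <- channel[channel >= thr]
  spread <- max(sd(lo), .Machine$double.eps)
  if (length(hi) == 0 || length(lo) < 2 || (mean(hi) - mean(lo)) < 4 * spread) {
    return(rng[2] + 1)  # no real foreground: nothing above threshold
  }
  thr
}

channel_quality <- function(channel, name) {
  warn <- character(0)
  if (diff(range(channel)) < .Machine$double.eps) {
    warn <- c(warn, sprintf("%s channel is empty/constant", name))
  }
  if (mean(channel >= max(channel)) > 0.25 && max(channel) > 0) {
    warn <- c(warn, sprintf("%s channel looks saturated", name))
  }
  warn
}

#' Count live effector cells in a frame
#'
#' Thresholds the green channel, labels connected components, and retains
#' components whose equivalent diameter (in um) lies within the effector gate,
#' whose circularity passes `min_circularity`, and whose mean red intensity is
#' below the red threshold (live = green-positive, red-negative). Saturated or
#' empty channels raise a warning, not an error.
#'
#' @param frame A [tk_frame()].
#' @param params A [seg_params()].
#' @return Integer count, with the per-object table as attribute `"objects"`
#'   (columns `label, area_px, perimeter_px, equiv_diam_um, circularity,
#'   mean_red, retained`).
#' @export
count_effectors <- function(frame, params = seg_params()) {
  stopifnot(inherits(frame, "tk_frame"))
  for (w in c(channel_quality(frame$green, "green"),
              channel_quality(frame$red, "red"))) warning(w, call. = FALSE)
  thr_g <- resolve_threshold(frame$green, params$green_threshold)
  thr_r <- resolve_threshold(frame$red, params$red_threshold)
  mask <- frame$green >= thr_g
  if (!any(mask)) {
    out <- 0L
    attr(out, "objects") <- tibble::tibble(
      label = integer(), area_px = numeric(), perimeter_px = numeric(),
      equiv_diam_um = numeric(), circularity = numeric(), mean_red = numeric(),
      retained = logical())
    return(out)
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  shp <- EBImage::computeFeatures.shape(lab)
  labm <- EBImage::imageData(lab)
  n_lab <- max(labm)
  area <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  idx <- labm > 0
  mean_red <- as.numeric(tapply(frame$red[idx],
                                factor(labm[idx], levels = seq_len(n_lab)),
                                mean))
  equiv_um <- 2 * sqrt(area / pi) * frame$microns_per_pixel
  circ <- 4 * pi * area / perim^2
  retained <- equiv_um >= params$effector_diameter_range[1] &
    equiv_um <= params$effector_diameter_range[2] &
    circ >= params$min_circularity &
    mean_red < thr_r
  out <- sum(retained)
  attr(out, "objects") <- tibble::tibble(
    label = seq_along(area), area_px = as.numeric(area),
    perimeter_px = as.numeric(perim), equiv_diam_um = equiv_um,
    circularity = circ, mean_red = mean_red, retained = retained)
  out
}

#' Red (dead/dying) pixel area
#'
#' Number of pixels with red intensity at or above the red threshold; the
#' numerator of the death-fraction measurement.
#'
#' @inheritParams count_effectors
#' @return Numeric pixel count.
#' @export
red_area <- function(frame, params = seg_params()) {
  stopifnot(inherits(frame, "tk_frame"))
  thr <- resolve_threshold(frame$red, params$red_threshold)
  sum(frame$red >= thr)
}

#' Phase-contrast occupied pixel area
#'
#' Number of pixels classified as cell-occupied in the phase channel; the
#' denominator (confluency surrogate) of the death-fraction measurement.
#'
#' @inheritParams count_effectors
#' @return Numeric pixel count.
#' @export
phase_area <- function(frame, params = seg_params()) {
  stopifnot(inherits(frame, "tk_frame"))
  thr <- resolve_threshold(frame$phase, params$phase_threshold)
  sum(frame$phase >= thr)
}

#' Quantify a single frame
#'
#' @inheritParams count_effectors
#' @return One-row tibble: `well_id, time_h, e_live, red_px, phase_px`.
#' @export
quantify_frame <- function(frame, params = seg_params()) {
  tibble::tibble(
    well_id = frame$well_id,
    time_h = frame$time_h,
    e_live = as.numeric(count_effectors(frame, params)),
    red_px = as.numeric(red_area(frame, params)),
    phase_px = as.numeric(phase_area(frame, params))
  )
}

#' Quantify a time-ordered stack of frames into a well time series
#'
#' @param frames List of [tk_frame()] objects for one well, ordered by
#'   strictly increasing `time_h`; mixed wells or non-monotone timestamps are
#'   rejected.
#' @param params A [seg_params()].
#' @return Tibble with one row per frame: `well_id, time_h, e_live, red_px,
#'   phase_px`.
#' @export
quantify_stack <- function(frames, params = seg_params()) {
  if (length(frames) == 0) abort_bad_arg("no frames supplied.")
  wells <- unique(vapply(frames, function(f) f$well_id, ""))
  if (length(wells) != 1) {
    abort_bad_arg(paste0("frames span multiple wells: ", paste(wells, collapse = ", ")))
  }
  times <- vapply(frames, function(f) f$time_h, numeric(1))
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    abort_bad_arg("frame times must be finite and strictly increasing.")
  }
  dplyr::bind_rows(lapply(frames, quantify_frame, params = params))
}
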