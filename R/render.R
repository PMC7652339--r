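#' Construct a three-channel frame
#'
#' A frame holds co-registered phase, green and red intensity rasters for one
#' well at one time. Intensities are in `[0, 1]`-ish arbitrary units; the
#' pixel scale links object areas to physical size.
#'
#' @param phase,green,red Numeric matrices of identical dimensions, finite,
#'   >= 0.
#' @param microns_per_pixel Pixel scale, um/px (> 0).
#' @param time_h Acquisition time, hours.
#' @param well_id Well identifier.
#' @return A `tk_frame` list.
#' @export
tk_frame <- function(phase, green, red, microns_per_pixel, time_h = NA_real_,
                     well_id = "W1") {
  dims <- list(dim(phase), dim(green), dim(red))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    abort_bad_arg("phase, green and red channels must share dimensions.")
  }
  for (ch in list(phase, green, red)) {
    if (any(!is.finite(ch)) || any(ch < 0)) {
      abort_bad_arg("channel intensities must be finite and >= 0.")
    }
  }
  assert_scalar_num(microns_per_pixel, "microns_per_pixel")
  if (microns_per_pixel <= 0) abort_bad_arg("`microns_per_pixel` must be > 0.")
  structure(list(phase = phase, green = green, red = red,
                 microns_per_pixel = microns_per_pixel,
                 time_h = time_h, well_id = well_id),
            class = "tk_frame")
}

#' @export
print.tk_frame <- function(x, ...) {
  cat(sprintf("<tk_frame> %dx%d px (%.3g um/px), well %s, t = %s h\n",
              nrow(x$phase), ncol(x$phase), x$microns_per_pixel, x$well_id,
              format(x$time_h)))
  invisible(x)
}

#' Imaging geometry for the synthetic renderer
#'
#' @param field_px Raster size, pixels (rows, cols).
#' @param microns_per_pixel Pixel scale (default 1 um/px, i.e. 10x-class).
#' @param effector_diam_um Sampling range for effector (T cell) diameters;
#'   kept inside the 5-15 um classification gate so rendering quantization
#'   cannot push an object across the gate.
#' @param target_diam_um Live/dead target phase footprint diameter; the
#'   default matches a 200 px phase area at 1 um/px.
#' @param red_diam_um Dead-cell red footprint diameter; the default matches a
#'   100 px red area at 1 um/px.
#' @param bg_level,bg_noise_sd Background intensity and Gaussian noise sd.
#' @param fg_intensity Foreground intensity of rendered objects.
#' @return A list of class `tk_geometry`.
#' @export
render_geometry <- function(field_px = c(1000, 1000),
                            microns_per_pixel = 1,
                            effector_diam_um = c(6, 14),
                            target_diam_um = 2 * sqrt(200 / pi),
                            red_diam_um = 2 * sqrt(100 / pi),
                            bg_level = 0.05, bg_noise_sd = 0.02,
                            fg_intensity = 0.9) {
  structure(list(field_px = field_px, microns_per_pixel = microns_per_pixel,
                 effector_diam_um = effector_diam_um,
                 target_diam_um = target_diam_um, red_diam_um = red_diam_um,
                 bg_level = bg_level, bg_noise_sd = bg_noise_sd,
                 fg_intensity = fg_intensity),
            class = "tk_geometry")
}

#' Render a synthetic three-channel frame with ground-truth labels
#'
#' Draws non-overlapping disks on a noisy background: live effectors as green
#' disks with diameters sampled uniformly within `effector_diam_um`; live
#' targets as phase-occupied disks; dead targets as phase-occupied disks with
#' a concentric red core; dead effectors (optional) as green disks with a red
#' core. Returns the frame plus a label map and an object table giving each
#' object's class, center, radius and exact rasterized pixel area, so
#' segmentation can be validated against known truth.
#'
#' @param n_effectors Live effectors to draw.
#' @param n_targets_live,n_targets_dead Live / dead targets.
#' @param n_dead_effectors Red-positive effectors (counted green but excluded
#'   from the live gate).
#' @param geometry A [render_geometry()].
#' @param seed Integer seed; fixed seed gives an identical raster.
#' @param time_h,well_id Metadata carried onto the frame.
#' @param max_place_tries Rejection-sampling budget per object before the
#'   packing is declared impossible.
#' @return List with `frame` (a [tk_frame()]), `labels` (integer matrix) and
#'   `objects` (tibble: `label, class, cx, cy, radius_px, area_px`).
#' @examples
#' r <- render_frame(5, 3, 2, geometry = render_geometry(field_px = c(200, 200)),
#'                   seed = 1)
#' r$objects
#' @export
render_frame <- function(n_effectors, n_targets_live = 0, n_targets_dead = 0,
                         n_dead_effectors = 0,
                         geometry = render_geometry(), seed = 1,
                         time_h = NA_real_, well_id = "W1",
                         max_place_tries = 2000) {
  for (nm in c("n_effectors", "n_targets_live", "n_targets_dead", "n_dead_effectors")) {
    assert_scalar_num(get(nm), nm, lower = 0)
  }
  g <- geometry
  nr <- g$field_px[1]; nc <- g$field_px[2]
  mpp <- g$microns_per_pixel

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))

  classes <- c(rep("target_live", n_targets_live),
               rep("target_dead", n_targets_dead),
               rep("effector", n_effectors),
               rep("effector_dead", n_dead_effectors))
  n_obj <- length(classes)
  radii <- numeric(n_obj)
  for (i in seq_len(n_obj)) {
    radii[i] <- switch(classes[i],
      target_live = , target_dead = g$target_diam_um / 2 / mpp,
      effector = , effector_dead =
        runif(1, g$effector_diam_um[1], g$effector_diam_um[2]) / 2 / mpp)
  }

  # largest first makes packing easier and keeps placement deterministic
  ord <- order(-radii)
  cx <- numeric(n_obj); cy <- numeric(n_obj)
  placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
  for (i in ord) {
    r <- radii[i]
    ok <- FALSE
    for (try in seq_len(max_place_tries)) {
      x <- runif(1, r + 1, nr - r)
      y <- runif(1, r + 1, nc - r)
      if (length(placed_x) == 0 ||
          all((placed_x - x)^2 + (placed_y - y)^2 > (placed_r + r + 1)^2)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort_bad_arg(sprintf(
        "impossible packing: could not place %d non-overlapping objects in a %dx%d field.",
        n_obj, nr, nc))
    }
    cx[i] <- x; cy[i] <- y
    placed_x <- c(placed_x, x); placed_y <- c(placed_y, y); placed_r <- c(placed_r, r)
  }

  phase <- matrix(pmax(0, g$bg_level + stats::rnorm(nr * nc, 0, g$bg_noise_sd)), nr, nc)
  green <- matrix(pmax(0, g$bg_level + stats::rnorm(nr * nc, 0, g$bg_noise_sd)), nr, nc)
  red <- matrix(pmax(0, g$bg_level + stats::rnorm(nr * nc, 0, g$bg_noise_sd)), nr, nc)
  labels <- matrix(0L, nr, nc)
  area_px <- integer(n_obj)

  for (i in seq_len(n_obj)) {
    r <- radii[i]
    xr <- max(1, floor(cx[i] - r)):min(nr, ceiling(cx[i] + r))
    yr <- max(1, floor(cy[i] - r)):min(nc, ceiling(cy[i] + r))
    dx <- outer((xr - cx[i])^2, (yr - cy[i])^2, `+`)
    inside <- dx <= r^2
    area_px[i] <- sum(inside)
    sub <- cbind(rep(xr, times = length(yr))[inside],
                 rep(yr, each = length(xr))[inside])
    labels[sub] <- i
    cls <- classes[i]
    if (cls %in% c("target_live", "target_dead")) phase[sub] <- g$fg_intensity
    if (cls %in% c("effector", "effector_dead")) green[sub] <- g$fg_intensity
    if (cls %in% c("effector_dead")) {
      red[sub] <- g$fg_intensity
    }
    if (cls == "target_dead") {
      rr <- g$red_diam_um / 2 / mpp
      ins_r <- dx <= rr^2
      sub_r <- cbind(rep(xr, times = length(yr))[ins_r],
                     rep(yr, each = length(xr))[ins_r])
      red[sub_r] <- g$fg_intensity
    }
  }

  red_area_true <- vapply(seq_len(n_obj), function(i) {
    if (classes[i] == "target_dead") {
      rr <- g$red_diam_um / 2 / mpp
      xr <- max(1, floor(cx[i] - rr)):min(nr, ceiling(cx[i] + rr))
      yr <- max(1, floor(cy[i] - rr)):min(nc, ceiling(cy[i] + rr))
      as.numeric(sum(outer((xr - cx[i])^2, (yr - cy[i])^2, `+`) <= rr^2))
    } else if (classes[i] == "effector_dead") as.numeric(area_px[i]) else 0
  }, numeric(1))

  objects <- tibble::tibble(
    label = seq_len(n_obj), class = classes, cx = cx, cy = cy,
    radius_px = radii, area_px = area_px, red_area_px = red_area_true
  )
  list(
    frame = tk_frame(phase, green, red, microns_per_pixel = mpp,
                     time_h = time_h, well_id = well_id),
    labels = labels,
    objects = objects
  )
}

#' Render frames for a simulated well trajectory
#'
#' Maps the latent state of one simulated well (live targets, cumulative dead
#' targets, live effectors at each scan) to a stack of rendered frames, so the
#' segmentation pipeline can be run end-to-end against simulator ground truth.
#' Use a small `target_seed_count` so the cells fit the field without overlap.
#'
#' @param latent Latent tibble for one well (from [simulate_well()] /
#'   [simulate_plate()]).
#' @param geometry A [render_geometry()].
#' @param seed Integer seed; per-frame seeds are derived from it.
#' @param times Optional subset of times to render (default: all).
#' @return List of render results (as from [render_frame()]), one per time.
#' @export
render_well_frames <- function(latent, geometry = render_geometry(), seed = 1,
                               times = NULL) {
  stopifnot(all(c("time_h", "t_live", "t_dead_cum", "e_live_latent") %in% names(latent)))
  if (!is.null(times)) latent <- latent[latent$time_h %in% times, ]
  seeds <- derive_seeds(seed, nrow(latent))
  purrr::pmap(
    list(latent$time_h, latent$t_live, latent$t_dead_cum,
         latent$e_live_latent, seeds),
    function(t, tl, td, el, s) {
      render_frame(n_effectors = el, n_targets_live = tl, n_targets_dead = td,
                   geometry = geometry, seed = s, time_h = t,
                   well_id = latent$well_id[1])
    })
}

#' Write / read a frame as TIFF
#'
#' Channels are stored as a 3-page float TIFF (phase, green, red) with the
#' pixel scale and metadata in the file name convention
#' `<well>_t<time>h.tif`. Requires the `tiff` package.
#'
#' @param frame A [tk_frame()].
#' @param path Output file path.
#' @return `write_frame()` the path, invisibly; `read_frame()` a `tk_frame`.
#' @export
write_frame <- function(frame, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort_bad_arg("the `tiff` package is required for frame I/O.")
  }
  stopifnot(inherits(frame, "tk_frame"))
  tiff::writeTIFF(list(frame$phase, frame$green, frame$red), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_frame
#' @param microns_per_pixel,time_h,well_id Metadata to attach on read.
#' @export
read_frame <- function(path, microns_per_pixel = 1, time_h = NA_real_,
                       well_id = "W1") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort_bad_arg("the `tiff` package is required for frame I/O.")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3) abort_bad_arg("expected a 3-page TIFF (phase, green, red).")
  tk_frame(pages[[1]], pages[[2]], pages[[3]],
           microns_per_pixel = microns_per_pixel, time_h = time_h,
           well_id = well_id)
}
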