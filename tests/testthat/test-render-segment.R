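small_geo <- function(...) render_geometry(field_px = c(400, 400), ...)

test_that("render_frame draws what it promises and is deterministic", {
  # empty frame: background only, empty label map
  r0 <- render_frame(0, 0, 0, geometry = small_geo(), seed = 1)
  expect_equal(nrow(r0$objects), 0)
  expect_true(all(r0$labels == 0))
  expect_lt(max(r0$frame$green), 0.2)

  # 50 effectors requested: exactly 50 effector objects in the label map
  r50 <- render_frame(50, 0, 0, geometry = render_geometry(field_px = c(700, 700)),
                      seed = 2)
  expect_equal(sum(r50$objects$class == "effector"), 50)
  expect_equal(length(setdiff(unique(as.vector(r50$labels)), 0L)), 50)

  # fixed seed reproduces the raster bit for bit
  a <- render_frame(10, 5, 3, geometry = small_geo(), seed = 9)
  b <- render_frame(10, 5, 3, geometry = small_geo(), seed = 9)
  expect_identical(a$frame$phase, b$frame$phase)
  expect_identical(a$frame$red, b$frame$red)
  expect_identical(a$objects, b$objects)

  # impossible packing is an error, not an infinite loop
  expect_error(render_frame(500, 0, 0,
                            geometry = render_geometry(field_px = c(60, 60)),
                            seed = 1, max_place_tries = 50),
               "impossible packing")
})

test_that("effector counting applies the size, shape and red-exclusion gates", {
  p <- seg_params()
  r <- render_frame(50, 0, 0, geometry = render_geometry(field_px = c(700, 700)),
                    seed = 3)
  expect_equal(as.integer(count_effectors(r$frame, p)), 50)

  # 3 um green disks fall below the 5 um bound: nothing is counted
  tiny <- render_frame(10, 0, 0,
                       geometry = small_geo(effector_diam_um = c(3, 3.01)),
                       seed = 4)
  expect_equal(as.integer(count_effectors(tiny$frame, p)), 0)

  # 20 green disks, 5 of them red-positive: 15 live
  mix <- render_frame(15, 0, 0, n_dead_effectors = 5,
                      geometry = render_geometry(field_px = c(700, 700)),
                      seed = 5)
  expect_equal(sum(mix$objects$class == "effector"), 15)
  expect_equal(as.integer(count_effectors(mix$frame, p)), 15)
})

test_that("red and phase areas match the label map and respect thresholds", {
  p <- seg_params()
  r <- render_frame(10, 8, 6, geometry = render_geometry(field_px = c(700, 700)),
                    seed = 6)
  true_red <- sum(r$objects$red_area_px)
  expect_lt(abs(red_area(r$frame, p) - true_red) / true_red, 0.05)
  true_phase <- sum(r$objects$area_px[r$objects$class %in%
                                        c("target_live", "target_dead")])
  expect_lt(abs(phase_area(r$frame, p) - true_phase) / true_phase, 0.05)

  # no red signal -> 0; threshold above the global maximum -> 0
  clean <- render_frame(5, 5, 0, geometry = small_geo(), seed = 7)
  expect_equal(red_area(clean$frame, p), 0)
  expect_equal(red_area(r$frame, seg_params(red_threshold = 2)), 0)

  # areas are monotone non-increasing in their thresholds
  thrs <- seq(0.1, 0.95, by = 0.1)
  reds <- vapply(thrs, function(th)
    red_area(r$frame, seg_params(red_threshold = th)), numeric(1))
  phases <- vapply(thrs, function(th)
    phase_area(r$frame, seg_params(phase_threshold = th)), numeric(1))
  expect_true(all(diff(reds) <= 0))
  expect_true(all(diff(phases) <= 0))

  # fully occupied phase channel with an explicit threshold: every pixel counts
  full <- tk_frame(matrix(0.9, 50, 50), matrix(0, 50, 50), matrix(0, 50, 50),
                   microns_per_pixel = 1)
  expect_equal(phase_area(full, seg_params(phase_threshold = 0.5)), 2500)
})

test_that("quantify_stack assembles ordered frames and rejects disorder", {
  p <- seg_params()
  g <- small_geo()
  f1 <- render_frame(5, 3, 0, geometry = g, seed = 1, time_h = 2)$frame
  f2 <- render_frame(6, 3, 1, geometry = g, seed = 2, time_h = 4)$frame
  one <- quantify_stack(list(f1), p)
  expect_equal(nrow(one), 1)
  two <- quantify_stack(list(f1, f2), p)
  expect_equal(two$time_h, c(2, 4))
  expect_error(quantify_stack(list(f2, f1), p), "strictly increasing")
  f3 <- render_frame(2, 1, 0, geometry = g, seed = 3, time_h = 6,
                     well_id = "B9")$frame
  expect_error(quantify_stack(list(f1, f3), p), "multiple wells")
})

test_that("simulator -> renderer -> quantify round-trip recovers the counts", {
  cfg <- sim_config(target_seed_count = 50, count_noise = "none",
                    concentrations = c(0, 1e-6), horizon = 16, rng_seed = 31)
  w <- simulate_well(cfg, 1e-6, 1, well_seed = 12, well_id = "A1")
  frames <- render_well_frames(w$latent,
                               geometry = render_geometry(field_px = c(800, 800)),
                               seed = 8)
  ts <- quantify_stack(lapply(frames, `[[`, "frame"), seg_params())
  lat <- w$latent
  expect_true(all(abs(ts$e_live - lat$e_live_latent) <=
                    pmax(1, 0.02 * lat$e_live_latent)))
  expect_equal(ts$phase_px / cfg$phase_area_per_target,
               lat$t_live + lat$t_dead_cum, tolerance = 0.02)
})

test_that("frames validate co-registration and scale", {
  expect_error(tk_frame(matrix(0, 2, 2), matrix(0, 3, 3), matrix(0, 2, 2), 1),
               "share dimensions")
  expect_error(tk_frame(matrix(-1, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2), 1),
               "finite")
  expect_error(tk_frame(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2), 0),
               "microns_per_pixel")
})
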