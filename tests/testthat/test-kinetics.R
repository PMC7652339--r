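test_that("grid resampling preserves coinciding samples and linear signals", {
  # 2-h cadence: every 6-h grid time is sampled, values pass through exactly
  t2 <- seq(2, 26, by = 2)
  s2 <- tibble::tibble(time_h = t2, e_live = rnorm(length(t2), 500, 5)^1,
                       red_px = abs(rnorm(length(t2), 100, 5)),
                       phase_px = abs(rnorm(length(t2), 1e5, 50)))
  g2 <- resample_to_grid(s2)
  expect_equal(g2$time_h, c(2, 8, 14, 20, 26))
  native <- s2[s2$time_h %in% g2$time_h, ]
  expect_equal(g2$e_live, native$e_live)
  expect_equal(g2$red_px, native$red_px)

  # 4-h cadence with a linear signal: interpolation is exact
  t4 <- seq(2, 50, by = 4)
  s4 <- tibble::tibble(time_h = t4, e_live = 10 + 3 * t4, red_px = 2 * t4,
                       phase_px = 1e5 - 10 * t4)
  g4 <- resample_to_grid(s4)
  expect_equal(g4$e_live, 10 + 3 * g4$time_h, tolerance = 1e-12)

  # quadratic signal sampled every 4 h: midpoint error is the known residual
  sq <- tibble::tibble(time_h = t4, e_live = t4^2, red_px = 0, phase_px = 1)
  gq <- resample_to_grid(sq)
  off <- gq[gq$time_h == 8, ]  # t = 8 interpolated from samples at 6 and 10
  expect_equal(off$e_live, (6^2 + 10^2) / 2)   # = 68, not 64
  expect_equal(off$e_live - 8^2, 4)            # quadratic residual h^2

  expect_error(resample_to_grid(tibble::tibble(
    time_h = c(2, 4), e_live = 1:2, red_px = 0, phase_px = 1)), "grid step")
  expect_error(resample_to_grid(tibble::tibble(
    time_h = c(2, 14, 26), e_live = 1:3, red_px = 0, phase_px = 1)), "cadence")
})

test_that("the six kinetic transforms evaluate their printed examples", {
  t <- c(2, 8, 14, 20, 26, 32, 38, 44, 50)
  # fold proliferation: E(2) = 100, E(50) = 250 -> P(50) = 2.5
  e <- c(100, 120, 140, 160, 180, 200, 220, 235, 250)
  s <- tibble::tibble(time_h = t, e_live = e, red_px = 0, phase_px = 1e5)
  expect_equal(fold_proliferation(s)$p_fold[9], 2.5)
  expect_equal(fold_proliferation(s)$p_fold[1], 1)
  sc <- s; sc$e_live <- rep(77, 9)
  expect_true(all(fold_proliferation(sc)$p_fold == 1))

  # death fraction: red 1500 over phase 6000 -> 25%; saturation -> 100%
  sd_ <- tibble::tibble(time_h = t[1:3], e_live = 1,
                        red_px = c(0, 1500, 6000), phase_px = 6000)
  expect_equal(death_fraction(sd_)$t_dead_pct, c(0, 25, 100))

  # specific killing: 30% over 5% -> 6
  expect_equal(specific_killing(30, 5)$k_specific, 6)

  # per-T-cell killing: (40/200) / (2/400) = 40 at t = 48 with lag 6
  tt <- c(42, 48)
  ss <- killing_per_tcell(t_dead = c(10, 40), t_dead_0 = c(1, 2),
                          e_live = c(200, 999), e_live_0 = c(400, 999),
                          time_h = tt)
  expect_equal(ss$s_per_tcell, c(NA, 40))

  # proliferation rate: 100 -> 120 over 6 h = 0.8/day = 80 %/day
  pr <- proliferation_rate(c(100, 120), c(42, 48))
  expect_equal(pr$p_rate_pct_day, c(NA, 80))
  # declining counts give negative rates, untruncated
  prd <- proliferation_rate(c(100, 90, 80), c(2, 8, 14))
  expect_true(all(prd$p_rate_pct_day[-1] < 0))

  # kill rate: (6 - 3) / 100 / 6 = 0.005 per T cell per hour
  kr <- kill_rate(c(3, 6), c(100, 999), c(42, 48))
  expect_equal(kr$k_rate_per_tcell_hr, c(NA, 0.005))
  kr0 <- kill_rate(rep(2.5, 4), rep(100, 4), c(2, 8, 14, 20))
  expect_true(all(kr0$k_rate_per_tcell_hr[-1] == 0))
})

test_that("zero denominators are flagged, not silently propagated", {
  s <- tibble::tibble(time_h = c(2, 8, 14), e_live = c(0, 10, 20),
                      red_px = 0, phase_px = 1e5)
  p <- fold_proliferation(s)
  expect_true(all(is.na(p$p_fold)))
  expect_true(all(p$flag == "e0_zero"))

  sd_ <- tibble::tibble(time_h = c(2, 8), e_live = 1, red_px = c(5, 5),
                        phase_px = c(1e5, 0))
  d <- death_fraction(sd_)
  expect_true(is.na(d$t_dead_pct[2]))
  expect_equal(d$flag[2], "phase_zero")

  # control below the one-pixel floor: clamped and flagged; when the dosed
  # well is also below the floor there is no signal at all -> NA
  k <- specific_killing(t_dead = c(10, 1e-9), t_dead_0 = c(1e-9, 1e-9),
                        phase_px_0 = c(1e5, 1e5))
  expect_equal(k$k_specific[1], 10 / (100 / 1e5))
  expect_equal(k$flag[1], "control_floor")
  expect_true(is.na(k$k_specific[2]))
  expect_equal(k$flag[2], "no_death_signal")

  # zero lagged effectors clamp to one cell and flag
  kk <- kill_rate(c(1, 4), c(0, 50), c(2, 8))
  expect_equal(kk$k_rate_per_tcell_hr[2], 3 / 1 / 6)
  expect_equal(kk$flag[2], "e_floor")
})

test_that("build_profiles averages replicates after per-well P and T_dead", {
  cfg <- quick_config(rng_seed = 5, count_noise = "poisson")
  pm1 <- plate_map(et_ratios = 3, concentrations = cfg$concentrations,
                   replicates = 1)
  truth <- simulate_plate(cfg, pm1)
  p1 <- build_profiles(truth$measurements)

  # single well per condition: profiles equal the per-well calculation
  one <- truth$measurements[truth$measurements$concentration == max(cfg$concentrations), ]
  g <- resample_to_grid(one)
  expect_equal(p1$p_fold[p1$concentration == max(cfg$concentrations)],
               fold_proliferation(g)$p_fold)

  # duplicating every well leaves the averaged profiles unchanged
  dup <- dplyr::mutate(truth$measurements, well_id = paste0(well_id, "bis"))
  p2 <- build_profiles(dplyr::bind_rows(truth$measurements, dup))
  expect_equal(p2$k_specific, p1$k_specific)
  expect_equal(p2$s_per_tcell, p1$s_per_tcell)
  expect_true(all(p2$n_wells == 2))

  # missing control is rejected with the group named
  no_ctrl <- truth$measurements[truth$measurements$concentration > 0, ]
  expect_error(build_profiles(no_ctrl), "missing 0 M control")
})

test_that("computing on native 2-h data matches pre-resampled 6-h data", {
  cfg <- quick_config(rng_seed = 8, horizon = 48)
  pm <- plate_map(et_ratios = 3, concentrations = cfg$concentrations,
                  replicates = 1)
  meas <- simulate_plate(cfg, pm)$measurements
  # pre-subsample the native series to the 6-h grid, then run the pipeline
  sub <- meas[meas$time_h %in% seq(2, 48, by = 6), ]
  p_native <- build_profiles(meas)
  p_sub <- build_profiles(sub)
  shared <- intersect(p_native$time_h, p_sub$time_h)
  a <- p_native[p_native$time_h %in% shared, ]
  b <- p_sub[p_sub$time_h %in% shared, ]
  expect_equal(a$p_fold, b$p_fold, tolerance = 1e-12)
  expect_equal(a$t_dead_pct, b$t_dead_pct, tolerance = 1e-12)
  expect_equal(a$k_specific, b$k_specific, tolerance = 1e-12)
})

test_that("profile sign and range invariants hold on simulated plates", {
  cfg <- quick_config(rng_seed = 13, count_noise = "poisson")
  pm <- plate_map(et_ratios = c(3, 1 / 3), concentrations = cfg$concentrations,
                  replicates = 2)
  prof <- build_profiles(simulate_plate(cfg, pm)$measurements)
  expect_true(all(prof$t_dead_pct >= 0 & prof$t_dead_pct <= 100, na.rm = TRUE))
  expect_true(all(prof$k_specific >= 0, na.rm = TRUE))
  expect_true(all(prof$s_per_tcell >= 0, na.rm = TRUE))
})
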