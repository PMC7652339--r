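test_that("noiseless 4PL responses are recovered essentially exactly", {
  conc <- 1e-4 / 3^(19:0)
  truth <- list(bottom = 1, top = 30, ec50 = 5e-8, slope = 1)
  r <- gen_4pl(conc, truth$bottom, truth$top, truth$ec50, truth$slope)
  f <- fit_4pl(conc, r)
  expect_true(f$converged)
  expect_false(f$flat)
  expect_lt(abs(f$bottom - truth$bottom), 1e-6 * truth$bottom)
  expect_lt(abs(f$top - truth$top) / truth$top, 1e-6)
  expect_lt(abs(f$ec50 - truth$ec50) / truth$ec50, 1e-6)
  expect_lt(abs(f$hill_slope - truth$slope) / truth$slope, 1e-6)
  expect_equal(f$emax, f$top)
})

test_that("fitting is invariant to point order and response rescaling", {
  conc <- 1e-4 / 3^(19:0)
  set.seed(42)
  r <- gen_4pl(conc, 2, 20, 2e-7, 1.3) + rnorm(20, 0, 0.3)
  f <- fit_4pl(conc, r)
  shuffle <- sample(20)
  f_shuf <- fit_4pl(conc[shuffle], r[shuffle])
  expect_equal(f_shuf$ec50, f$ec50, tolerance = 1e-8)
  f_scaled <- fit_4pl(conc, 10 * r)
  expect_equal(f_scaled$ec50, f$ec50, tolerance = 1e-6)
  expect_equal(f_scaled$emax, 10 * f$emax, tolerance = 1e-6)
})

test_that("flat and degenerate responses are flagged, not reported as dose-dependent", {
  conc <- 1e-4 / 3^(9:0)
  f_const <- fit_4pl(conc, rep(3.3, 10))
  expect_true(f_const$flat)
  expect_false(f_const$converged)
  set.seed(7)
  f_noise <- fit_4pl(conc, rnorm(10, 1, 0.01))
  expect_true(f_noise$flat)
  expect_match(f_noise$flags, "no_dose_dependence")
  # a clean sigmoid is not flagged
  expect_false(fit_4pl(conc, gen_4pl(conc, 1, 10, 1e-6, 1))$flat)
  # fewer than 5 doses is a hard error
  expect_error(fit_4pl(conc[1:4], 1:4), "at least 5")
  expect_error(fit_4pl(c(0, conc[1:9]), 1:10), "> 0")
})

test_that("noisy 4PL recovery: median log-EC50 error stays within 0.15 decades", {
  conc <- 1e-4 / 3^(19:0)
  truth <- gen_4pl(conc, 1, 30, 5e-8, 1)
  set.seed(123)
  errs <- replicate(100, {
    r <- truth + rnorm(20, 0, 0.05 * 30)
    abs(log10(fit_4pl(conc, r)$ec50 / 5e-8))
  })
  expect_lt(median(errs), 0.15)
})

test_that("peak-time extraction follows the 72/48 h and 30-72 h conventions", {
  grid <- seq(2, 96, by = 6)
  doses <- c(0, 1e-8, 1e-7, 1e-6)
  base <- tidyr::expand_grid(construct = "tcr", et_ratio = 3,
                             concentration = doses, time_h = grid)
  # P constant in time: the peak response equals that constant
  base$p_fold <- rep(c(1, 1.5, 2, 3), each = length(grid))
  base$s_per_tcell <- ifelse(base$time_h == 50, 9, 1) *
    rep(c(1, 1, 2, 4), each = length(grid))
  # K' spikes at t = 24, outside the 30-72 h window; in-window max is at 38
  base$k_rate_per_tcell_hr <- ifelse(base$time_h == 26, 100,
                                     ifelse(base$time_h == 38, 7, 0))
  base$p_rate_pct_day <- -(base$time_h - 50)^2 + 40  # unimodal, peak at t=50

  pp <- extract_peak_response(base, "proliferation")
  expect_equal(pp$concentration, doses[-1])          # control excluded
  expect_equal(pp$response, c(1.5, 2, 3))
  expect_match(pp$rule[1], "74 h")                   # nearest grid time to 72

  ss <- extract_peak_response(base, "specific_killing")
  expect_match(ss$rule[1], "50 h")                   # nearest grid time to 48
  expect_equal(ss$response, 9 * c(1, 2, 4))

  kk <- extract_peak_response(base, "kill_rate")
  expect_true(all(kk$response == 7))                 # 24 h spike excluded

  rr <- extract_peak_response(base, "proliferation_rate")
  expect_equal(unique(rr$response), 40)              # analytic in-window max

  # a short grid cannot serve the 72 h convention
  short <- base[base$time_h <= 32, ]
  expect_error(extract_peak_response(short, "proliferation"), "72 h")
})

test_that("concentration banding partitions doses with upward boundaries", {
  ec50 <- 5e-8
  b <- band_concentrations(ec50, c(1e-4, ec50, 100 * ec50, 0.001 * ec50, 1e-7))
  expect_equal(as.character(b$band), c("High", "Mid", "High", "Low", "Mid"))
  # every positive dose lands in exactly one band
  conc <- 1e-4 / 3^(20:0)
  bands <- band_concentrations(ec50, conc)
  expect_false(any(is.na(bands$band)))
  expect_equal(nrow(bands), length(conc))
  expect_error(band_concentrations(NA, conc), "converged")
  expect_error(band_concentrations(ec50, c(0, 1e-6)), "positive")
})

test_that("fit_dose_response and summarize_fits report every group", {
  cfg <- quick_config(rng_seed = 4,
                      concentrations = c(0, 1e-4 / 3^(8:0)), horizon = 96)
  pm <- plate_map(constructs = c("tcrA", "tcrB"), et_ratios = c(3, 1),
                  concentrations = cfg$concentrations, replicates = 1)
  prof <- build_profiles(simulate_plate(cfg, pm)$measurements)
  fits <- fit_dose_response(prof)
  expect_equal(nrow(fits), 2 * 2 * 4)   # constructs x E:T x readouts
  s <- summarize_fits(fits)
  expect_equal(nrow(s), 16)
  expect_setequal(unique(s$et_ratio), c("3:1", "1:1"))
  # non-converged fits keep their row with an empty EC50
  expect_true(all(is.na(s$ec50_uM[!s$converged])))
  # broom-style accessors
  f <- fits$fit[[which(fits$readout == "specific_killing")[1]]]
  td <- tidy(f)
  expect_equal(td$term, c("bottom", "top", "ec50", "hill_slope"))
  expect_equal(glance(f)$ec50, f$ec50)
})
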