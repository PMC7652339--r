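# shared fixtures: small configs and hand-built series used across test files

# a fast, small co-culture config (few doses, short horizon)
quick_config <- function(..., concentrations = c(0, 1e-8, 1e-7, 1e-6),
                         horizon = 48, count_noise = "none", rng_seed = 11) {
  sim_config(concentrations = concentrations, horizon = horizon,
             count_noise = count_noise, rng_seed = rng_seed, ...)
}

# a well series already on the 6-h grid, with generous signal so no clamp or
# floor fires; used by the formula tests
grid_series <- function(n = 12, seed = 1, well_id = "A1", construct = "tcr",
                        et_ratio = 3, concentration = 1e-6) {
  set.seed(seed)
  t <- 2 + 6 * (0:(n - 1))
  tibble::tibble(
    well_id = well_id, construct = construct, et_ratio = et_ratio,
    concentration = concentration, time_h = t,
    e_live = runif(n, 50, 5000),
    red_px = runif(n, 200, 10000),
    phase_px = runif(n, 20000, 400000)
  )
}

# independent literal re-codings of the six kinetic formulas, written as
# plain loops so they share nothing with the package implementation
oracle_fold_prolif <- function(e) {
  out <- numeric(length(e))
  for (i in seq_along(e)) out[i] <- e[i] / e[1]
  out
}
oracle_death_frac <- function(red, phase) {
  out <- numeric(length(red))
  for (i in seq_along(red)) out[i] <- red[i] / phase[i] * 100
  out
}
oracle_specific_killing <- function(td, td0) {
  out <- numeric(length(td))
  for (i in seq_along(td)) out[i] <- td[i] / td0[i]
  out
}
oracle_killing_per_tcell <- function(td, td0, e, e0) {
  out <- rep(NA_real_, length(td))
  for (i in 2:length(td)) {
    out[i] <- (td[i] / e[i - 1]) / (td0[i] / e0[i - 1])
  }
  out
}
oracle_prolif_rate <- function(e) {
  out <- rep(NA_real_, length(e))
  for (i in 2:length(e)) out[i] <- (e[i] - e[i - 1]) / e[i - 1] * 4 * 100
  out
}
oracle_kill_rate <- function(k, e) {
  out <- rep(NA_real_, length(k))
  for (i in 2:length(k)) out[i] <- (k[i] - k[i - 1]) / e[i - 1] / 6
  out
}

rel_err <- function(a, b) {
  i <- !is.na(a) & !is.na(b)
  max(abs(a[i] - b[i]) / pmax(abs(b[i]), .Machine$double.eps))
}

# exact 4PL evaluator for generating synthetic dose-response data
gen_4pl <- function(conc, bottom, top, ec50, slope) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^slope)
}
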