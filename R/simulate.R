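#' Simulate one co-culture well
#'
#' Discrete-time stochastic birth-death co-culture on the scan grid. The well
#' is seeded at time 0 with `target_seed_count` live targets and
#' `round(target_seed_count * et_ratio)` effectors; cells settle until the
#' first emitted scan at t = 2 h, after which the state advances once per scan
#' interval:
#'
#' * each live target dies with probability
#'   `1 - exp(-(h0 + h1 * hill_k(c) * rho_E) * dt)` where `h0` is the
#'   effector-independent background hazard, `h1` the saturating specific kill
#'   hazard, and `rho_E = E / (E + T)` the effector density;
#' * each effector divides with probability `1 - exp(-r * dt / 24)` where
#'   `r = (baseline + max * hill_p(c)) * (1 - coupling * f_kill)` per day and
#'   `f_kill = 1 - exp(-24 * total kill hazard)` is the per-day kill fraction
#'   implied by the current hazard;
#' * live targets grow logistically toward the carrying capacity.
#'
#' All draws use inverse-CDF sampling on per-step uniforms so that runs with a
#' common `well_seed` are coupled: raising the dose can only increase the
#' realized deaths at each step (common random numbers). Extinction is valid;
#' the series continues with zeros.
#'
#' Emitted measurements: `e_live` (Poisson-resampled if configured), `red_px =
#' red_area_per_dead_cell * cumulative dead` (with optional exponential decay)
#' and `phase_px = phase_area_per_target * (live + dead targets)`.
#'
#' @param config A [sim_config()].
#' @param concentration Molar peptide dose; must be one of `config$concentrations`.
#' @param et_ratio Effector:target ratio (> 0).
#' @param well_seed Integer seed for this well.
#' @param well_id Identifier carried into the output (default "W1").
#' @param construct Construct label carried into the output.
#' @return List with `measurements` (tibble: `well_id, construct, et_ratio,
#'   concentration, time_h, e_live, red_px, phase_px`) and `latent` (tibble:
#'   `time_h, t_live, t_dead_cum, e_live_latent`).
#' @examples
#' cfg <- sim_config(count_noise = "none")
#' w <- simulate_well(cfg, concentration = 1e-4, et_ratio = 3, well_seed = 11)
#' head(w$measurements)
#' @export
simulate_well <- function(config, concentration, et_ratio, well_seed,
                          well_id = "W1", construct = "construct") {
  stopifnot(inherits(config, "tk_sim_config"))
  assert_scalar_num(concentration, "concentration", lower = 0)
  if (!any(abs(concentration - config$concentrations) <= 1e-12 * max(1, concentration))) {
    abort_bad_arg(sprintf(
      "concentration %.4g M is not in config$concentrations (well %s).",
      concentration, well_id))
  }
  assert_scalar_num(et_ratio, "et_ratio")
  if (et_ratio <= 0) abort_bad_arg("`et_ratio` must be > 0.")

  dt <- config$scan_interval
  times <- seq(2, config$horizon, by = dt)
  n_t <- length(times)

  hk <- hill_response(concentration, config$kill_EC50, config$hill_slope_kill)
  hp <- hill_response(concentration, config$prolif_EC50, config$hill_slope_prolif)
  h0 <- config$nonspecific_hazard
  h1 <- config$kill_max_hazard * hk

  t_live <- round(config$target_seed_count)
  e_live <- round(config$target_seed_count * et_ratio)
  d_cum <- 0L
  red_sig <- 0
  births_cum <- 0L

  lat_t <- integer(n_t); lat_d <- integer(n_t); lat_e <- integer(n_t)
  obs_e <- numeric(n_t); obs_red <- numeric(n_t); obs_phase <- numeric(n_t)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(well_seed %% .Machine$integer.max))
  # one uniform per process per step, drawn up front in fixed order so the
  # stream is identical across doses (common random numbers)
  u <- matrix(runif(4L * n_t), nrow = n_t, ncol = 4L)

  for (k in seq_len(n_t)) {
    if (k > 1L) {
      rho_e <- if (e_live + t_live > 0) e_live / (e_live + t_live) else 0
      haz <- h0 + h1 * rho_e
      p_die <- 1 - exp(-haz * dt)
      f_kill <- 1 - exp(-24 * haz)
      r_div <- (config$prolif_baseline + config$prolif_max_rate * hp) *
        (1 - config$coupling_strength * f_kill)
      p_div <- 1 - exp(-r_div * dt / 24)
      p_grow <- 1 - exp(-config$target_growth_rate *
                          max(0, 1 - t_live / config$well_carrying_capacity) * dt / 24)

      deaths <- qbinom(u[k, 1L], t_live, p_die)
      divisions <- qbinom(u[k, 2L], e_live, p_div)
      t_births <- qbinom(u[k, 3L], t_live, p_grow)

      t_live <- t_live - deaths + t_births
      d_cum <- d_cum + deaths
      e_live <- e_live + divisions
      births_cum <- births_cum + t_births
      red_sig <- red_sig * exp(-config$red_decay_per_hour * dt) +
        config$red_area_per_dead_cell * deaths
    } else {
      red_sig <- config$red_area_per_dead_cell * d_cum
    }

    lat_t[k] <- t_live; lat_d[k] <- d_cum; lat_e[k] <- e_live
    obs_e[k] <- if (config$count_noise == "poisson") qpois(u[k, 4L], e_live) else e_live
    obs_red[k] <- red_sig
    obs_phase[k] <- config$phase_area_per_target * (t_live + d_cum)
  }

  list(
    measurements = tibble::tibble(
      well_id = well_id, construct = construct, et_ratio = et_ratio,
      concentration = concentration, time_h = times,
      e_live = obs_e, red_px = obs_red, phase_px = obs_phase
    ),
    latent = tibble::tibble(
      well_id = well_id, time_h = times,
      t_live = lat_t, t_dead_cum = lat_d, e_live_latent = lat_e,
      t_births_cum = births_cum
    )
  )
}

#' Simulate a whole plate with ground truth
#'
#' Runs [simulate_well()] for every row of a plate map, with per-well seeds
#' derived reproducibly from `config$rng_seed`. Identical seeds give
#' bit-identical output.
#'
#' @param config A [sim_config()].
#' @param plate A plate map tibble from [plate_map()] / [read_plate_map()]:
#'   columns `well_id, construct, et_ratio, concentration, replicate`.
#' @return A `tk_sim_truth` list: `config`, `plate`, `measurements` (all wells,
#'   row-bound), `latent` (latent trajectories per well).
#' @examples
#' cfg <- sim_config(concentrations = c(0, 1e-8, 1e-6), rng_seed = 3)
#' pm <- plate_map(et_ratios = 3, concentrations = cfg$concentrations)
#' truth <- simulate_plate(cfg, pm)
#' dplyr::count(truth$measurements, concentration)
#' @export
simulate_plate <- function(config, plate) {
  stopifnot(inherits(config, "tk_sim_config"))
  plate <- validate_plate_map(plate)

  bad_c <- !vapply(plate$concentration, function(cc)
    any(abs(cc - config$concentrations) <= 1e-12 * max(1, cc)), logical(1))
  if (any(bad_c)) {
    abort_bad_arg(paste0(
      "plate concentrations absent from config for wells: ",
      paste(plate$well_id[bad_c], collapse = ", ")))
  }
  bad_r <- !vapply(plate$et_ratio, function(r)
    any(abs(r - config$effector_to_target_ratios) <= 1e-9 * max(1, r)), logical(1))
  if (any(bad_r)) {
    abort_bad_arg(paste0(
      "plate E:T ratios absent from config for wells: ",
      paste(plate$well_id[bad_r], collapse = ", ")))
  }

  seeds <- derive_seeds(config$rng_seed, nrow(plate))
  runs <- purrr::pmap(
    list(plate$concentration, plate$et_ratio, seeds, plate$well_id, plate$construct),
    function(cc, r, s, w, con) simulate_well(config, cc, r, s, well_id = w, construct = con)
  )
  out <- list(
    config = config,
    plate = plate,
    measurements = dplyr::bind_rows(purrr::map(runs, "measurements")),
    latent = dplyr::bind_rows(purrr::map(runs, "latent"))
  )
  class(out) <- "tk_sim_truth"
  out
}

#' @export
print.tk_sim_truth <- function(x, ...) {
  cat(sprintf("<tk_sim_truth> %d wells x %d timepoints (seed %d)\n",
              nrow(x$plate), length(unique(x$measurements$time_h)), x$config$rng_seed))
  invisible(x)
}
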