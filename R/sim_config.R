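#' Co-culture simulation configuration
#'
#' Builds and validates the parameter set for the stochastic co-culture
#' simulator. Defaults describe a 384-well adherent-target assay: 2000
#' peptide-loaded targets per well, effectors added at 3:1, 1:1 or 1:3,
#' a 21-point 3-fold peptide titration from 100 uM down plus a 0 uM control,
#' scans every 2 h to 96 h with the first usable scan at 2 h (settling time).
#'
#' Rate parameters are hazards: `kill_max_hazard` is the per-target per-hour
#' death hazard at saturating dose and effector density 1; it is scaled by the
#' instantaneous effector density `E / (E + T)`. `nonspecific_hazard` is the
#' effector-independent background death hazard (spontaneous death plus dye
#' background) that the 0 uM control estimates. Proliferation rates are per
#' effector per day; `coupling_strength` (0-1) down-weights division while
#' killing is active, encoding the inverse proliferation/cytotoxicity
#' relationship seen at high dose and high effector:target ratio.
#'
#' @param target_seed_count Targets seeded per well (default 2000).
#' @param effector_to_target_ratios Positive effector:target ratios.
#' @param concentrations Molar peptide concentrations, must include 0.
#' @param scan_interval Hours between scans (2 or 4).
#' @param horizon Assay length, hours; must be a multiple of `scan_interval`.
#' @param kill_EC50,prolif_EC50 Molar half-max concentrations (> 0).
#' @param kill_max_hazard Per-target per-hour specific kill hazard at
#'   saturating dose and effector density 1.
#' @param nonspecific_hazard Per-target per-hour background death hazard.
#' @param prolif_max_rate,prolif_baseline Per-effector per-day division rates
#'   (antigen-driven maximum above baseline, and baseline).
#' @param hill_slope_kill,hill_slope_prolif Hill coefficients (> 0).
#' @param coupling_strength In `[0, 1]`; 0 decouples proliferation from killing.
#' @param target_growth_rate Per-day logistic growth rate of live targets.
#' @param well_carrying_capacity Target carrying capacity per well (cells).
#' @param red_area_per_dead_cell Red pixels contributed per dead cell.
#' @param phase_area_per_target Phase pixels occupied per (live or dead) target.
#' @param red_decay_per_hour Exponential decay of accumulated red signal
#'   (default 0: dead-cell signal persists).
#' @param count_noise `"none"` or `"poisson"` observation noise on counts.
#' @param rng_seed Integer master seed.
#' @return A validated list of class `tk_sim_config`.
#' @examples
#' cfg <- sim_config(rng_seed = 7)
#' cfg$kill_EC50
#' @export
sim_config <- function(target_seed_count = 2000,
                       effector_to_target_ratios = c(3, 1, 1 / 3),
                       concentrations = default_titration(),
                       scan_interval = 2,
                       horizon = 96,
                       kill_EC50 = 5e-8,
                       kill_max_hazard = 0.025,
                       nonspecific_hazard = 0.003,
                       prolif_EC50 = 5e-8 / 7,
                       prolif_max_rate = 0.35,
                       prolif_baseline = 0.05,
                       hill_slope_kill = 1.5,
                       hill_slope_prolif = 1.5,
                       coupling_strength = 0.9,
                       target_growth_rate = 0.2,
                       well_carrying_capacity = 8000,
                       red_area_per_dead_cell = 100,
                       phase_area_per_target = 200,
                       red_decay_per_hour = 0,
                       count_noise = c("poisson", "none"),
                       rng_seed = 1L) {
  count_noise <- match.arg(count_noise)
  if (is.numeric(concentrations) && anyDuplicated(concentrations)) {
    abort_bad_arg("`concentrations` must be unique.")
  }
  cfg <- list(
    target_seed_count = target_seed_count,
    effector_to_target_ratios = effector_to_target_ratios,
    concentrations = sort(concentrations),
    scan_interval = scan_interval,
    horizon = horizon,
    kill_EC50 = kill_EC50,
    kill_max_hazard = kill_max_hazard,
    nonspecific_hazard = nonspecific_hazard,
    prolif_EC50 = prolif_EC50,
    prolif_max_rate = prolif_max_rate,
    prolif_baseline = prolif_baseline,
    hill_slope_kill = hill_slope_kill,
    hill_slope_prolif = hill_slope_prolif,
    coupling_strength = coupling_strength,
    target_growth_rate = target_growth_rate,
    well_carrying_capacity = well_carrying_capacity,
    red_area_per_dead_cell = red_area_per_dead_cell,
    phase_area_per_target = phase_area_per_target,
    red_decay_per_hour = red_decay_per_hour,
    count_noise = count_noise,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "tk_sim_config"
  validate_sim_config(cfg)
}

#' Default 3-fold peptide titration
#'
#' 21 concentrations serially diluted 3-fold from 100 uM (down to ~29 pM),
#' plus the 0 uM control, in molar units, ascending.
#'
#' @param top Top concentration, molar (default 1e-4 = 100 uM).
#' @param n_doses Number of positive doses (default 21).
#' @param fold Dilution factor (default 3).
#' @return Numeric vector of length `n_doses + 1` including 0.
#' @export
default_titration <- function(top = 1e-4, n_doses = 21, fold = 3) {
  c(0, top / fold^((n_doses - 1):0))
}

validate_sim_config <- function(cfg) {
  rates <- c("kill_max_hazard", "nonspecific_hazard", "prolif_max_rate",
             "prolif_baseline", "target_growth_rate", "red_decay_per_hour")
  for (r in rates) assert_scalar_num(cfg[[r]], r, lower = 0)
  for (p in c("kill_EC50", "prolif_EC50", "hill_slope_kill", "hill_slope_prolif")) {
    assert_scalar_num(cfg[[p]], p)
    if (cfg[[p]] <= 0) abort_bad_arg(sprintf("`%s` must be > 0.", p))
  }
  assert_scalar_num(cfg$coupling_strength, "coupling_strength", 0, 1)
  assert_scalar_num(cfg$target_seed_count, "target_seed_count", lower = 1)
  assert_scalar_num(cfg$well_carrying_capacity, "well_carrying_capacity", lower = 1)
  assert_scalar_num(cfg$red_area_per_dead_cell, "red_area_per_dead_cell", lower = 0)
  assert_scalar_num(cfg$phase_area_per_target, "phase_area_per_target")
  if (cfg$phase_area_per_target <= 0) abort_bad_arg("`phase_area_per_target` must be > 0.")
  if (!cfg$scan_interval %in% c(2, 4)) abort_bad_arg("`scan_interval` must be 2 or 4 hours.")
  assert_scalar_num(cfg$horizon, "horizon", lower = cfg$scan_interval)
  if (cfg$horizon %% cfg$scan_interval != 0) {
    abort_bad_arg("`scan_interval` must divide `horizon`.")
  }
  if (!is.numeric(cfg$concentrations) || any(!is.finite(cfg$concentrations)) ||
      any(cfg$concentrations < 0)) {
    abort_bad_arg("`concentrations` must be finite and >= 0.")
  }
  if (anyDuplicated(cfg$concentrations)) abort_bad_arg("`concentrations` must be unique.")
  if (is.unsorted(cfg$concentrations)) abort_bad_arg("`concentrations` must be sorted ascending.")
  if (any(!is.finite(cfg$effector_to_target_ratios)) ||
      any(cfg$effector_to_target_ratios <= 0)) {
    abort_bad_arg("`effector_to_target_ratios` must be positive.")
  }
  cfg
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML file holds exactly the fields of [sim_config()]; unknown keys are
#' an error so typos do not silently fall back to defaults.
#'
#' @param path File path.
#' @return `read_sim_config()` returns a validated `tk_sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort_bad_arg(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A `tk_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "tk_sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @export
print.tk_sim_config <- function(x, ...) {
  cat("<tk_sim_config>\n")
  cat(sprintf("  targets/well: %d, E:T ratios: %s\n", x$target_seed_count,
              paste(et_label(x$effector_to_target_ratios), collapse = ", ")))
  cat(sprintf("  doses: %d positive (%.3g - %.3g M) + control, scan %g h to %g h\n",
              sum(x$concentrations > 0), min(x$concentrations[x$concentrations > 0]),
              max(x$concentrations), x$scan_interval, x$horizon))
  cat(sprintf("  kill: EC50 %.3g M, max hazard %.3g /h, background %.3g /h\n",
              x$kill_EC50, x$kill_max_hazard, x$nonspecific_hazard))
  cat(sprintf("  proliferation: EC50 %.3g M, max %.3g /d over baseline %.3g /d, coupling %.2g\n",
              x$prolif_EC50, x$prolif_max_rate, x$prolif_baseline, x$coupling_strength))
  invisible(x)
}
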