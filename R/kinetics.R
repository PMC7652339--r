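#' Resample a well time series onto the analysis grid
#'
#' Linearly interpolates `e_live`, `red_px` and `phase_px` onto the grid
#' t = 2, 2 + step, 2 + 2*step, ... hours (anchored at the 2-hour settling
#' point). Native samples that coincide with grid times are preserved exactly.
#' All downstream kinetic quantities are computed on this grid; the default
#' 6-hour step reflects the observation that killing at time t is driven by
#' the effectors present 6 hours earlier.
#'
#' @param series Tibble for one well: columns `time_h`, `e_live`, `red_px`,
#'   `phase_px` (plus any id columns, which are carried through).
#' @param step Grid step in hours (default 6).
#' @return Tibble with the same columns on the grid times.
#' @examples
#' s <- tibble::tibble(time_h = seq(2, 26, 2), e_live = 100 + time_h,
#'                     red_px = 0, phase_px = 1000)
#' resample_to_grid(s)
#' @export
resample_to_grid <- function(series, step = 6) {
  check_series(series)
  assert_scalar_num(step, "step")
  if (step <= 0) abort_bad_arg("`step` must be > 0.")
  t <- series$time_h
  if (max(t) - min(t) < step) {
    abort_bad_arg("series spans less than one grid step; cannot resample.")
  }
  if (min(diff(t)) > step + 1e-9) {
    abort_bad_arg("native cadence is coarser than the grid step.")
  }
  grid <- seq(2, max(t), by = step)
  grid <- grid[grid >= min(t)]
  interp <- function(y) approx(t, y, xout = grid, method = "linear", ties = "ordered")$y
  out <- series[rep(1L, length(grid)), , drop = FALSE]
  out$time_h <- grid
  out$e_live <- interp(series$e_live)
  out$red_px <- interp(series$red_px)
  out$phase_px <- interp(series$phase_px)
  tibble::as_tibble(out)
}

check_series <- function(series) {
  needed <- c("time_h", "e_live", "red_px", "phase_px")
  miss <- setdiff(needed, names(series))
  if (length(miss)) {
    abort_bad_arg(paste0("series lacks columns: ", paste(miss, collapse = ", ")))
  }
  t <- series$time_h
  if (length(t) < 2) abort_bad_arg("series needs at least two timepoints.")
  if (any(diff(t) <= 0)) abort_bad_arg("`time_h` must be strictly increasing.")
  if (any(!is.finite(series$e_live)) || any(series$e_live < 0)) {
    abort_bad_arg("`e_live` must be finite and >= 0.")
  }
  if (any(!is.finite(series$red_px)) || any(series$red_px < 0)) {
    abort_bad_arg("`red_px` must be finite and >= 0.")
  }
  if (any(!is.finite(series$phase_px))) abort_bad_arg("`phase_px` must be finite.")
  invisible(series)
}

#' Fold proliferation of effectors
#'
#' `P(t) = E_live(t) / E_live(t0 = 2 h)`: effector expansion relative to the
#' post-settling count, correcting for well-to-well seeding differences.
#' `P = 1` at the first timepoint by construction.
#'
#' @param series Gridded well series (see [resample_to_grid()]).
#' @return Input tibble with columns `p_fold` and `flag` added. If the
#'   settling-time count is zero the well is unusable for P: `p_fold` is `NA`
#'   and flagged `"e0_zero"`.
#' @export
fold_proliferation <- function(series) {
  check_series(series)
  e0 <- series$e_live[1]
  out <- series
  if (e0 <= 0) {
    out$p_fold <- NA_real_
    out$flag <- "e0_zero"
  } else {
    out$p_fold <- series$e_live / e0
    out$flag <- ""
  }
  tibble::as_tibble(out)
}

#' Total target death fraction
#'
#' `T_dead(t) = 100 * red_px(t) / phase_px(t)` percent: red (dead/dying) pixel
#' area over the phase-contrast occupied area, capturing death irrespective of
#' well-to-well seeding.
#'
#' @param series Gridded well series.
#' @return Input tibble with columns `t_dead_pct` and `flag` added. Timepoints
#'   with `phase_px <= 0` get `NA` and flag `"phase_zero"`.
#' @export
death_fraction <- function(series) {
  check_series(series)
  out <- series
  bad <- series$phase_px <= 0
  out$t_dead_pct <- ifelse(bad, NA_real_, 100 * series$red_px / series$phase_px)
  out$flag <- ifelse(bad, "phase_zero", "")
  tibble::as_tibble(out)
}

#' Specific killing relative to the 0-dose control
#'
#' `K(t, c) = T_dead(t, c) / T_dead(t, 0)`: target death at dose c normalized
#' to the no-peptide control, removing nonspecific/allo-reactive killing.
#' `K(t, 0) = 1` identically. Control values below the one-pixel floor (the
#' death fraction a single red pixel would produce) are clamped to the floor
#' and flagged `"control_floor"`; when the dosed well is *also* below the
#' floor there is no death signal at all and K is undefined: `NA` with flag
#' `"no_death_signal"` (typically only the earliest scans).
#'
#' @param t_dead Numeric vector: death fraction (%) at dose c on the grid.
#' @param t_dead_0 Numeric vector: death fraction (%) of the matched control.
#' @param phase_px_0 Numeric vector: control phase area (pixels), used for the
#'   one-pixel floor; defaults to `Inf` (no floor, clamp only at exact zero).
#' @return Tibble with columns `k_specific` and `flag`.
#' @export
specific_killing <- function(t_dead, t_dead_0, phase_px_0 = Inf) {
  if (length(t_dead) != length(t_dead_0)) {
    abort_bad_arg("`t_dead` and `t_dead_0` must share the time grid.")
  }
  floor_pct <- 100 * 1 / phase_px_0
  floor_pct <- pmax(floor_pct, .Machine$double.xmin)
  clamped <- !is.na(t_dead_0) & t_dead_0 < floor_pct
  no_signal <- clamped & !is.na(t_dead) & t_dead < floor_pct
  denom <- ifelse(clamped, floor_pct, t_dead_0)
  tibble::tibble(
    k_specific = ifelse(no_signal, NA_real_, t_dead / denom),
    flag = ifelse(no_signal, "no_death_signal",
                  ifelse(clamped, "control_floor", ""))
  )
}

#' Per-T-cell specific killing
#'
#' `S(t, c) = [T_dead(t, c) / E_live(t - lag, c)] / [T_dead(t, 0) /
#' E_live(t - lag, 0)]`: cytotoxic activity per T cell, attributing killing
#' observed at t to the effectors present `lag` hours earlier (default 6 h).
#' `S(t, 0) = 1` identically. Effector counts of zero are clamped to 1 cell
#' and flagged `"e_floor"`.
#'
#' @param t_dead,t_dead_0 Death fractions (%) at dose c and at 0, on the grid.
#' @param e_live,e_live_0 Effector counts at dose c and at 0, on the grid.
#' @param time_h Grid times (hours).
#' @param lag Killing attribution lag in hours (default 6); must be a multiple
#'   of the grid step.
#' @param phase_px_0 Control phase area for the control floor (see
#'   [specific_killing()]).
#' @return Tibble with `s_per_tcell` and `flag`; times earlier than
#'   `t0 + lag` are `NA`.
#' @export
killing_per_tcell <- function(t_dead, t_dead_0, e_live, e_live_0, time_h,
                              lag = 6, phase_px_0 = Inf) {
  n <- length(time_h)
  stopifnot(length(t_dead) == n, length(t_dead_0) == n,
            length(e_live) == n, length(e_live_0) == n)
  shift <- lag_steps(time_h, lag)
  floor_pct <- pmax(100 / phase_px_0, .Machine$double.xmin)
  ctrl_flag <- !is.na(t_dead_0) & t_dead_0 < floor_pct
  no_signal <- ctrl_flag & !is.na(t_dead) & t_dead < floor_pct
  td0 <- ifelse(ctrl_flag, floor_pct, t_dead_0)

  s <- rep(NA_real_, n)
  fl <- character(n)
  idx <- seq_len(n)[-seq_len(shift)]
  e_lag <- e_live[idx - shift]
  e0_lag <- e_live_0[idx - shift]
  ef <- e_lag <= 0
  e0f <- e0_lag <= 0
  e_lag[ef] <- 1
  e0_lag[e0f] <- 1
  s[idx] <- ifelse(no_signal[idx], NA_real_,
                   (t_dead[idx] / e_lag) / (td0[idx] / e0_lag))
  fl[idx] <- mapply(function(a, b, c2, d) join_flags(c(
    if (a) "e_floor" else "", if (b) "e_floor" else "",
    if (d) "no_death_signal" else if (c2) "control_floor" else "")),
    ef, e0f, if (length(idx)) ctrl_flag[idx] else logical(0),
    if (length(idx)) no_signal[idx] else logical(0))
  tibble::tibble(s_per_tcell = s, flag = fl)
}

#' Proliferation rate
#'
#' `P'(t) = 100 * 4 * (E_live(t) - E_live(t - lag)) / E_live(t - lag)` in
#' percent per day for the default 6-hour lag (the factor 24 / lag converts
#' the lag interval to a day). Negative rates (declining effector counts) are
#' reported, not truncated.
#'
#' @param e_live Effector counts on the grid.
#' @param time_h Grid times (hours).
#' @param lag Differencing lag in hours (default 6).
#' @return Tibble with `p_rate_pct_day` and `flag`; the first `lag` hours are
#'   `NA`, and zero lagged denominators are flagged `"e_zero"` with `NA` rate.
#' @export
proliferation_rate <- function(e_live, time_h, lag = 6) {
  n <- length(time_h)
  stopifnot(length(e_live) == n)
  shift <- lag_steps(time_h, lag)
  out <- rep(NA_real_, n)
  fl <- character(n)
  idx <- seq_len(n)[-seq_len(shift)]
  e_lag <- e_live[idx - shift]
  zero <- e_lag <= 0
  out[idx] <- ifelse(zero, NA_real_,
                     100 * (24 / lag) * (e_live[idx] - e_lag) / e_lag)
  fl[idx] <- ifelse(zero, "e_zero", "")
  tibble::tibble(p_rate_pct_day = out, flag = fl)
}

#' Specific kill rate
#'
#' `K'(t) = [(K(t) - K(t - lag)) / E_live(t - lag)] / lag`: the rate of
#' specific target death per T cell per hour. Zero lagged effector counts are
#' clamped to 1 cell and flagged.
#'
#' @param k_specific Specific killing K on the grid.
#' @param e_live Effector counts on the grid.
#' @param time_h Grid times (hours).
#' @param lag Differencing lag in hours (default 6).
#' @return Tibble with `k_rate_per_tcell_hr` and `flag`.
#' @export
kill_rate <- function(k_specific, e_live, time_h, lag = 6) {
  n <- length(time_h)
  stopifnot(length(k_specific) == n, length(e_live) == n)
  shift <- lag_steps(time_h, lag)
  out <- rep(NA_real_, n)
  fl <- character(n)
  idx <- seq_len(n)[-seq_len(shift)]
  e_lag <- e_live[idx - shift]
  zero <- e_lag <= 0
  e_lag[zero] <- 1
  out[idx] <- (k_specific[idx] - k_specific[idx - shift]) / e_lag / lag
  fl[idx] <- ifelse(zero, "e_floor", "")
  tibble::tibble(k_rate_per_tcell_hr = out, flag = fl)
}

lag_steps <- function(time_h, lag) {
  if (length(time_h) < 2) abort_bad_arg("need at least two grid times.")
  step <- diff(time_h)[1]
  if (any(abs(diff(time_h) - step) > 1e-9)) {
    abort_bad_arg("time grid must be evenly spaced; resample first.")
  }
  shift <- lag / step
  if (abs(shift - round(shift)) > 1e-9 || shift < 1) {
    abort_bad_arg("`lag` must be a positive multiple of the grid step.")
  }
  as.integer(round(shift))
}

#' Build kinetic profiles for a plate
#'
#' Orchestrates the per-well transforms for every (construct, E:T,
#' concentration) condition of a plate: each well is resampled to the grid and
#' its fold proliferation and death fraction computed, replicate wells are
#' then averaged, and the normalized quantities (specific killing, per-T-cell
#' killing, proliferation and kill rates) are computed from the averaged
#' curves using the group's averaged 0-dose control. Flags raised anywhere
#' (zero denominators, control floors) propagate into the `flag` column.
#'
#' @param measurements Tibble of well time series: columns `well_id,
#'   construct, et_ratio, concentration, time_h, e_live, red_px, phase_px`.
#' @param step Grid step, hours (default 6).
#' @param lag Killing/proliferation attribution lag, hours (default 6).
#' @return A `tk_profile` tibble: one row per (construct, et_ratio,
#'   concentration, time_h) with columns `e_live, p_fold, t_dead_pct,
#'   k_specific, s_per_tcell, p_rate_pct_day, k_rate_per_tcell_hr, n_wells,
#'   flag`.
#' @examples
#' cfg <- sim_config(concentrations = c(0, 1e-6), count_noise = "none")
#' pm <- plate_map(et_ratios = 3, concentrations = cfg$concentrations, replicates = 1)
#' prof <- build_profiles(simulate_plate(cfg, pm)$measurements)
#' head(prof)
#' @export
build_profiles <- function(measurements, step = 6, lag = 6) {
  needed <- c("well_id", "construct", "et_ratio", "concentration",
              "time_h", "e_live", "red_px", "phase_px")
  miss <- setdiff(needed, names(measurements))
  if (length(miss)) {
    abort_bad_arg(paste0("measurements lack columns: ", paste(miss, collapse = ", ")))
  }
  groups <- dplyr::distinct(measurements, .data$construct, .data$et_ratio)
  no_ctrl <- purrr::pmap_lgl(groups, function(construct, et_ratio) {
    sub <- measurements[measurements$construct == construct &
                          measurements$et_ratio == et_ratio, ]
    !any(sub$concentration == 0)
  })
  if (any(no_ctrl)) {
    bad <- groups[no_ctrl, ]
    abort_bad_arg(paste0(
      "missing 0 M control well for group(s): ",
      paste(sprintf("%s / %s", bad$construct, et_label(bad$et_ratio)),
            collapse = "; ")))
  }

  # per-well grid resampling + Eq 1-2, then replicate averaging
  per_well <- measurements |>
    dplyr::group_by(.data$well_id, .data$construct, .data$et_ratio,
                    .data$concentration) |>
    dplyr::group_modify(function(df, key) {
      g <- resample_to_grid(df, step = step)
      p <- fold_proliferation(g)
      d <- death_fraction(g)
      tibble::tibble(
        time_h = g$time_h, e_live = g$e_live, red_px = g$red_px,
        phase_px = g$phase_px, p_fold = p$p_fold, t_dead_pct = d$t_dead_pct,
        flag = combine_flag_cols(p$flag, d$flag)
      )
    }) |>
    dplyr::ungroup()

  cond <- per_well |>
    dplyr::group_by(.data$construct, .data$et_ratio, .data$concentration,
                    .data$time_h) |>
    dplyr::summarise(
      e_live = mean(.data$e_live),
      phase_px = mean(.data$phase_px),
      p_fold = mean(.data$p_fold),
      t_dead_pct = mean(.data$t_dead_pct),
      n_wells = dplyr::n(),
      flag = join_flags(.data$flag),
      .groups = "drop"
    )

  cond |>
    dplyr::group_by(.data$construct, .data$et_ratio) |>
    dplyr::group_modify(function(df, key) profile_one_group(df, lag = lag)) |>
    dplyr::ungroup() |>
    structure(class = c("tk_profile", "tbl_df", "tbl", "data.frame"))
}

# normalized quantities for one (construct, E:T) group of averaged curves
profile_one_group <- function(df, lag) {
  ctrl <- df[df$concentration == 0, ]
  ctrl <- ctrl[order(ctrl$time_h), ]
  df <- df[order(df$concentration, df$time_h), ]

  out <- df |>
    dplyr::group_by(.data$concentration) |>
    dplyr::group_modify(function(d, key) {
      if (!isTRUE(all.equal(d$time_h, ctrl$time_h))) {
        abort_bad_arg("dose and control wells are on different time grids.")
      }
      k <- specific_killing(d$t_dead_pct, ctrl$t_dead_pct, ctrl$phase_px)
      s <- killing_per_tcell(d$t_dead_pct, ctrl$t_dead_pct, d$e_live,
                             ctrl$e_live, d$time_h, lag = lag,
                             phase_px_0 = ctrl$phase_px)
      if (key$concentration == 0) {
        # self-normalization: the identities K(t,0) = 1 and S(t,0) = 1 hold by
        # definition and must not be disturbed by the control-floor clamp or
        # the no-death-signal rule (0/0 at dose 0 is definitionally 1)
        k$k_specific <- ifelse(is.na(d$t_dead_pct), NA_real_, 1)
        n_pts <- length(d$time_h)
        shift <- lag_steps(d$time_h, lag)
        s$s_per_tcell <- ifelse(seq_len(n_pts) <= shift | is.na(d$t_dead_pct),
                                NA_real_, 1)
        k$flag <- s$flag <- rep("", n_pts)
      }
      pr <- proliferation_rate(d$e_live, d$time_h, lag = lag)
      kr <- kill_rate(k$k_specific, d$e_live, d$time_h, lag = lag)
      d$k_specific <- k$k_specific
      d$s_per_tcell <- s$s_per_tcell
      d$p_rate_pct_day <- pr$p_rate_pct_day
      d$k_rate_per_tcell_hr <- kr$k_rate_per_tcell_hr
      d$flag <- combine_flag_cols(
        combine_flag_cols(d$flag, k$flag),
        combine_flag_cols(s$flag, combine_flag_cols(pr$flag, kr$flag)))
      d
    }) |>
    dplyr::ungroup()
  dplyr::select(out, "concentration", "time_h", "e_live", "p_fold",
                "t_dead_pct", "k_specific", "s_per_tcell", "p_rate_pct_day",
                "k_rate_per_tcell_hr", "n_wells", "flag")
}
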