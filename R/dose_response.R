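#' Extract per-concentration responses at the conventional peak times
#'
#' Reduces a kinetic profile to one response per positive concentration using
#' the assay's peak-time conventions: fold proliferation is read at the grid
#' time nearest 72 h, per-T-cell specific killing at the grid time nearest
#' 48 h, and the proliferation and kill rates as the per-concentration maximum
#' over grid times inside the 30-72 h window. Zero-dose wells serve only the
#' normalization and are excluded here (log-dose is undefined for them).
#'
#' @param profile A `tk_profile` tibble from [build_profiles()] (a single
#'   construct x E:T group, or pass grouped data through
#'   [fit_dose_response()]).
#' @param readout One of `"proliferation"`, `"specific_killing"`,
#'   `"proliferation_rate"`, `"kill_rate"`.
#' @param peak_time_prolif,peak_time_kill Target peak times, hours.
#' @param rate_window Two-element window (hours) for the rate maxima.
#' @return Tibble with columns `construct, et_ratio, concentration, response,
#'   rule` (one row per positive concentration).
#' @export
extract_peak_response <- function(profile,
                                  readout = c("proliferation", "specific_killing",
                                              "proliferation_rate", "kill_rate"),
                                  peak_time_prolif = 72,
                                  peak_time_kill = 48,
                                  rate_window = c(30, 72)) {
  readout <- match.arg(readout)
  col <- switch(readout,
                proliferation = "p_fold",
                specific_killing = "s_per_tcell",
                proliferation_rate = "p_rate_pct_day",
                kill_rate = "k_rate_per_tcell_hr")
  prof <- dplyr::filter(profile, .data$concentration > 0)
  if (nrow(prof) == 0) abort_bad_arg("profile has no positive concentrations.")
  times <- sort(unique(prof$time_h))

  if (readout %in% c("proliferation", "specific_killing")) {
    target <- if (readout == "proliferation") peak_time_prolif else peak_time_kill
    if (target > max(times) + diff(range(times)) / length(times) ||
        target < min(times)) {
      abort_bad_arg(sprintf(
        "profile grid (%g-%g h) does not cover the %g h peak time for %s.",
        min(times), max(times), target, readout))
    }
    # nearest grid time; ties resolved toward the earlier time
    t_use <- times[which.min(abs(times - target))]
    out <- prof |>
      dplyr::filter(.data$time_h == t_use) |>
      dplyr::mutate(response = .data[[col]],
                    rule = sprintf("%s at %g h (nearest %g h)", col, t_use, target))
  } else {
    in_win <- times >= rate_window[1] & times <= rate_window[2]
    if (!any(in_win)) {
      abort_bad_arg(sprintf(
        "profile grid does not cover the %g-%g h window for %s.",
        rate_window[1], rate_window[2], readout))
    }
    out <- prof |>
      dplyr::filter(.data$time_h >= rate_window[1],
                    .data$time_h <= rate_window[2]) |>
      dplyr::group_by(.data$construct, .data$et_ratio, .data$concentration) |>
      dplyr::summarise(response = if (all(is.na(.data[[col]]))) NA_real_ else
        max(.data[[col]], na.rm = TRUE), .groups = "drop") |>
      dplyr::mutate(rule = sprintf("max %s in [%g, %g] h", col,
                                   rate_window[1], rate_window[2]))
  }
  dplyr::select(out, "construct", "et_ratio", "concentration", "response", "rule") |>
    dplyr::arrange(.data$concentration) |>
    tibble::as_tibble()
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `r(c) = bottom + (top - bottom) / (1 +
#' (ec50 / c)^slope)` in log10-concentration space, by Levenberg-Marquardt
#' with multi-start initialization (five log-spaced EC50 starting points
#' across the dose range). The Hill slope is bounded to `[0.1, 10]` and the
#' EC50 to `[min dose / 10, max dose * 10]`. Emax is the fitted top plateau.
#'
#' A fit is flagged *flat* ("no dose dependence") when the 4PL does not beat a
#' constant-response model: zero response variance, an F-test p-value >= 0.01,
#' or a fitted span smaller than 5% of the mean absolute response.
#'
#' @param concentration Positive molar doses (>= 5 distinct values).
#' @param response Finite responses, same length.
#' @param slope_bounds,ec50_bounds_factor Parameter bounds (see details).
#' @param n_starts Number of log-spaced EC50 initializations (default 5).
#' @return A `tk_4pl` object: list with `bottom, top, ec50, hill_slope, emax,
#'   rss, converged, flat, n_points, data, flags`.
#' @examples
#' c <- 1e-4 / 3^(19:0)
#' r <- 1 + 29 / (1 + (5e-8 / c))
#' f <- fit_4pl(c, r)
#' f$ec50
#' @export
fit_4pl <- function(concentration, response, slope_bounds = c(0.1, 10),
                    ec50_bounds_factor = 10, n_starts = 5) {
  ok <- is.finite(concentration) & is.finite(response)
  if (any(!is.finite(response))) abort_bad_arg("`response` must be finite.")
  if (any(concentration <= 0)) {
    abort_bad_arg("`concentration` must be > 0 for a log-dose fit; drop the control.")
  }
  concentration <- concentration[ok]
  response <- response[ok]
  n <- length(response)
  if (length(unique(concentration)) < 5) {
    abort_bad_arg("need at least 5 distinct positive concentrations.")
  }
  x <- log10(concentration)
  lo_le <- log10(min(concentration) / ec50_bounds_factor)
  hi_le <- log10(max(concentration) * ec50_bounds_factor)

  resid_fn <- function(p) {
    response - (p[1] + (p[2] - p[1]) / (1 + 10^(p[4] * (p[3] - x))))
  }

  rss_flat <- sum((response - mean(response))^2)
  if (rss_flat == 0) {
    return(new_tk_4pl(bottom = response[1], top = response[1],
                      ec50 = NA_real_, hill_slope = NA_real_, rss = 0,
                      converged = FALSE, flat = TRUE, n_points = n,
                      concentration = concentration, response = response,
                      flags = "flat_zero_variance"))
  }

  b0 <- quantile(response, 0.1, names = FALSE)
  t0 <- quantile(response, 0.9, names = FALSE)
  starts_le <- seq(min(x), max(x), length.out = n_starts)
  best <- NULL
  for (le0 in starts_le) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(b0, t0, le0, 1),
        fn = resid_fn,
        lower = c(-Inf, -Inf, lo_le, slope_bounds[1]),
        upper = c(Inf, Inf, hi_le, slope_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }

  if (is.null(best)) {
    return(new_tk_4pl(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
                      hill_slope = NA_real_, rss = NA_real_, converged = FALSE,
                      flat = FALSE, n_points = n, concentration = concentration,
                      response = response, flags = "no_convergence"))
  }

  p <- best$par
  converged <- best$info %in% 1:4
  span <- abs(p[2] - p[1])
  sigma2 <- best_rss / max(1, n - 4)
  f_p <- if (best_rss <= 0) 0 else {
    fstat <- ((rss_flat - best_rss) / 3) / (best_rss / max(1, n - 4))
    pf(fstat, 3, max(1, n - 4), lower.tail = FALSE)
  }
  flat <- f_p >= 0.01 || span < 0.05 * mean(abs(response))
  flags <- join_flags(c(
    if (!converged) "no_convergence" else "",
    if (flat) "no_dose_dependence" else "",
    if (converged && (abs(p[3] - lo_le) < 1e-6 || abs(p[3] - hi_le) < 1e-6))
      "ec50_at_bound" else ""))

  new_tk_4pl(bottom = p[1], top = p[2], ec50 = 10^p[3], hill_slope = p[4],
             rss = best_rss, converged = converged, flat = flat, n_points = n,
             concentration = concentration, response = response, flags = flags)
}

new_tk_4pl <- function(bottom, top, ec50, hill_slope, rss, converged, flat,
                       n_points, concentration, response, flags = "") {
  structure(list(
    bottom = bottom, top = top, ec50 = ec50, hill_slope = hill_slope,
    emax = top, rss = rss, converged = converged, flat = flat,
    n_points = n_points,
    data = tibble::tibble(concentration = concentration, response = response),
    flags = flags
  ), class = "tk_4pl")
}

#' Predict from a 4PL fit
#'
#' @param object A `tk_4pl` fit.
#' @param newdata Optional tibble with a `concentration` column (> 0).
#' @param ... Unused.
#' @return Numeric vector of fitted responses.
#' @export
predict.tk_4pl <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration else newdata$concentration
  x <- log10(conc)
  le <- log10(object$ec50)
  object$bottom + (object$top - object$bottom) /
    (1 + 10^(object$hill_slope * (le - x)))
}

#' @export
print.tk_4pl <- function(x, ...) {
  cat("<tk_4pl>",
      sprintf("EC50 = %.4g M (%.4g uM), Emax = %.4g, slope = %.3g, bottom = %.4g",
              x$ec50, x$ec50 * 1e6, x$emax, x$hill_slope, x$bottom),
      sprintf("n = %d, rss = %.4g, converged = %s%s", x$n_points, x$rss,
              x$converged, if (x$flat) ", FLAT (no dose dependence)" else ""),
      sep = "\n")
  invisible(x)
}

#' @rdname tidy.tk_4pl
#' @method glance tk_4pl
#' @export
glance.tk_4pl <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, emax = x$emax, bottom = x$bottom,
                 hill_slope = x$hill_slope, rss = x$rss, n = x$n_points,
                 converged = x$converged, flat = x$flat)
}

#' Broom-style accessors for 4PL fits
#'
#' `tidy()` returns one row per parameter; `glance()` a one-row model summary.
#'
#' @param x A `tk_4pl` fit.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tk_4pl
#' @export
tidy.tk_4pl <- function(x, ...) {
  tibble::tibble(
    term = c("bottom", "top", "ec50", "hill_slope"),
    estimate = c(x$bottom, x$top, x$ec50, x$hill_slope)
  )
}

#' Fit dose-response curves for every construct, E:T ratio and readout
#'
#' Applies [extract_peak_response()] and [fit_4pl()] across a profile set.
#' Groups whose response cannot be extracted (grid not covering the peak
#' times) or fitted (< 5 doses) are reported with an `NA` fit and a message in
#' `flags` rather than dropped silently.
#'
#' @param profiles A `tk_profile` tibble from [build_profiles()].
#' @param readouts Character vector of readouts (default all four).
#' @param ... Passed to [extract_peak_response()].
#' @return A tibble with one row per (construct, et_ratio, readout): list
#'   column `fit` plus unpacked `ec50, emax, converged, flat, flags`.
#' @export
fit_dose_response <- function(profiles,
                              readouts = c("proliferation", "specific_killing",
                                           "proliferation_rate", "kill_rate"),
                              ...) {
  groups <- dplyr::distinct(profiles, .data$construct, .data$et_ratio)
  out <- tidyr::expand_grid(groups, readout = readouts)
  fits <- purrr::pmap(out, function(construct, et_ratio, readout) {
    prof <- profiles[profiles$construct == construct &
                       profiles$et_ratio == et_ratio, ]
    tryCatch({
      resp <- extract_peak_response(prof, readout = readout, ...)
      resp <- resp[is.finite(resp$response), ]
      fit_4pl(resp$concentration, resp$response)
    }, error = function(e) conditionMessage(e))
  })
  out$fit <- lapply(fits, function(f) if (inherits(f, "tk_4pl")) f else NULL)
  out$ec50 <- vapply(fits, function(f) if (inherits(f, "tk_4pl")) f$ec50 else NA_real_, 1)
  out$emax <- vapply(fits, function(f) if (inherits(f, "tk_4pl")) f$emax else NA_real_, 1)
  out$hill_slope <- vapply(fits, function(f) if (inherits(f, "tk_4pl")) f$hill_slope else NA_real_, 1)
  out$converged <- vapply(fits, function(f) if (inherits(f, "tk_4pl")) f$converged else FALSE, TRUE)
  out$flat <- vapply(fits, function(f) if (inherits(f, "tk_4pl")) f$flat else NA, TRUE)
  out$flags <- vapply(fits, function(f) if (inherits(f, "tk_4pl")) f$flags else paste0("error: ", f), "")
  out
}

#' Summary table of EC50 / Emax per construct, E:T and readout
#'
#' The long-format analogue of a per-construct parameter table: EC50 reported
#' in micromolar, Emax in the readout's units (fold increase, per T cell,
#' percent per day, per T cell per hour). Non-converged fits keep their row
#' with an empty EC50.
#'
#' @param fits Output of [fit_dose_response()].
#' @return Tibble with columns `construct, et_ratio, readout, ec50_uM, emax,
#'   hill_slope, converged, flat, flags`.
#' @export
summarize_fits <- function(fits) {
  fits |>
    dplyr::mutate(
      et_ratio = et_label(.data$et_ratio),
      ec50_uM = ifelse(.data$converged, .data$ec50 * 1e6, NA_real_),
      emax = ifelse(.data$converged, .data$emax, NA_real_)
    ) |>
    dplyr::select("construct", "et_ratio", "readout", "ec50_uM", "emax",
                  "hill_slope", "converged", "flat", "flags") |>
    tibble::as_tibble()
}

#' Band concentrations relative to a fitted EC50
#'
#' Assigns each positive dose to the High (`c >= 100 * ec50`), Mid
#' (`ec50 <= c < 100 * ec50`) or Low (`c < ec50`) band. Both boundaries are
#' assigned to the higher band.
#'
#' @param ec50 Fitted EC50 (molar, > 0) from a converged fit.
#' @param concentrations Positive molar doses.
#' @return Tibble with `concentration` and `band` (ordered factor Low < Mid <
#'   High).
#' @examples
#' band_concentrations(5e-8, c(1e-9, 5e-8, 1e-4))
#' @export
band_concentrations <- function(ec50, concentrations) {
  if (!is.finite(ec50) || ec50 <= 0) {
    abort_bad_arg("banding requires a converged fit with finite ec50 > 0.")
  }
  if (any(concentrations <= 0)) abort_bad_arg("banding applies to positive doses only.")
  band <- ifelse(concentrations >= 100 * ec50, "High",
                 ifelse(concentrations >= ec50, "Mid", "Low"))
  tibble::tibble(
    concentration = concentrations,
    band = factor(band, levels = c("Low", "Mid", "High"), ordered = TRUE)
  )
}
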