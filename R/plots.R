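#' Plot kinetic profiles
#'
#' Time courses of a chosen kinetic quantity, one line per concentration,
#' faceted by construct and E:T ratio. Dose is colored on a log scale with the
#' 0 M control drawn in grey.
#'
#' @param object A `tk_profile` tibble from [build_profiles()].
#' @param quantity Column to plot (default `"k_specific"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tk_profile
#' @export
autoplot.tk_profile <- function(object, quantity = "k_specific", ...) {
  if (!quantity %in% names(object)) {
    abort_bad_arg(sprintf("unknown profile quantity `%s`.", quantity))
  }
  df <- dplyr::mutate(tibble::as_tibble(object),
                      et = et_label(.data$et_ratio),
                      dose_uM = .data$concentration * 1e6)
  ctrl <- dplyr::filter(df, .data$concentration == 0)
  dosed <- dplyr::filter(df, .data$concentration > 0)
  ggplot2::ggplot(dosed, ggplot2::aes(x = .data$time_h, y = .data[[quantity]],
                                      group = .data$dose_uM,
                                      colour = .data$dose_uM)) +
    ggplot2::geom_line(data = ctrl, colour = "grey55", linewidth = 0.4) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c(trans = "log10", name = "peptide (uM)") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$construct),
                        cols = ggplot2::vars(.data$et)) +
    ggplot2::labs(x = "time (h)", y = quantity) +
    ggplot2::theme_bw()
}

#' Plot a 4PL dose-response fit
#'
#' Observed responses and the fitted curve on a log-dose axis, with the EC50
#' marked.
#'
#' @param object A `tk_4pl` fit.
#' @param n_curve Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tk_4pl
#' @export
autoplot.tk_4pl <- function(object, n_curve = 200, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration,
                                       y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "peptide (M)", y = "response") +
    ggplot2::theme_bw()
  if (isTRUE(object$converged) && is.finite(object$ec50)) {
    grid <- tibble::tibble(concentration = 10^seq(log10(min(d$concentration)),
                                                  log10(max(d$concentration)),
                                                  length.out = n_curve))
    grid$response <- predict(object, grid)
    p <- p +
      ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$ec50, linetype = 2,
                          colour = "grey40")
  }
  p
}

#' Dose-response overview across constructs and E:T ratios
#'
#' Peak responses and fitted curves for one readout, faceted by construct,
#' colored by E:T ratio.
#'
#' @param fits Output of [fit_dose_response()].
#' @param readout Readout to display.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(fits, readout = "specific_killing") {
  sub <- dplyr::filter(fits, .data$readout == !!readout, !is.na(.data$ec50))
  if (nrow(sub) == 0) abort_bad_arg("no fitted groups for this readout.")
  pts <- purrr::pmap_dfr(sub, function(construct, et_ratio, fit, ...) {
    dplyr::mutate(fit$data, construct = construct, et = et_label(et_ratio))
  })
  curves <- purrr::pmap_dfr(sub, function(construct, et_ratio, fit, ...) {
    grid <- tibble::tibble(concentration = 10^seq(
      log10(min(fit$data$concentration)), log10(max(fit$data$concentration)),
      length.out = 150))
    grid$response <- predict(fit, grid)
    dplyr::mutate(grid, construct = construct, et = et_label(et_ratio))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$concentration,
                                    y = .data$response, colour = .data$et)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = curves) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$construct), scales = "free_y") +
    ggplot2::labs(x = "peptide (M)", y = readout, colour = "E:T") +
    ggplot2::theme_bw()
}
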