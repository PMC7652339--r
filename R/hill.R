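#' Hill activation fraction
#'
#' Fractional receptor response at ligand concentration `c` for a Hill
#' (log-logistic) activation curve: `c^slope / (c^slope + ec50^slope)`.
#' This is the generative counterpart of the sigmoid dose-response curves the
#' analysis fits: 0 at zero dose, 0.5 at `ec50`, approaching 1 at saturation.
#'
#' @param c Ligand (peptide) concentration, molar. Vectorised; must be >= 0.
#' @param ec50 Half-maximal concentration, molar (> 0).
#' @param slope Hill coefficient (> 0).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' hill_response(0, 5e-8, 1)            # 0
#' hill_response(5e-8, 5e-8, 1)         # 0.5
#' hill_response(5e-7, 5e-8, 1)         # 10/11
#' @export
hill_response <- function(c, ec50, slope) {
  assert_scalar_num(ec50, "ec50")
  assert_scalar_num(slope, "slope")
  if (ec50 <= 0) abort_bad_arg("`ec50` must be > 0.")
  if (slope <= 0) abort_bad_arg("`slope` must be > 0.")
  if (!is.numeric(c) || any(!is.finite(c))) abort_bad_arg("`c` must be finite numeric.")
  if (any(c < 0)) abort_bad_arg("`c` must be >= 0.")
  # compute on the log scale to dodge overflow for extreme c/ec50 ratios
  out <- numeric(length(c))
  pos <- c > 0
  lr <- slope * (log(c[pos]) - log(ec50))
  out[pos] <- 1 / (1 + exp(-lr))
  out
}
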