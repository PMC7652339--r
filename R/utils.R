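# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_bad_arg <- function(msg) stop(msg, call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort_bad_arg(sprintf("`%s` must be in [%s, %s], got %s.",
                          name, format(lower), format(upper), format(x)))
  }
  invisible(x)
}

#' Format an effector:target ratio as the conventional string
#'
#' Ratios at or above one are printed as `"3:1"`; ratios below one as `"1:3"`.
#'
#' @param et_ratio Numeric vector of effector:target ratios (> 0).
#' @return Character vector like `"3:1"`, `"1:1"`, `"1:3"`.
#' @examples
#' et_label(c(3, 1, 1/3))
#' @export
et_label <- function(et_ratio) {
  if (any(!is.finite(et_ratio)) || any(et_ratio <= 0)) {
    abort_bad_arg("`et_ratio` must be positive and finite.")
  }
  vapply(et_ratio, function(r) {
    if (r >= 1) paste0(format(round(r, 2)), ":1") else paste0("1:", format(round(1 / r, 2)))
  }, character(1))
}

# paste flags together, dropping empties
join_flags <- function(...) {
  parts <- c(...)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) "" else paste(unique(parts), collapse = ";")
}

# vectorised flag union for two equal-length character vectors
combine_flag_cols <- function(a, b) {
  mapply(function(x, y) join_flags(c(x, y)), a, b, USE.NAMES = FALSE)
}

# deterministic sub-seed derivation: one call site so simulate_plate and the
# pipeline agree; returns `n` integers < 2^31 reproducibly from `seed`
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}
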