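#' Build a plate map
#'
#' Lays out a full-factorial design (construct x E:T ratio x concentration x
#' replicate) onto plate wells row-major (A1, A2, ...). Every (construct, E:T)
#' group must include the 0-concentration control that the specific-killing
#' normalization requires; [plate_map()] enforces this by requiring 0 in
#' `concentrations`.
#'
#' @param constructs Character vector of receptor construct labels.
#' @param et_ratios Numeric effector:target ratios (> 0).
#' @param concentrations Molar doses, must include 0.
#' @param replicates Number of replicate wells per condition (default 2).
#' @param plate_format 96, 384 (default) or 1536 wells.
#' @return A tibble with columns `well_id, construct, et_ratio, concentration,
#'   replicate`, validated by [validate_plate_map()].
#' @examples
#' plate_map(et_ratios = c(3, 1), concentrations = c(0, 1e-8, 1e-6), replicates = 1)
#' @export
plate_map <- function(constructs = "construct",
                      et_ratios = c(3, 1, 1 / 3),
                      concentrations = default_titration(),
                      replicates = 2,
                      plate_format = 384) {
  if (!0 %in% concentrations) {
    abort_bad_arg("`concentrations` must include the 0 M control.")
  }
  design <- tidyr::expand_grid(
    construct = constructs,
    et_ratio = et_ratios,
    concentration = sort(unique(concentrations)),
    replicate = seq_len(replicates)
  )
  ids <- well_ids(plate_format)
  if (nrow(design) > length(ids)) {
    abort_bad_arg(sprintf("design needs %d wells but a %d-well plate has %d.",
                          nrow(design), plate_format, length(ids)))
  }
  design$well_id <- ids[seq_len(nrow(design))]
  validate_plate_map(dplyr::select(design, "well_id", "construct", "et_ratio",
                                   "concentration", "replicate"))
}

plate_dims <- function(plate_format) {
  switch(as.character(plate_format),
         "96" = c(8L, 12L), "384" = c(16L, 24L), "1536" = c(32L, 48L),
         abort_bad_arg("`plate_format` must be 96, 384 or 1536."))
}

well_ids <- function(plate_format = 384) {
  d <- plate_dims(plate_format)
  rows <- if (d[1] <= 26) LETTERS[seq_len(d[1])] else {
    c(LETTERS, paste0("A", LETTERS))[seq_len(d[1])]
  }
  as.vector(t(outer(rows, seq_len(d[2]), paste0)))
}

#' Validate a plate map
#'
#' Checks well-id uniqueness and format validity, non-negative concentrations,
#' positive E:T ratios, and that every (construct, E:T) group has a 0 M control.
#' All violations are collected and reported together.
#'
#' @param plate A data frame with columns `well_id, construct, et_ratio,
#'   concentration, replicate`.
#' @param plate_format Plate format used to validate well ids (default 384).
#' @param lines Optional integer vector of source line numbers (used by
#'   [read_plate_map()] for error messages).
#' @return The plate map as a tibble, invisibly validated.
#' @export
validate_plate_map <- function(plate, plate_format = 384, lines = NULL) {
  plate <- tibble::as_tibble(plate)
  needed <- c("well_id", "construct", "et_ratio", "concentration", "replicate")
  missing_cols <- setdiff(needed, names(plate))
  if (length(missing_cols)) {
    abort_bad_arg(paste0("plate map lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (is.null(lines)) lines <- seq_len(nrow(plate))
  errs <- character()

  dup <- plate$well_id[duplicated(plate$well_id)]
  for (w in unique(dup)) {
    at <- lines[plate$well_id == w]
    errs <- c(errs, sprintf("duplicate well_id %s (lines %s)", w,
                            paste(at, collapse = ", ")))
  }
  valid_ids <- well_ids(plate_format)
  bad_id <- !plate$well_id %in% valid_ids
  if (any(bad_id)) {
    errs <- c(errs, sprintf("invalid well_id for %d-well plate: %s", plate_format,
                            paste(sprintf("%s (line %d)", plate$well_id[bad_id],
                                          lines[bad_id]), collapse = ", ")))
  }
  bad_conc <- !is.finite(plate$concentration) | plate$concentration < 0
  if (any(bad_conc)) {
    errs <- c(errs, sprintf("malformed concentration at lines %s",
                            paste(lines[bad_conc], collapse = ", ")))
  }
  bad_et <- !is.finite(plate$et_ratio) | plate$et_ratio <= 0
  if (any(bad_et)) {
    errs <- c(errs, sprintf("non-positive E:T ratio at lines %s",
                            paste(lines[bad_et], collapse = ", ")))
  }
  if (!any(c(bad_conc, bad_et))) {
    ctrl <- dplyr::summarise(
      dplyr::group_by(plate, .data$construct, .data$et_ratio),
      has_control = any(.data$concentration == 0), .groups = "drop")
    no_ctrl <- ctrl[!ctrl$has_control, ]
    if (nrow(no_ctrl)) {
      errs <- c(errs, sprintf(
        "missing 0 M control for group(s): %s",
        paste(sprintf("%s / %s", no_ctrl$construct, et_label(no_ctrl$et_ratio)),
              collapse = "; ")))
    }
  }
  if (length(errs)) {
    abort_bad_arg(paste0("invalid plate map:\n  - ", paste(errs, collapse = "\n  - ")))
  }
  plate
}

#' Read a plate map from CSV
#'
#' Expects columns `well_id, construct, et_ratio, concentration, replicate`.
#' `et_ratio` may be numeric or a ratio string like `"3:1"`; `concentration`
#' is molar. Schema violations are fatal and reported with CSV line numbers.
#'
#' @param path CSV file path.
#' @param plate_format Plate format for well-id validation (default 384).
#' @return A validated plate-map tibble.
#' @export
read_plate_map <- function(path, plate_format = 384) {
  if (!file.exists(path)) abort_bad_arg(sprintf("plate map not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  if ("et_ratio" %in% names(raw) && is.character(raw$et_ratio)) {
    raw$et_ratio <- parse_et_ratio(raw$et_ratio)
  }
  if ("concentration" %in% names(raw)) {
    raw$concentration <- suppressWarnings(as.numeric(raw$concentration))
  }
  validate_plate_map(raw, plate_format = plate_format, lines = lines)
}

parse_et_ratio <- function(x) {
  vapply(x, function(s) {
    if (grepl(":", s, fixed = TRUE)) {
      parts <- suppressWarnings(as.numeric(strsplit(s, ":", fixed = TRUE)[[1]]))
      if (length(parts) == 2 && all(is.finite(parts)) && parts[2] > 0) {
        parts[1] / parts[2]
      } else NA_real_
    } else suppressWarnings(as.numeric(s))
  }, numeric(1), USE.NAMES = FALSE)
}
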