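# Long-format measurement tables: one row per wound-area measurement with
# columns patient_id, arm, day, area_cm2, method. This is the unit of
# analysis throughout the package.

mt_required_cols <- c("patient_id", "arm", "day", "area_cm2", "method")

#' Validate a long-format wound-measurement table
#'
#' Checks the canonical schema (`patient_id`, `arm`, `day`, `area_cm2`,
#' `method`), enforces that each patient belongs to exactly one arm, that
#' arms are coded 0/1 and days are non-negative, and applies the zero-area
#' policy: a lognormal likelihood cannot absorb an observed area of zero, so
#' such rows are either dropped with a warning (default) or flagged as
#' left-censored at `censor_limit` for a censored likelihood contribution.
#'
#' @param data A data frame in the canonical schema.
#' @param zero_policy `"drop"` (default) removes rows with `area_cm2 <= 0`
#'   and warns with the count; `"censor"` keeps them, sets a logical
#'   `censored` column and replaces the area by `censor_limit`.
#' @param censor_limit Detection limit in cm² used by the `"censor"` policy.
#' @return A validated tibble (with a `censored` column when applicable).
#' @export
as_measurement_table <- function(data, zero_policy = c("drop", "censor"),
                                 censor_limit = 0.25) {
  zero_policy <- match.arg(zero_policy)
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  missing_cols <- setdiff(mt_required_cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(data)
  out$arm <- as.integer(out$arm)
  out$day <- as.numeric(out$day)
  out$area_cm2 <- as.numeric(out$area_cm2)
  out$method <- as.character(out$method)
  if (nrow(out) == 0L) abort("measurement table is empty")
  if (anyNA(out[mt_required_cols])) abort("missing values in required columns")
  if (!all(out$arm %in% c(0L, 1L))) abort("`arm` must be coded 0 (control) or 1 (treatment)")
  if (any(out$day < 0)) abort("`day` must be non-negative")
  arms_per_patient <- tapply(out$arm, out$patient_id, function(a) length(unique(a)))
  if (any(arms_per_patient > 1L)) {
    bad <- names(arms_per_patient)[arms_per_patient > 1L]
    abort(paste0("patient(s) appear in both arms: ", paste(bad, collapse = ", ")))
  }
  nonpos <- which(out$area_cm2 <= 0)
  if (length(nonpos)) {
    if (zero_policy == "drop") {
      warn(sprintf("dropping %d row(s) with area <= 0 cm2 (lognormal likelihood)",
                   length(nonpos)))
      out <- out[-nonpos, , drop = FALSE]
      if (nrow(out) == 0L) abort("no rows left after dropping non-positive areas")
    } else {
      inform(sprintf("flagging %d row(s) with area <= 0 cm2 as left-censored at %g cm2",
                     length(nonpos), censor_limit))
      out$censored <- FALSE
      out$censored[nonpos] <- TRUE
      out$area_cm2[nonpos] <- censor_limit
    }
  }
  out
}

#' Read a measurement table from CSV
#'
#' Reads the canonical CSV schema (`patient_id,arm,day,area_cm2,method`),
#' optionally filters to one measurement method, validates via
#' [as_measurement_table()] and logs a short summary.
#'
#' @param path Path to a CSV file.
#' @param method Optional method label to filter to (the model is fitted to
#'   one measurement method at a time).
#' @inheritParams as_measurement_table
#' @return A validated measurement tibble.
#' @export
load_measurements <- function(path, method = NULL,
                              zero_policy = c("drop", "censor"),
                              censor_limit = 0.25) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(method)) {
    raw <- raw[raw$method %in% method, , drop = FALSE]
    if (nrow(raw) == 0L) abort(sprintf("no rows for method '%s'", method))
  }
  out <- as_measurement_table(raw, zero_policy = zero_policy,
                              censor_limit = censor_limit)
  inform(sprintf(
    "loaded %d measurements: %d patients, %d method(s), days %g-%g",
    nrow(out), length(unique(out$patient_id)),
    length(unique(out$method)), min(out$day), max(out$day)
  ))
  out
}

#' Write a measurement table to CSV
#'
#' @param data A measurement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  readr::write_csv(data[, intersect(c(mt_required_cols, "censored"), names(data))],
                   path)
  invisible(path)
}
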