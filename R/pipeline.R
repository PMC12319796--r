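#' Add model OEF estimates to a per-region table
#'
#' Applies the transit-time OEF model row by row to a delimited-style table
#' with columns `subject_id`, `roi`, `mtt_s`, `cth_s`, adding an `oef_mri`
#' column. This is the estimation step only; the constants (notably `PtO2`
#' and `k`) are used as given.
#'
#' @param df data frame (or path to a CSV file) with the columns above.
#' @param constants an [oef_constants()] object.
#' @return The table with an `oef_mri` column appended.
#' @export
estimate_table <- function(df, constants = oef_constants()) {
  if (is.character(df)) df <- utils::read.csv(df, stringsAsFactors = FALSE)
  .check_table(df, c("subject_id", "roi", "mtt_s", "cth_s"))
  df$oef_mri <- oef(df$mtt_s, df$cth_s, constants)
  df
}

#' Run the full calibrate--estimate--compare pipeline
#'
#' Orchestrates the whole analysis on a per-subject, per-region table:
#' calibrates `(PtO2, k)` against PET OEF in the calibration region, predicts
#' the model OEF for every row, and computes per-region agreement (Pearson
#' correlation and Bland--Altman) between model and PET OEF. When the table
#' has no `oef_pet` column the pipeline runs in estimation-only mode and
#' skips calibration and agreement.
#'
#' With `out_dir` set, writes `calibration.json`, `subjects.csv` (input plus
#' `oef_mri`) and `agreement.json`; numeric columns are written with 17
#' significant digits so that re-reading the table and recomputing the
#' agreement reproduces the report exactly. A short log of constants and
#' exclusions goes to the message stream.
#'
#' @param roi_table data frame or path to a CSV file with columns
#'   `subject_id`, `roi`, `mtt_s`, `cth_s` and optionally `oef_pet`.
#' @param out_dir optional output directory (created if needed).
#' @param constants an [oef_constants()] object (Hill constants; also `PtO2`
#'   and `k` in estimation-only mode).
#' @param target_max_oef OEF ceiling fixing `PtO2` during calibration.
#' @param roi_calibrate calibration region.
#' @return Invisibly, a list with `fit` (the [oefcal()] object), `subjects`
#'   (table with `oef_mri`), `calibration`, `agreement`, and `files` (paths
#'   written, or `NULL`).
#' @export
run_pipeline <- function(roi_table, out_dir = NULL,
                         constants = oef_constants(),
                         target_max_oef = 0.6, roi_calibrate = "NAWM") {
  if (is.character(roi_table)) {
    if (!file.exists(roi_table))
      stop("input table not found: ", roi_table, call. = FALSE)
    roi_table <- utils::read.csv(roi_table, stringsAsFactors = FALSE)
  }
  .check_table(roi_table, c("subject_id", "roi", "mtt_s", "cth_s"))
  has_pet <- "oef_pet" %in% names(roi_table)
  message("capox pipeline: ", length(unique(roi_table$subject_id)),
          " subject(s), regions ",
          paste(unique(roi_table$roi), collapse = ", "),
          if (has_pet) "" else " (estimation-only mode)")
  fit <- oefcal(roi_table, roi_calibrate = roi_calibrate,
                target_max_oef = target_max_oef, constants = constants)
  message(sprintf("constants: PtO2 = %.4f mmHg, k = %.2f 1/s",
                  fit$constants$PtO2, fit$constants$k))
  if (!is.null(fit$calibration) && nrow(fit$calibration$excluded) > 0)
    message("excluded ", nrow(fit$calibration$excluded), " subject(s): ",
            paste(fit$calibration$excluded$reason, collapse = "; "))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(subjects = file.path(out_dir, "subjects.csv"))
    .write_table_full(fit$data, files$subjects)
    if (!is.null(fit$calibration)) {
      files$calibration <- file.path(out_dir, "calibration.json")
      cal <- fit$calibration
      jsonlite::write_json(
        list(pto2_mmHg = cal$pto2,
             target_max_oef = cal$target_max_oef,
             roi = cal$roi,
             k_per_subject = cal$k,
             k_mean = cal$k_mean, k_median = cal$k_median,
             k_range = cal$k_range,
             excluded = cal$excluded),
        files$calibration, auto_unbox = TRUE, digits = NA)
    }
    if (length(fit$agreement)) {
      files$agreement <- file.path(out_dir, "agreement.json")
      jsonlite::write_json(
        lapply(fit$agreement, unclass),
        files$agreement, auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(list(fit = fit, subjects = fit$data,
                 calibration = fit$calibration,
                 agreement = fit$agreement, files = files))
}

# CSV writer that round-trips doubles exactly (%.17g).
.write_table_full <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}
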