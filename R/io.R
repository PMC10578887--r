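cohort_required_cols <- c("subject_id", "abeta42", "ptau", "mfw", "psmd",
                          "adni_mem", "adni_ef", "age", "sex", "education",
                          "protocol")
cohort_optional_cols <- c("apoe4", "cdrsb", "delta_cdrsb", "hv", "ba",
                          "clinical_label")
cohort_numeric_cols <- c("abeta42", "ptau", "mfw", "psmd", "adni_mem",
                         "adni_ef", "age", "education", "apoe4", "cdrsb",
                         "delta_cdrsb", "hv", "ba")

#' Read and validate a cohort CSV
#'
#' Expects the fixed column schema: `subject_id, abeta42, ptau, mfw, psmd,
#' adni_mem, adni_ef, age, sex, education, protocol` (required) plus the
#' optional auxiliaries `apoe4, cdrsb, delta_cdrsb, hv, ba,
#' clinical_label`. Units: pg/mL for the CSF markers, mm^2/s for PSMD,
#' dimensionless fraction for mFW, standardized units for the cognition
#' composites, years for age and education. Missing values (empty cells)
#' are tolerated in any biomarker column — subjects lacking an axis input
#' are excluded from that axis downstream — but a non-numeric entry in a
#' numeric column is an error. Row count and per-column missingness are
#' logged via `message()`.
#'
#' @param path CSV file path (RFC-4180, UTF-8, "." decimal).
#' @return Cohort data frame with typed columns.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- read.csv(path, colClasses = "character", check.names = TRUE,
                  na.strings = c("", "NA"))
  missing_cols <- setdiff(cohort_required_cols, names(raw))
  if (length(missing_cols))
    stopf("missing column: %s", paste(missing_cols, collapse = ", "))
  out <- raw
  for (col in intersect(cohort_numeric_cols, names(raw))) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stopf("non-numeric value '%s' in column %s, row %d", v[bad[1]], col, bad[1])
    out[[col]] <- num
  }
  message(sprintf("read %d subjects from %s", nrow(out), path))
  nmiss <- vapply(out, function(x) sum(is.na(x)), 0L)
  for (col in names(nmiss)[nmiss > 0])
    message(sprintf("  column %s: %d missing", col, nmiss[[col]]))
  out
}

#' Write a cohort table to CSV
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces the values exactly.
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA, fmt_num(out[[col]]))
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
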