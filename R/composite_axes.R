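#' Linear composite axis definition
#'
#' A composite axis is a named linear rule on (optionally log-transformed)
#' biomarkers: `raw = sum_i coef_i * t_i(x_i) + intercept`, together with a
#' cutoff `cth` on the raw scale. Scores above `cth` are disease-positive
#' (or cognitively low, for the cognition axis). Feature transforms are part
#' of the axis definition so callers always supply biomarkers in their
#' natural units (e.g. PSMD in mm^2/s), preventing silent unit errors.
#'
#' @param name axis name, e.g. `"VDF"`.
#' @param features data frame with columns `field` (column name in a cohort
#'   table), `transform` (`"identity"` or `"log10"`), and `scale` (the value
#'   is multiplied by `scale` before `log10`; ignored for identity).
#' @param coefficients numeric vector, one per feature row.
#' @param intercept numeric scalar added to the weighted sum.
#' @param cth cutoff on the raw scale separating factor-negative from
#'   factor-positive.
#' @param derivation provenance tag: `"published"`, `"lda"` or `"user"`.
#' @return An object of class `composite_axis`.
#' @export
composite_axis <- function(name, features, coefficients, intercept, cth,
                           derivation = "user") {
  stopifnot(is.character(name), length(name) == 1L)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!all(c("field", "transform", "scale") %in% names(features)))
    stopf("features must have columns field, transform, scale")
  if (!all(features$transform %in% c("identity", "log10")))
    stopf("unknown transform: %s",
          paste(setdiff(features$transform, c("identity", "log10")), collapse = ", "))
  if (length(coefficients) != nrow(features))
    stopf("need one coefficient per feature (%d features, %d coefficients)",
          nrow(features), length(coefficients))
  structure(
    list(name = name, features = features,
         coefficients = as.numeric(coefficients),
         intercept = as.numeric(intercept), cth = as.numeric(cth),
         derivation = derivation),
    class = "composite_axis")
}

#' @export
print.composite_axis <- function(x, ...) {
  cat(sprintf("<composite_axis> %s (%s)\n", x$name, x$derivation))
  for (i in seq_len(nrow(x$features))) {
    f <- x$features[i, ]
    term <- if (f$transform == "log10")
      sprintf("log10(%s * %s)", f$field, format(f$scale)) else f$field
    cat(sprintf("  %+g * %s\n", x$coefficients[i], term))
  }
  cat(sprintf("  %+g (intercept); cth = %g\n", x$intercept, x$cth))
  invisible(x)
}

# Apply the axis's feature transforms to a cohort table; returns an n x p
# matrix. Non-positive values under a log10 transform are a domain error;
# NA propagates (ragged tables are handled upstream by per-axis exclusion).
transform_features <- function(axis, data) {
  out <- matrix(NA_real_, nrow = nrow(data), ncol = nrow(axis$features))
  for (i in seq_len(nrow(axis$features))) {
    f <- axis$features[i, ]
    if (!f$field %in% names(data))
      stopf("axis %s needs column '%s'", axis$name, f$field)
    v <- as.numeric(data[[f$field]])
    if (f$transform == "log10") {
      bad <- which(!is.na(v) & v <= 0)
      if (length(bad))
        stopf("axis %s: non-positive value in '%s' (row %d): log10 undefined",
              axis$name, f$field, bad[1])
      v <- log10(v * f$scale)
    }
    out[, i] <- v
  }
  out
}

#' Evaluate a composite axis on a cohort table
#'
#' @param axis a [composite_axis()].
#' @param data data frame containing the axis's input columns.
#' @return Numeric vector of raw scores (NA where any input is missing).
#' @export
compute_raw_score <- function(axis, data) {
  X <- transform_features(axis, data)
  drop(X %*% axis$coefficients) + axis$intercept
}

#' Published trichotomy axis presets
#'
#' The fixed composite-axis definitions of the trichotomy framework
#' (the `"adni2023"` set), shipped as immutable presets:
#' \describe{
#'   \item{VDF}{`0.135*log10(PSMD*1e4) + 0.991*log10(mFW*1e2) - 1.474`,
#'     cutoff 0; derived by two-class LDA separating controls from
#'     subcortical ischemic vascular disease in an enriched clinical cohort.}
#'   \item{Cog}{`-0.076*ADNI_EF - 0.997*ADNI_MEM + 0.519`, cutoff 0; derived
#'     by LDA separating cognitively normal subjects from those with
#'     impairment. Larger values mean worse cognition.}
#'   \item{ADF}{`log10(pTau/Abeta42)`, cutoff `log10(0.022)` (-1.66 to two
#'     decimals), from an independent CSF-vs-amyloid-PET calibration study.}
#' }
#' The two LDA-derived coefficient vectors have unit Euclidean norm, which
#' makes a cutoff of 0 a geometric distance from the decision boundary.
#'
#' @param set preset set name; only `"adni2023"` is defined.
#' @return Named list of [composite_axis()] objects (`adf`, `vdf`, `cog`).
#' @export
trichotomy_axes <- function(set = "adni2023") {
  if (!identical(set, "adni2023")) stopf("unknown preset set '%s'", set)
  list(
    adf = composite_axis(
      "ADF",
      data.frame(field = c("ptau", "abeta42"),
                 transform = "log10", scale = 1),
      coefficients = c(1, -1), intercept = 0,
      cth = log10(0.022), derivation = "published"),
    vdf = composite_axis(
      "VDF",
      data.frame(field = c("psmd", "mfw"),
                 transform = "log10", scale = c(1e4, 1e2)),
      coefficients = c(0.135, 0.991), intercept = -1.474,
      cth = 0, derivation = "published"),
    cog = composite_axis(
      "Cog",
      data.frame(field = c("adni_ef", "adni_mem"),
                 transform = "identity", scale = 1),
      coefficients = c(-0.076, -0.997), intercept = 0.519,
      cth = 0, derivation = "published"))
}

#' Raw vascular disease factor
#'
#' `VDFraw = 0.135*log10(PSMD*1e4) + 0.991*log10(mFW*1e2) - 1.474`; the
#' cutoff on this scale is 0. Increasing in both white-matter injury markers.
#'
#' @param mfw mean free water fraction in white matter (0 < mfw < 1).
#' @param psmd peak width of skeletonized mean diffusivity, mm^2/s.
#' @return Raw VDF score(s).
#' @export
compute_vdf_raw <- function(mfw, psmd) {
  if (any(!is.na(mfw) & mfw <= 0) || any(!is.na(psmd) & psmd <= 0))
    stopf("mfw and psmd must be positive (log10 undefined otherwise)")
  0.135 * log10(psmd * 1e4) + 0.991 * log10(mfw * 1e2) - 1.474
}

#' Raw cognition composite
#'
#' `Cograw = -0.076*ADNI_EF - 0.997*ADNI_MEM + 0.519`; cutoff 0. Larger
#' values mean worse cognition (the score is dominated by memory).
#'
#' @param adni_mem standardized composite memory score.
#' @param adni_ef standardized composite executive-function score.
#' @return Raw cognition score(s).
#' @export
compute_cog_raw <- function(adni_mem, adni_ef) {
  if (missing(adni_mem) || missing(adni_ef))
    stopf("both adni_mem and adni_ef are required")
  -0.076 * adni_ef - 0.997 * adni_mem + 0.519
}

#' Raw Alzheimer's disease factor
#'
#' `ADFraw = log10(pTau/Abeta42)`. The cutoff is `log10(0.022)`: a
#' pTau/Abeta42 ratio of 0.022 best matched amyloid-PET positivity in the
#' calibration study this constant comes from.
#'
#' @param abeta42 CSF amyloid-beta 1-42 concentration, pg/mL.
#' @param ptau CSF phosphorylated tau concentration, pg/mL.
#' @return Raw ADF score(s).
#' @export
compute_adf_raw <- function(abeta42, ptau) {
  if (any(!is.na(abeta42) & abeta42 <= 0) || any(!is.na(ptau) & ptau <= 0))
    stopf("abeta42 and ptau must be positive (log10 undefined otherwise)")
  log10(ptau / abeta42)
}

#' Score a cohort on a set of composite axes
#'
#' Computes the raw score for each axis; subjects missing any input of an
#' axis get NA on that axis and a per-axis exclusion count is reported via
#' `message()`.
#'
#' @param cohort cohort data frame (see [read_cohort_csv()] for the schema).
#' @param axes named list of [composite_axis()] objects, default the
#'   published presets.
#' @return Data frame with `subject_id` and one `<axis>_raw` column per axis.
#' @export
score_cohort <- function(cohort, axes = trichotomy_axes()) {
  out <- data.frame(subject_id = cohort$subject_id %||% seq_len(nrow(cohort)))
  for (nm in names(axes)) {
    s <- compute_raw_score(axes[[nm]], cohort)
    n_miss <- sum(is.na(s))
    if (n_miss > 0)
      message(sprintf("axis %s: %d of %d subjects lack inputs and are excluded",
                      axes[[nm]]$name, n_miss, length(s)))
    out[[paste0(nm, "_raw")]] <- s
  }
  out
}

#' Write a composite axis to a plain-text config file
#'
#' One `key: value` line per scalar field plus one `feature:` line per
#' feature. Numbers are written with 17 significant digits so that
#' write/read/write reproduces the file byte-for-byte.
#'
#' @param axis a [composite_axis()].
#' @param path output file path.
#' @export
write_axis_config <- function(axis, path) {
  lines <- c(
    sprintf("name: %s", axis$name),
    sprintf("derivation: %s", axis$derivation),
    sprintf("intercept: %s", fmt_num(axis$intercept)),
    sprintf("cth: %s", fmt_num(axis$cth)),
    sprintf("feature: %s %s %s %s",
            axis$features$field, axis$features$transform,
            fmt_num(axis$features$scale), fmt_num(axis$coefficients)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a composite axis from a plain-text config file
#'
#' @param path file written by [write_axis_config()].
#' @return A [composite_axis()].
#' @export
read_axis_config <- function(path) {
  lines <- readLines(path)
  get1 <- function(key) {
    m <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (length(m) != 1L) stopf("axis config: expected one '%s' line", key)
    sub(paste0("^", key, ": "), "", m)
  }
  feat <- grep("^feature: ", lines, value = TRUE)
  if (!length(feat)) stopf("axis config: no feature lines")
  parts <- do.call(rbind, strsplit(sub("^feature: ", "", feat), " ", fixed = TRUE))
  composite_axis(
    name = get1("name"),
    features = data.frame(field = parts[, 1], transform = parts[, 2],
                          scale = as.numeric(parts[, 3])),
    coefficients = as.numeric(parts[, 4]),
    intercept = as.numeric(get1("intercept")),
    cth = as.numeric(get1("cth")),
    derivation = get1("derivation"))
}
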