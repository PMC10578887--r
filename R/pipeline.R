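#' Pipeline configuration
#'
#' Bundles every choice the scoring pipeline makes: which axes to use
#' (the published presets by name, or user-fitted [composite_axis()]
#' objects), where the normalization tables come from (the cohort itself,
#' or pre-fitted tables), the positivity threshold, the covariate list for
#' the optional statistics battery, and output paths.
#'
#' @param axes `"adni2023"` or a named list of [composite_axis()] objects
#'   with names `adf`, `vdf`, `cog`.
#' @param calibration NULL to calibrate the normalization on the input
#'   cohort, a cohort data frame to calibrate on, or a named list of
#'   `unt_table` objects to reuse frozen tables.
#' @param threshold positivity threshold on the normalized scale, in
#'   (0, 1).
#' @param covariates covariate column names for the statistics battery.
#' @param run_stats also run the Bonferroni-corrected group-pair battery.
#' @param output_dir optional directory for CSV/text artifacts.
#' @param seed recorded in output metadata (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(axes = "adni2023", calibration = NULL,
                            threshold = 0.5,
                            covariates = c("age", "sex", "education",
                                           "protocol"),
                            run_stats = FALSE, output_dir = NULL,
                            seed = NULL) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0,1)")
  structure(list(axes = axes, calibration = calibration,
                 threshold = threshold, covariates = covariates,
                 run_stats = run_stats, output_dir = output_dir,
                 seed = seed),
            class = "pipeline_config")
}

resolve_axes <- function(axes) {
  if (is.character(axes)) return(trichotomy_axes(axes))
  if (!is.list(axes) || !all(c("adf", "vdf", "cog") %in% names(axes)))
    stopf("axes must be a preset name or a named list with adf, vdf, cog")
  for (a in axes[c("adf", "vdf", "cog")])
    if (!inherits(a, "composite_axis")) stopf("axes entries must be composite_axis")
  axes
}

#' Run the full trichotomy pipeline on a cohort
#'
#' Score (raw composites) -> normalize (cutoff-anchored UNT per axis) ->
#' classify (eight subgroups) -> report (prevalence, clinical cross-tab,
#' optional statistics battery). Subjects missing any axis input are
#' carried through with NA scores and no label. The pipeline is a pure
#' function of (cohort, config): repeated runs produce byte-identical
#' outputs.
#'
#' @param cohort cohort data frame (see [read_cohort_csv()]).
#' @param config a [pipeline_config()].
#' @return List of class `trichotomy_result`: `scored` (per-subject raw
#'   and normalized scores plus `label`), `unt` (the three `unt_table`s),
#'   `prevalence`, `crosstab` (when `clinical_label` is present), `stats`
#'   (when requested), `axes`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  axes <- resolve_axes(config$axes)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", name, conditionMessage(e)))
  }

  scored <- step("score", score_cohort(cohort, axes))

  unt <- config$calibration
  if (is.null(unt) || is.data.frame(unt)) {
    calib <- if (is.data.frame(unt))
      step("calibrate", score_cohort(unt, axes)) else scored
    unt <- lapply(names(axes), function(nm)
      step("calibrate",
           fit_unt(calib[[paste0(nm, "_raw")]], axes[[nm]]$cth,
                   name = axes[[nm]]$name)))
    names(unt) <- names(axes)
  } else {
    for (t in unt) if (!inherits(t, "unt_table"))
      stopf("[calibrate] calibration list must contain unt_table objects")
  }

  for (nm in names(axes))
    scored[[paste0(nm, "_norm")]] <-
      step("normalize", apply_unt(unt[[nm]], scored[[paste0(nm, "_raw")]]))

  scored$label <- step("classify",
                       classify_subject(scored$cog_norm, scored$adf_norm,
                                        scored$vdf_norm,
                                        threshold = config$threshold))

  complete <- !is.na(scored$label)
  prevalence <- step("report", group_prevalence(scored$label[complete]))

  crosstab <- NULL
  if ("clinical_label" %in% names(cohort) &&
      !all(is.na(cohort$clinical_label))) {
    crosstab <- step("report",
                     crosstab_clinical(scored$label[complete],
                                       cohort$clinical_label[complete]))
  }

  stats <- NULL
  if (isTRUE(config$run_stats))
    stats <- step("stats",
                  group_pair_tests(cohort[complete, , drop = FALSE],
                                   scored$label[complete]))

  result <- structure(
    list(scored = scored, unt = unt, prevalence = prevalence,
         crosstab = crosstab, stats = stats, axes = axes, config = config),
    class = "trichotomy_result")
  if (!is.null(config$output_dir))
    write_pipeline_outputs(result, config$output_dir)
  result
}

write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scored <- result$scored
  num <- vapply(scored, is.numeric, TRUE)
  scored[num] <- lapply(scored[num], fmt_num)
  write.csv(scored, file.path(dir, "scored.csv"), row.names = FALSE, na = "")
  for (nm in names(result$unt))
    write_unt_table(result$unt[[nm]],
                    file.path(dir, sprintf("unt_%s.txt", nm)))
  write.csv(result$prevalence, file.path(dir, "prevalence.csv"),
            row.names = FALSE)
  if (!is.null(result$crosstab))
    write.csv(as.data.frame.matrix(result$crosstab),
              file.path(dir, "crosstab.csv"))
  if (!is.null(result$stats))
    write.csv(result$stats, file.path(dir, "group_tests.csv"),
              row.names = FALSE)
  meta <- c(sprintf("threshold: %s", fmt_num(result$config$threshold)),
            sprintf("seed: %s", result$config$seed %||% "none"),
            sprintf("axes: %s", paste(vapply(result$axes, `[[`, "", "name"),
                                      collapse = ", ")))
  writeLines(meta, file.path(dir, "run_metadata.txt"))
  invisible(dir)
}

#' @export
print.trichotomy_result <- function(x, ...) {
  n <- nrow(x$scored)
  n_lab <- sum(!is.na(x$scored$label))
  cat(sprintf("<trichotomy_result> %d subjects (%d classified)\n", n, n_lab))
  print(x$prevalence)
  invisible(x)
}
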