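#' The eight trichotomy subgroup labels
#'
#' Factor levels, in reporting order, with their clinical annotations.
#' `b` stands for "biologically defined", distinguishing these groups from
#' clinical diagnoses: bMX mixed dementia, bAD Alzheimer's disease, bVD
#' vascular disease (closest to subcortical ischemic vascular disease),
#' bCL cognitively low with no disease factors, and the cognitively normal
#' counterparts bCN_MX (preclinical mixed), bCN_AD (preclinical AD),
#' bCN_VD (preclinical VD) and bCN (no factors).
#'
#' @return Character vector of the eight labels.
#' @export
trichotomy_levels <- function() {
  c("bMX", "bAD", "bVD", "bCL", "bCN_MX", "bCN_AD", "bCN_VD", "bCN")
}

#' Display annotations for the subgroup labels
#' @return Named character vector mapping label to description.
#' @export
trichotomy_annotations <- function() {
  c(bMX    = "biological mixed dementia",
    bAD    = "biological Alzheimer's disease",
    bVD    = "biological vascular disease (SIVD)",
    bCL    = "cognitively low, no AD or VD factors",
    bCN_MX = "cognitively normal with AD and VD factors (preclinical MX)",
    bCN_AD = "cognitively normal with AD factors (preclinical AD)",
    bCN_VD = "cognitively normal with VD factors (preclinical VD)",
    bCN    = "cognitively normal, no AD or VD factors")
}

# index = 1 + vdf + 2*adf + 4*cog over the (cog, adf, vdf) sign triple
subgroup_lookup <- c("bCN", "bCN_VD", "bCN_AD", "bCN_MX",
                     "bCL", "bVD", "bAD", "bMX")

#' Assign trichotomy subgroup labels from normalized scores
#'
#' An axis is positive iff its normalized score is strictly greater than
#' the threshold; a score of exactly 0.5 is negative, matching the
#' cognition dichotomy "Cog <= 0.5" vs "Cog > 0.5". The (Cog, ADF, VDF)
#' sign triple maps to the eight labels: (+,+,+) bMX, (+,+,-) bAD,
#' (+,-,+) bVD, (+,-,-) bCL, (-,+,+) bCN_MX, (-,+,-) bCN_AD,
#' (-,-,+) bCN_VD, (-,-,-) bCN.
#'
#' @param cog_norm,adf_norm,vdf_norm normalized scores, strictly in (0, 1).
#' @param threshold positivity threshold, default 0.5.
#' @return Factor with levels [trichotomy_levels()] (NA where any score is
#'   NA).
#' @export
classify_subject <- function(cog_norm, adf_norm, vdf_norm, threshold = 0.5) {
  scores <- cbind(cog_norm, adf_norm, vdf_norm)
  bad <- !is.na(scores) & (scores <= 0 | scores >= 1)
  if (any(bad))
    stopf("normalized scores must lie strictly inside (0,1); got %g",
          scores[bad][1])
  idx <- 1L + (vdf_norm > threshold) + 2L * (adf_norm > threshold) +
    4L * (cog_norm > threshold)
  factor(subgroup_lookup[idx], levels = trichotomy_levels())
}

#' Subgroup prevalence table
#'
#' Counts and percentages (rounded half-up to one decimal, the convention
#' used throughout the package's reports) for each of the eight labels.
#'
#' @param labels factor or character vector of trichotomy labels.
#' @return Data frame with columns `group`, `n`, `pct`; counts sum to the
#'   number of subjects.
#' @export
group_prevalence <- function(labels) {
  labels <- as_trichotomy_factor(labels)
  if (length(labels) == 0L) stopf("empty label vector")
  n <- table(labels)
  data.frame(group = names(n),
             n = as.integer(n),
             pct = round_half_up(100 * as.integer(n) / length(labels), 1),
             row.names = NULL)
}

as_trichotomy_factor <- function(labels) {
  if (!is.factor(labels)) labels <- factor(labels, levels = trichotomy_levels())
  if (anyNA(labels)) stopf("unknown or missing trichotomy label")
  if (!all(levels(labels) %in% trichotomy_levels()))
    stopf("unknown trichotomy label: %s",
          paste(setdiff(levels(labels), trichotomy_levels()), collapse = ", "))
  factor(labels, levels = trichotomy_levels())
}

#' Membership of a set of subgroups, optionally within a clinical stratum
#'
#' E.g. the fraction of clinically mild-cognitive-impairment subjects
#' falling in any AD-factor-positive subgroup.
#'
#' @param labels trichotomy labels per subject.
#' @param subset character vector of trichotomy labels defining the
#'   membership set.
#' @param clinical optional clinical label per subject (aCN/aMCI/aAD).
#' @param stratum optional clinical stratum to restrict to; requires
#'   `clinical`.
#' @return List with `count`, `denominator`, `pct` (one decimal, half-up).
#' @export
aggregate_membership <- function(labels, subset, clinical = NULL,
                                 stratum = NULL) {
  labels <- as_trichotomy_factor(labels)
  if (length(subset) == 0L) stopf("subset must be non-empty")
  if (!all(subset %in% trichotomy_levels()))
    stopf("unknown label in subset: %s",
          paste(setdiff(subset, trichotomy_levels()), collapse = ", "))
  keep <- rep(TRUE, length(labels))
  if (!is.null(stratum)) {
    if (is.null(clinical)) stopf("stratum given without clinical labels")
    keep <- clinical == stratum
    if (!any(keep)) stopf("empty stratum '%s'", stratum)
  }
  count <- sum(labels[keep] %in% subset)
  denom <- sum(keep)
  list(count = count, denominator = denom,
       pct = round_half_up(100 * count / denom, 1))
}

#' Cross-tabulate trichotomy subgroups against clinical diagnosis
#'
#' @param labels trichotomy labels per subject.
#' @param clinical_labels clinical diagnosis per subject; must be one of
#'   aCN, aMCI, aAD.
#' @return 8 x 3 contingency table (all levels kept, including empty ones).
#' @export
crosstab_clinical <- function(labels, clinical_labels) {
  labels <- as_trichotomy_factor(labels)
  known <- c("aCN", "aMCI", "aAD")
  if (!all(clinical_labels %in% known))
    stopf("unknown clinical category: %s",
          paste(setdiff(unique(clinical_labels), known), collapse = ", "))
  if (length(labels) != length(clinical_labels))
    stopf("labels and clinical_labels lengths differ")
  table(group = labels, clinical = factor(clinical_labels, levels = known))
}

#' Two-panel scatter of the trichotomy axes split on cognition
#'
#' ADF vs VDF normalized scores, one panel for cognitively normal
#' (Cog <= threshold) and one for cognitively low subjects, colored by
#' subgroup. Requires ggplot2.
#'
#' @param scored data frame with columns `adf_norm`, `vdf_norm`,
#'   `cog_norm`, `label`.
#' @param threshold positivity threshold, default 0.5.
#' @return A ggplot object.
#' @export
plot_trichotomy <- function(scored, threshold = 0.5) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("ggplot2 is required for plotting")
  scored$cog_side <- ifelse(scored$cog_norm > threshold,
                            "Cog > 0.5 (low cognition)",
                            "Cog <= 0.5 (normal cognition)")
  ggplot2::ggplot(scored,
                  ggplot2::aes(x = vdf_norm, y = adf_norm, colour = label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::facet_wrap(~cog_side) +
    ggplot2::labs(x = "VDF (normalized)", y = "ADF (normalized)",
                  colour = "subgroup") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("vdf_norm", "adf_norm", "label"))
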