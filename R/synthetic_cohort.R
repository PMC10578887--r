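#' Configuration for the synthetic cohort generator
#'
#' Defaults describe an ADNI-like memory-clinic research cohort: roughly
#' 40% of subjects carry the Alzheimer's latent state and 18% the vascular
#' latent state; age 71.7 (7.0) years, 48.5% male, education 16.4 (2.5)
#' years, two acquisition protocols. Biomarkers are modeled on the log10
#' scale (CSF Abeta42 around 1200 pg/mL, pTau around 21 pg/mL, mFW around
#' 0.20, PSMD around 2.2e-4 mm^2/s) with within-modality correlations
#' induced by shared latent factors; cognition composites are linear in
#' both latent disease states plus Gaussian noise, with the AD state
#' hitting memory harder than executive function and the VD state the
#' reverse.
#'
#' @param n_subjects number of subjects.
#' @param seed RNG seed used by [generate_cohort()].
#' @param prevalence_ad,prevalence_vd Bernoulli probabilities of the two
#'   latent disease states.
#' @param biomarker_params named list of `list(mean, sd)` on the modeling
#'   scale (log10 for abeta42, ptau, mfw, psmd; linear for adni_mem,
#'   adni_ef).
#' @param effect_sizes named list `list(ad = c(...), vd = c(...))`: additive
#'   shifts of each log-scale biomarker under each latent state.
#' @param cognition_coupling named list `list(ad = c(mem=, ef=),
#'   vd = c(mem=, ef=))`: shifts of the cognition composites under each
#'   latent state.
#' @param correlations within-pair residual correlations for the CSF,
#'   diffusion and cognition variable pairs.
#' @param age_slope per-year effect of (age - mean age) on both cognition
#'   composites.
#' @param covariates list with `age_mean`, `age_sd`, `p_male`, `edu_mean`,
#'   `edu_sd`, `protocols` (named probability vector).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 538, seed = 1,
                          prevalence_ad = 0.38, prevalence_vd = 0.18,
                          biomarker_params = list(
                            abeta42 = list(mean = log10(1300), sd = 0.10),
                            ptau = list(mean = log10(17), sd = 0.10),
                            mfw = list(mean = log10(0.20), sd = 0.05),
                            psmd = list(mean = log10(2.2e-4), sd = 0.08),
                            adni_mem = list(mean = 0.95, sd = 0.45),
                            adni_ef = list(mean = 0.70, sd = 0.45)),
                          effect_sizes = list(
                            ad = c(abeta42 = -0.30, ptau = 0.28),
                            vd = c(mfw = 0.19, psmd = 0.25)),
                          cognition_coupling = list(
                            ad = c(mem = -0.85, ef = -0.45),
                            vd = c(mem = -0.35, ef = -0.75)),
                          correlations = list(csf = -0.25, dti = 0.7,
                                              cog = 0.6),
                          age_slope = -0.01,
                          covariates = list(age_mean = 71.7, age_sd = 7.0,
                                            p_male = 0.485,
                                            edu_mean = 16.4, edu_sd = 2.5,
                                            protocols = c(ADNI2 = 0.5,
                                                          ADNI3 = 0.5))) {
  stopifnot(n_subjects >= 1,
            prevalence_ad >= 0, prevalence_ad <= 1,
            prevalence_vd >= 0, prevalence_vd <= 1)
  sds <- vapply(biomarker_params, `[[`, 0, "sd")
  if (any(sds <= 0)) stopf("biomarker scales must be positive")
  structure(list(n_subjects = n_subjects, seed = seed,
                 prevalence_ad = prevalence_ad, prevalence_vd = prevalence_vd,
                 biomarker_params = biomarker_params,
                 effect_sizes = effect_sizes,
                 cognition_coupling = cognition_coupling,
                 correlations = correlations, age_slope = age_slope,
                 covariates = covariates),
            class = "cohort_config")
}

# Correlated standard-normal pair via a shared factor: cor(e1, e2) = rho.
corr_pair <- function(n, rho) {
  f <- rnorm(n)
  a <- sqrt(abs(rho))
  b <- sqrt(1 - abs(rho))
  cbind(a * f + b * rnorm(n), sign(rho) * a * f + b * rnorm(n))
}

#' Generate a synthetic ADNI-like cohort with known ground truth
#'
#' Latent AD and VD disease states are drawn as independent Bernoulli
#' variables; biomarkers are drawn on the log10 scale around their
#' state-shifted locations and exponentiated; cognition composites are
#' linear in both latent states (plus an age term and correlated noise).
#' Auxiliary variables (APOE4, CDRSB, its annual change, hippocampal
#' volume, brain atrophy, clinical label) are generated conditionally on
#' the latent states and the noise-free cognition signal.
#'
#' @param config a [cohort_config()].
#' @return List with `cohort` (the standard cohort table, see
#'   [read_cohort_csv()]) and `truth` (per-subject latent states:
#'   `latent_ad`, `latent_vd`, `cognitive_impairment` — the sign of the
#'   noise-free cognition composite — and the `implied_label` the truth
#'   triple maps to).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  bp <- config$biomarker_params
  es <- config$effect_sizes
  cc <- config$cognition_coupling
  cov <- config$covariates

  ad <- rbinom(n, 1, config$prevalence_ad)
  vd <- rbinom(n, 1, config$prevalence_vd)

  age <- rnorm(n, cov$age_mean, cov$age_sd)
  sex <- ifelse(runif(n) < cov$p_male, "male", "female")
  education <- pmax(6, round(rnorm(n, cov$edu_mean, cov$edu_sd)))
  protocol <- sample(names(cov$protocols), n, replace = TRUE,
                     prob = cov$protocols)

  eff <- function(state_vec, effects, field)
    if (field %in% names(effects)) state_vec * effects[[field]] else 0

  e_csf <- corr_pair(n, config$correlations$csf)
  abeta42 <- 10^(bp$abeta42$mean + eff(ad, es$ad, "abeta42") +
                   eff(vd, es$vd, "abeta42") + bp$abeta42$sd * e_csf[, 1])
  ptau <- 10^(bp$ptau$mean + eff(ad, es$ad, "ptau") +
                eff(vd, es$vd, "ptau") + bp$ptau$sd * e_csf[, 2])

  e_dti <- corr_pair(n, config$correlations$dti)
  mfw <- 10^(bp$mfw$mean + eff(ad, es$ad, "mfw") + eff(vd, es$vd, "mfw") +
               bp$mfw$sd * e_dti[, 1])
  psmd <- 10^(bp$psmd$mean + eff(ad, es$ad, "psmd") + eff(vd, es$vd, "psmd") +
                bp$psmd$sd * e_dti[, 2])

  age_c <- age - cov$age_mean
  mem_true <- bp$adni_mem$mean + ad * cc$ad[["mem"]] + vd * cc$vd[["mem"]] +
    config$age_slope * age_c
  ef_true <- bp$adni_ef$mean + ad * cc$ad[["ef"]] + vd * cc$vd[["ef"]] +
    config$age_slope * age_c
  e_cog <- corr_pair(n, config$correlations$cog)
  adni_mem <- mem_true + bp$adni_mem$sd * e_cog[, 1]
  adni_ef <- ef_true + bp$adni_ef$sd * e_cog[, 2]

  cog_true <- compute_cog_raw(mem_true, ef_true)
  cogimp <- cog_true > 0

  apoe4 <- as.numeric(ifelse(ad == 1,
                  sample(0:2, n, replace = TRUE, prob = c(0.25, 0.50, 0.25)),
                  sample(0:2, n, replace = TRUE, prob = c(0.65, 0.30, 0.05))))
  cdrsb <- round(pmax(0, rnorm(n, 0.3 + 3 * pmax(cog_true, 0), 0.8)) * 2) / 2
  delta_cdrsb <- rnorm(n, 0.1 + 0.8 * ad * cogimp + 0.3 * cogimp, 0.4)
  hv <- rnorm(n, 7400 - 900 * ad - 300 * cogimp, 500)
  ba <- rnorm(n, 0.5 + 0.4 * ad + 0.2 * vd, 0.3)
  # clinical diagnosis tracks cognitive severity with rater noise, so
  # biomarker-positive subjects spread over aCN/aMCI/aAD as in real cohorts
  severity <- cog_true + rnorm(n, 0, 0.35)
  clinical_label <- ifelse(severity > 0.65, "aAD",
                           ifelse(severity > 0.05, "aMCI", "aCN"))

  cohort <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    abeta42 = abeta42, ptau = ptau, mfw = mfw, psmd = psmd,
    adni_mem = adni_mem, adni_ef = adni_ef,
    age = age, sex = sex, education = education, protocol = protocol,
    apoe4 = apoe4, cdrsb = cdrsb, delta_cdrsb = delta_cdrsb,
    hv = hv, ba = ba, clinical_label = clinical_label,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    subject_id = cohort$subject_id,
    latent_ad = ad == 1, latent_vd = vd == 1,
    cognitive_impairment = cogimp,
    stringsAsFactors = FALSE)
  truth$implied_label <- implied_label(truth)
  list(cohort = cohort, truth = truth)
}

# Map a latent truth triple to the subgroup it implies.
implied_label <- function(truth) {
  idx <- 1L + truth$latent_vd + 2L * truth$latent_ad +
    4L * truth$cognitive_impairment
  factor(subgroup_lookup[idx], levels = trichotomy_levels())
}

#' Two-Gaussian-class feature fixture for discriminant-recovery tests
#'
#' Draws `n_per_class` subjects per class from multivariate normals with a
#' common covariance: controls at the origin, patients at `mean_shift`.
#'
#' @param n_per_class subjects per class.
#' @param mean_shift numeric vector, the patient-class mean.
#' @param covariance positive-definite covariance matrix (default
#'   identity).
#' @param seed RNG seed.
#' @return List with `features` (matrix) and `labels` (logical, TRUE =
#'   patient).
#' @export
generate_two_group_features <- function(n_per_class, mean_shift,
                                        covariance = diag(length(mean_shift)),
                                        seed = 1) {
  p <- length(mean_shift)
  covariance <- as.matrix(covariance)
  ok <- tryCatch({chol(covariance); TRUE}, error = function(e) FALSE)
  if (!ok) stopf("covariance not positive definite")
  set.seed(seed)
  x0 <- MASS::mvrnorm(n_per_class, rep(0, p), covariance)
  x1 <- MASS::mvrnorm(n_per_class, mean_shift, covariance)
  list(features = rbind(x0, x1),
       labels = rep(c(FALSE, TRUE), each = n_per_class))
}
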