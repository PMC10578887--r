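# Strong-effect generator configuration: every axis separates its latent
# classes by >= 4 pooled SD, so end-to-end label recovery is limited only
# by pipeline correctness, not by biomarker overlap.
strong_effect_config <- function(n = 2000, seed = 42) {
  cohort_config(
    n_subjects = n, seed = seed,
    prevalence_ad = 0.40, prevalence_vd = 0.30,
    biomarker_params = list(
      abeta42 = list(mean = log10(1400), sd = 0.08),
      ptau = list(mean = log10(16), sd = 0.08),
      mfw = list(mean = log10(0.19), sd = 0.035),
      psmd = list(mean = log10(2e-4), sd = 0.05),
      adni_mem = list(mean = 1.0, sd = 0.20),
      adni_ef = list(mean = 0.8, sd = 0.20)),
    effect_sizes = list(
      ad = c(abeta42 = -0.45, ptau = 0.45),
      vd = c(mfw = 0.28, psmd = 0.35)),
    cognition_coupling = list(
      ad = c(mem = -1.5, ef = -0.8),
      vd = c(mem = -0.8, ef = -1.5)),
    age_slope = 0)
}

# Independent null-cohort fixture for family-wise-error checks: subgroup
# labels drawn independently of every auxiliary variable.
null_battery_data <- function(n = 240) {
  probs <- c(bMX = 0.09, bAD = 0.20, bVD = 0.05, bCL = 0.10,
             bCN_MX = 0.05, bCN_AD = 0.13, bCN_VD = 0.06, bCN = 0.32)
  labels <- factor(sample(names(probs), n, replace = TRUE, prob = probs),
                   levels = trichotomy_levels())
  data <- data.frame(
    sex = sample(c("male", "female"), n, replace = TRUE),
    apoe4 = sample(0:2, n, replace = TRUE, prob = c(0.5, 0.35, 0.15)),
    cdrsb = round(abs(rnorm(n, 0.8, 1.2)) * 2) / 2,
    delta_cdrsb = rnorm(n, 0.3, 0.5),
    hv = rnorm(n, 7000, 500),
    ba = rnorm(n, 0.6, 0.3))
  list(data = data, labels = labels)
}

angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, abs(ca)))) * 180 / pi
}
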