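P_FLOOR <- 1e-300  # reporting floor; avoids -Inf when p-values are logged

# Build a design matrix (intercept always included; categorical covariates
# expanded to indicators). `covariates` may be NULL, a data frame, or a
# numeric matrix.
design_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, nrow = n, dimnames = list(NULL, "(Intercept)")))
  df <- as.data.frame(covariates, stringsAsFactors = TRUE)
  if (nrow(df) != n) stopf("covariates have %d rows, expected %d", nrow(df), n)
  chr <- vapply(df, is.character, logical(1))
  df[chr] <- lapply(df[chr], factor)
  model.matrix(~ ., data = df)
}

#' Residualize a variable on a covariate set
#'
#' Ordinary least-squares residuals of `y` after regression on the
#' covariates (plus an intercept, always). Residuals have mean exactly 0
#' and are orthogonal to every covariate column. Collinear columns are
#' dropped with a warning.
#'
#' @param y numeric response.
#' @param covariates data frame or matrix of covariates (categorical
#'   columns are expanded to indicators); NULL for intercept-only.
#' @return Numeric residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stopf("y must be complete")
  X <- design_matrix(covariates, length(y))
  if (length(y) <= ncol(X)) stopf("need n > number of covariate columns + 1")
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X))
    warnf("rank-deficient design: dropping %d collinear column(s)",
          ncol(X) - fit$rank)
  as.numeric(fit$residuals)
}

#' Covariate-adjusted partial correlation between two biomarkers
#'
#' Both biomarkers are residualized on the shared covariate set; the
#' partial correlation is the Pearson correlation of the two residual
#' vectors, with a two-sided p-value from the t distribution on
#' `n - 2 - k` degrees of freedom (k = covariate columns excluding the
#' intercept, after categorical expansion). The regression slope (beta)
#' and its standard error come from the OLS fit of biomarker1 on
#' biomarker2 plus the covariates.
#'
#' @param biomarker1,biomarker2 numeric vectors.
#' @param covariates as in [residualize()].
#' @param names optional character pair naming the two biomarkers in the
#'   result.
#' @return Object of class `partial_correlation` (a list with `beta`,
#'   `se`, `r_partial`, `p`, `df`, `n` and the variable names).
#' @export
partial_correlation <- function(biomarker1, biomarker2, covariates = NULL,
                                names = c("biomarker1", "biomarker2")) {
  n <- length(biomarker1)
  if (length(biomarker2) != n) stopf("biomarker vectors have different lengths")
  r1 <- residualize(biomarker1, covariates)
  r2 <- residualize(biomarker2, covariates)
  if (sd(r1) < 1e-14 || sd(r2) < 1e-14)
    stopf("zero-variance residuals: partial correlation undefined")
  r <- cor(r1, r2)
  X <- design_matrix(covariates, n)
  k <- ncol(X) - 1L
  df <- n - 2L - k
  if (df < 1L) stopf("not enough residual degrees of freedom")
  tstat <- r * sqrt(df / max(1 - r^2, 1e-16))
  p <- max(2 * pt(-abs(tstat), df), P_FLOOR)
  # slope of biomarker1 on biomarker2, adjusting for the covariates
  d <- data.frame(X[, -1, drop = FALSE], .b2 = biomarker2, check.names = FALSE)
  fit <- lm(biomarker1 ~ ., data = d)
  beta <- unname(coef(fit)[".b2"])
  se <- sqrt(diag(vcov(fit)))[[".b2"]]
  structure(list(biomarker1 = names[1], biomarker2 = names[2],
                 covariates = colnames(X)[-1],
                 beta = beta, se = se, r_partial = r, p = p,
                 df = df, n = n),
            class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("partial correlation %s ~ %s | %s\n", x$biomarker1, x$biomarker2,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(none)"))
  cat(sprintf("  beta = %.4g (SE %.3g), r_partial = %.3f, p = %.3g (df %d)\n",
              x$beta, x$se, x$r_partial, x$p, x$df))
  invisible(x)
}

#' Compare linear models of one response by R-squared and AIC
#'
#' Fits `y ~ predictors` by OLS for each predictor set and reports
#' `R^2 = 1 - RSS/TSS` and the Gaussian-likelihood
#' `AIC = n log(RSS/n) + 2 (k + 2)` (k predictors; the +2 counts the
#' intercept and the error variance). Models are returned ranked by AIC
#' ascending, so the first row is the most parsimonious fit.
#'
#' @param y numeric response, shared across models.
#' @param predictor_sets named list; each element a data frame or matrix
#'   of predictors for one model.
#' @return Data frame with columns `model`, `k`, `r_squared`, `aic`,
#'   `delta_aic`, ordered by AIC.
#' @export
compare_models_aic <- function(y, predictor_sets) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(names(predictor_sets)))
    names(predictor_sets) <- paste0("model", seq_along(predictor_sets))
  tss <- sum((y - mean(y))^2)
  rows <- lapply(names(predictor_sets), function(nm) {
    X <- design_matrix(predictor_sets[[nm]], n)
    k <- ncol(X) - 1L
    if (n <= k + 2L) stopf("model '%s': need n > k + 2 (n=%d, k=%d)", nm, n, k)
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    data.frame(model = nm, k = k,
               r_squared = 1 - rss / tss,
               aic = n * log(rss / n) + 2 * (k + 2))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}

#' The nine canonical subgroup-pair contrasts
#'
#' The standard G1-G9 contrasts over the eight trichotomy subgroups:
#' marginal contrasts on each axis (G1 cognition, G2 vascular disease,
#' G3 Alzheimer's disease) and conditional contrasts within disease or
#' cognition strata (G4-G9).
#'
#' @param labels optional trichotomy label vector; when given, each pair
#'   also carries `idx1`/`idx2` subject index sets (always disjoint).
#' @return Named list of 9 pairs, each with `id`, `description`,
#'   `g1_labels`, `g2_labels` (and index sets when `labels` is supplied).
#' @export
define_group_pairs <- function(labels = NULL) {
  P <- function(id, desc, g1, g2)
    list(id = id, description = desc, g1_labels = g1, g2_labels = g2)
  pairs <- list(
    P("G1", "Cognition (low vs normal)",
      c("bCL", "bVD", "bAD", "bMX"), c("bCN", "bCN_VD", "bCN_AD", "bCN_MX")),
    P("G2", "Vascular disease (yes vs no)",
      c("bVD", "bMX", "bCN_VD", "bCN_MX"), c("bCN", "bCN_AD", "bCL", "bAD")),
    P("G3", "Alzheimer's disease (yes vs no)",
      c("bAD", "bMX", "bCN_AD", "bCN_MX"), c("bCN", "bCN_VD", "bCL", "bVD")),
    P("G4", "Cognition (low vs normal) for VD-yes",
      c("bVD", "bMX"), c("bCN_VD", "bCN_MX")),
    P("G5", "Cognition (low vs normal) for AD-yes",
      c("bAD", "bMX"), c("bCN_AD", "bCN_MX")),
    P("G6", "VD (yes vs no) for cognition-low",
      c("bVD", "bMX"), c("bCL", "bAD")),
    P("G7", "VD (yes vs no) for AD-yes",
      c("bMX", "bCN_MX"), c("bAD", "bCN_AD")),
    P("G8", "AD (yes vs no) for cognition-low",
      c("bAD", "bMX"), c("bCL", "bVD")),
    P("G9", "AD (yes vs no) for VD-yes",
      c("bMX", "bCN_MX"), c("bVD", "bCN_VD")))
  names(pairs) <- vapply(pairs, `[[`, "", "id")
  if (!is.null(labels)) {
    labels <- as_trichotomy_factor(labels)
    pairs <- lapply(pairs, function(p) {
      p$idx1 <- which(labels %in% p$g1_labels)
      p$idx2 <- which(labels %in% p$g2_labels)
      p
    })
  }
  pairs
}

#' Default hypothesis battery over the auxiliary variables
#'
#' Nine hypotheses over the six variables not used in building the
#' composite scores: sex, APOE4 allele count, CDR sum-of-boxes, its annual
#' change, hippocampal volume and brain atrophy. Proportions are compared
#' by chi-squared test, means by two-sample t-test. The set is a package
#' default and fully replaceable: supply your own list to
#' [group_pair_tests()] with the same element structure.
#'
#' @return List of hypothesis specs: `id`, `variable`, `type`
#'   (`"proportion"`/`"mean"`), `indicator` (for proportions, a function
#'   mapping the variable to a logical), `description`.
#' @export
default_hypotheses <- function() {
  H <- function(id, variable, type, desc, indicator = NULL)
    list(id = id, variable = variable, type = type,
         indicator = indicator, description = desc)
  list(
    H("H1", "sex", "proportion", "proportion male",
      function(x) x == "male"),
    H("H2", "apoe4", "proportion", "APOE4 carrier (>= 1 allele)",
      function(x) x >= 1),
    H("H3", "apoe4", "proportion", "APOE4 homozygote (2 alleles)",
      function(x) x == 2),
    H("H4", "cdrsb", "proportion", "CDRSB > 0",
      function(x) x > 0),
    H("H5", "cdrsb", "proportion", "CDRSB >= 1",
      function(x) x >= 1),
    H("H6", "delta_cdrsb", "proportion", "CDRSB increasing (>0/year)",
      function(x) x > 0),
    H("H7", "delta_cdrsb", "proportion", "CDRSB fast increase (>=0.5/year)",
      function(x) x >= 0.5),
    H("H8", "hv", "mean", "hippocampal volume"),
    H("H9", "ba", "mean", "brain atrophy"))
}

#' Bonferroni-corrected hypothesis tests across subgroup pairs
#'
#' For every (pair, hypothesis) combination, compares the two subject
#' groups: chi-squared test of equal proportions (without continuity
#' correction) for proportion hypotheses, two-sample t-test for mean
#' hypotheses (pooled variance by default; set `welch = TRUE` for the
#' unequal-variance form). Raw p-values are multiplied by the correction
#' factor (default pairs x hypotheses = 81) and capped at 1. A 2x2 table
#' with an empty cell, or an empty group, is reported as untestable (NA
#' statistic) with a warning rather than a p-value.
#'
#' @param data cohort data frame holding the hypothesis variables.
#' @param labels trichotomy label per row of `data`.
#' @param hypotheses list of hypothesis specs, see [default_hypotheses()].
#' @param pairs list of pair specs, see [define_group_pairs()].
#' @param correction_factor Bonferroni multiplier; default
#'   `length(pairs) * length(hypotheses)`.
#' @param welch use Welch's t-test for mean hypotheses.
#' @return Data frame of class `group_comparison`: `pair_id`,
#'   `hypothesis_id`, `test_type`, `statistic`, `p_raw`, `p_adjusted`,
#'   `note`; one row per (pair, hypothesis).
#' @export
group_pair_tests <- function(data, labels, hypotheses = default_hypotheses(),
                             pairs = define_group_pairs(),
                             correction_factor = NULL, welch = FALSE) {
  labels <- as_trichotomy_factor(labels)
  if (nrow(data) != length(labels)) stopf("data rows and labels differ")
  factor_n <- correction_factor %||% (length(pairs) * length(hypotheses))
  rows <- list()
  for (p in pairs) {
    i1 <- which(labels %in% p$g1_labels)
    i2 <- which(labels %in% p$g2_labels)
    for (h in hypotheses) {
      if (!h$variable %in% names(data))
        stopf("hypothesis %s needs column '%s'", h$id, h$variable)
      v <- data[[h$variable]]
      res <- test_one_pair(v[i1], v[i2], h, welch)
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = p$id, hypothesis_id = h$id, test_type = res$type,
        statistic = res$stat, p_raw = res$p,
        p_adjusted = if (is.na(res$p)) NA_real_ else min(1, res$p * factor_n),
        note = res$note, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "correction_factor") <- factor_n
  class(out) <- c("group_comparison", class(out))
  out
}

test_one_pair <- function(v1, v2, h, welch) {
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) == 0L || length(v2) == 0L) {
    warnf("%s: empty group, untestable", h$id)
    return(list(type = h$type, stat = NA_real_, p = NA_real_,
                note = "untestable: empty group"))
  }
  if (h$type == "proportion") {
    ind1 <- h$indicator(v1); ind2 <- h$indicator(v2)
    tab <- rbind(c(sum(ind1), sum(!ind1)), c(sum(ind2), sum(!ind2)))
    if (any(tab == 0)) {
      warnf("%s: zero cell in the 2x2 table, untestable", h$id)
      return(list(type = "chi-squared", stat = NA_real_, p = NA_real_,
                  note = "untestable: zero cell"))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(type = "chi-squared", stat = unname(ct$statistic),
         p = max(ct$p.value, P_FLOOR), note = "")
  } else {
    if (length(v1) < 2L || length(v2) < 2L)
      return(list(type = "t", stat = NA_real_, p = NA_real_,
                  note = "untestable: group too small"))
    tt <- t.test(v1, v2, var.equal = !welch)
    list(type = if (welch) "welch-t" else "t", stat = unname(tt$statistic),
         p = max(tt$p.value, P_FLOOR), note = "")
  }
}

#' Write group-comparison results as a pair x hypothesis matrix of
#' adjusted p-values
#'
#' @param results output of [group_pair_tests()].
#' @param path optional CSV path; when NULL the matrix is returned only.
#' @return Matrix of adjusted p-values (pairs as rows), invisibly written
#'   to `path` when given.
#' @export
comparison_matrix <- function(results, path = NULL) {
  m <- tapply(results$p_adjusted,
              list(results$pair_id, results$hypothesis_id), identity)
  if (!is.null(path))
    write.csv(data.frame(pair = rownames(m), m, check.names = FALSE),
              path, row.names = FALSE)
  m
}
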