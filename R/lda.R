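#' Derive a linear composite axis by two-class linear discriminant analysis
#'
#' Fisher LDA with pooled within-class covariance and equal priors, the
#' procedure used to construct the published VDF and Cog axes: the weight
#' vector is `w proportional to S_pooled^-1 (mu_patient - mu_control)`,
#' rescaled to unit Euclidean norm, and the intercept places the decision
#' boundary at the projected midpoint of the class means, so the raw-score
#' cutoff is 0. The patient class projects positive.
#'
#' @param x numeric matrix (n x p) of features, already on the modeling
#'   scale (apply log10 transforms before fitting; record them in
#'   `features` so scoring applies them automatically).
#' @param labels patient indicator: logical, 0/1, or a two-level factor
#'   whose second level is the patient class.
#' @param name axis name for the returned definition.
#' @param features optional feature-transform data frame as in
#'   [composite_axis()]; defaults to identity transforms on the column
#'   names of `x`.
#' @return A [composite_axis()] with unit-norm coefficients, `cth = 0` and
#'   `derivation = "lda"`.
#' @export
fit_lda_axis <- function(x, labels, name = "custom", features = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  g <- as_patient_indicator(labels)
  n <- nrow(x); p <- ncol(x)
  if (length(g) != n) stopf("labels length (%d) != rows of x (%d)", length(g), n)
  if (anyNA(x) || anyNA(g)) stopf("x and labels must be complete")
  n0 <- sum(!g); n1 <- sum(g)
  if (n0 == 0L || n1 == 0L) stopf("both classes must be non-empty")
  if (n < p + 2L) stopf("need n >= p + 2 (n=%d, p=%d)", n, p)

  mu0 <- colMeans(x[!g, , drop = FALSE])
  mu1 <- colMeans(x[g, , drop = FALSE])
  d <- mu1 - mu0
  scale_ref <- mean(apply(x, 2, sd))
  if (sqrt(sum(d^2)) < 1e-12 * max(scale_ref, 1e-300))
    stopf("degenerate separation: identical class means")

  S0 <- if (n0 > 1L) stats::cov(x[!g, , drop = FALSE]) else matrix(0, p, p)
  S1 <- if (n1 > 1L) stats::cov(x[g, , drop = FALSE]) else matrix(0, p, p)
  S <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n - 2)

  w <- tryCatch(
    if (rcond(S) < 1e-12) NULL else solve(S, d),
    error = function(e) NULL)
  if (is.null(w)) {
    eps <- 1e-6 * mean(diag(S))
    warnf("pooled covariance is singular; applying ridge %g * I", eps)
    w <- solve(S + diag(eps, p), d)
  }
  w <- w / sqrt(sum(w^2))
  if (sum(w * d) < 0) w <- -w
  b <- -sum(w * (mu0 + mu1) / 2)

  if (is.null(features)) {
    fields <- colnames(x) %||% paste0("x", seq_len(p))
    features <- data.frame(field = fields, transform = "identity", scale = 1)
  }
  composite_axis(name, features, coefficients = as.numeric(w),
                 intercept = b, cth = 0, derivation = "lda")
}

as_patient_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stopf("labels must have exactly two levels")
    return(labels == levels(labels)[2L])
  }
  u <- sort(unique(labels))
  if (length(u) != 2L) stopf("labels must take exactly two values")
  labels == u[2L]
}

#' Classification accuracy of a thresholded score
#'
#' Fraction of subjects for which `score > cth` agrees with the patient
#' label.
#'
#' @param scores numeric raw scores.
#' @param labels patient indicator (see [fit_lda_axis()]).
#' @param cth decision threshold on the score scale.
#' @return Fraction correct in \[0, 1\].
#' @export
classification_accuracy <- function(scores, labels, cth = 0) {
  g <- as_patient_indicator(labels)
  if (length(scores) == 0L) stopf("empty input")
  if (length(scores) != length(g)) stopf("scores and labels lengths differ")
  if (!any(g) || all(g)) stopf("both classes must be present")
  mean((scores > cth) == g)
}

#' Leave-one-out cross-validated accuracy of an LDA axis
#'
#' Refits the discriminant on n-1 subjects for each held-out subject and
#' classifies it with the refit axis; reports the mean accuracy. Used to
#' check the stability of an axis fitted and applied on the same cohort.
#'
#' @inheritParams fit_lda_axis
#' @return Mean held-out accuracy in \[0, 1\].
#' @export
loocv_accuracy <- function(x, labels, name = "loocv") {
  x <- as.matrix(x)
  g <- as_patient_indicator(labels)
  n <- nrow(x)
  if (n < 4L) stopf("need at least 4 subjects for leave-one-out")
  correct <- logical(n)
  for (i in seq_len(n)) {
    gtr <- g[-i]
    if (!any(gtr) || all(gtr))
      stopf("fold %d has a single-class training set", i)
    ax <- fit_lda_axis(x[-i, , drop = FALSE], gtr, name = name)
    s <- drop(x[i, , drop = FALSE] %*% ax$coefficients) + ax$intercept
    correct[i] <- (s > ax$cth) == g[i]
  }
  mean(correct)
}
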