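test_that("raw composite formulas reproduce their printed values", {
  # VDF: both log terms vanish at mfw=0.01, psmd=1e-4
  expect_equal(compute_vdf_raw(mfw = 0.01, psmd = 1e-4), -1.474)
  expect_equal(compute_vdf_raw(mfw = 0.1, psmd = 1e-3),
               0.135 + 0.991 - 1.474)
  # Cog: intercept only, then direct evaluation at (+/-1, +/-1)
  expect_equal(compute_cog_raw(adni_mem = 0, adni_ef = 0), 0.519)
  expect_equal(compute_cog_raw(adni_mem = 1, adni_ef = 1), -0.554)
  expect_equal(compute_cog_raw(adni_mem = -1, adni_ef = -1), 1.592)
  # ADF: the ratio rule, with the published cutoff at ratio 0.022
  expect_equal(compute_adf_raw(abeta42 = 1000, ptau = 22), log10(0.022))
  expect_equal(compute_adf_raw(abeta42 = 1000, ptau = 10), -2)
  expect_equal(compute_adf_raw(abeta42 = 50, ptau = 50), 0)
})

test_that("the VDF zero contour at psmd = 1e-4 sits near mfw = 0.307", {
  root <- uniroot(function(m) compute_vdf_raw(m, 1e-4),
                  c(0.25, 0.35), tol = 1e-12)$root
  expect_lt(abs(compute_vdf_raw(root, 1e-4)), 1e-10)
  expect_equal(root, 0.3072, tolerance = 1e-3)
  expect_lt(abs(compute_vdf_raw(0.30728, 1e-4)), 2.5e-4)
})

test_that("published LDA-derived coefficient vectors have unit norm", {
  axes <- trichotomy_axes()
  expect_lt(abs(sqrt(sum(axes$vdf$coefficients^2)) - 1), 1e-3)
  expect_lt(abs(sqrt(sum(axes$cog$coefficients^2)) - 1), 1e-3)
})

test_that("raw scores are monotone in the disease-positive direction", {
  set.seed(11)
  for (i in 1:200) {
    mfw <- runif(1, 0.05, 0.5); psmd <- runif(1, 5e-5, 1e-3)
    d <- runif(1, 1e-4, 0.1)
    expect_gt(compute_vdf_raw(mfw + d * 0.3, psmd), compute_vdf_raw(mfw, psmd))
    expect_gt(compute_vdf_raw(mfw, psmd * (1 + d)), compute_vdf_raw(mfw, psmd))
    ab <- runif(1, 200, 2000); pt <- runif(1, 8, 60)
    expect_gt(compute_adf_raw(ab, pt * (1 + d)), compute_adf_raw(ab, pt))
    expect_lt(compute_adf_raw(ab * (1 + d), pt), compute_adf_raw(ab, pt))
    mem <- rnorm(1); ef <- rnorm(1)
    expect_lt(compute_cog_raw(mem + d, ef), compute_cog_raw(mem, ef))
    expect_lt(compute_cog_raw(mem, ef + d), compute_cog_raw(mem, ef))
  }
})

test_that("non-positive inputs to log-scale composites are rejected", {
  expect_error(compute_vdf_raw(-0.1, 1e-4), "positive")
  expect_error(compute_vdf_raw(0.2, 0), "positive")
  expect_error(compute_adf_raw(0, 20), "positive")
  expect_error(compute_raw_score(trichotomy_axes()$adf,
                                 data.frame(ptau = -1, abeta42 = 900)),
               "non-positive")
})

test_that("LDA recovers the discriminant direction of separable Gaussians", {
  sim <- generate_two_group_features(2000, c(1, 0), diag(2), seed = 5)
  ax <- fit_lda_axis(sim$features, sim$labels, name = "toy")
  expect_lt(angle_deg(ax$coefficients, c(1, 0)), 2)
  expect_equal(sqrt(sum(ax$coefficients^2)), 1, tolerance = 1e-12)
  # boundary at the projected midpoint of the class means -> raw score 0
  mid <- (colMeans(sim$features[!sim$labels, ]) +
            colMeans(sim$features[sim$labels, ])) / 2
  expect_lt(abs(sum(ax$coefficients * mid) + ax$intercept), 1e-12)
  expect_identical(ax$cth, 0)
  # patient class projects positive
  s <- drop(sim$features %*% ax$coefficients) + ax$intercept
  expect_gt(mean(s[sim$labels]), mean(s[!sim$labels]))
})

test_that("LDA direction agrees with the MASS reference on correlated data", {
  Sigma <- matrix(c(1, 0.6, 0.6, 2), 2)
  sim <- generate_two_group_features(500, c(0.8, -0.4), Sigma, seed = 9)
  ax <- fit_lda_axis(sim$features, sim$labels)
  ref <- MASS::lda(sim$features, grouping = sim$labels,
                   prior = c(0.5, 0.5))
  expect_lt(angle_deg(ax$coefficients, ref$scaling[, 1]), 0.01)
})

test_that("LDA recovers a planted (0.135, 0.991) axis on cohort-like data", {
  # plant the discriminant direction w: the class-mean shift must be
  # Sigma %*% w (LDA recovers Sigma^-1 * shift); separation 3 SD.
  # Covariance mimics the DTI features: log10-scale SDs 0.08 and 0.05,
  # correlation 0.7.
  w_true <- c(0.135, 0.991)
  Sigma <- matrix(c(0.08^2, 0.7 * 0.08 * 0.05,
                    0.7 * 0.08 * 0.05, 0.05^2), 2)
  sd_along <- sqrt(drop(t(w_true) %*% Sigma %*% w_true))
  shift <- drop(Sigma %*% w_true) * 3 / sd_along
  sim <- generate_two_group_features(2000, shift, Sigma, seed = 31)
  ax <- fit_lda_axis(sim$features, sim$labels, name = "VDF-like")
  expect_lt(max(abs(ax$coefficients - w_true)), 0.05)
  expect_lt(angle_deg(ax$coefficients, w_true), 5)
})

test_that("degenerate and singular LDA inputs are handled", {
  set.seed(1)
  x <- matrix(rnorm(80), ncol = 2)
  # identical class means
  xx <- rbind(x, x)
  expect_error(fit_lda_axis(xx, rep(c(FALSE, TRUE), each = nrow(x))),
               "degenerate separation")
  # duplicated feature column -> singular pooled covariance -> ridge + warning
  set.seed(2)
  x1 <- matrix(rnorm(200), ncol = 1)
  xdup <- cbind(x1, x1)
  g2 <- rep(c(FALSE, TRUE), each = 100)
  xdup[g2, ] <- xdup[g2, ] + 1
  expect_warning(ax <- fit_lda_axis(xdup, g2), "ridge")
  expect_equal(sqrt(sum(ax$coefficients^2)), 1, tolerance = 1e-12)
})

test_that("classification accuracy equals the exhaustive count", {
  scores <- c(-2.1, -1.3, -0.4, -0.2, 0.1, 0.3, 0.7, 1.2, -0.6, 0.05)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  # brute-force loop oracle
  correct <- 0
  for (i in seq_along(scores))
    correct <- correct + ((scores[i] > 0) == labels[i])
  expect_equal(classification_accuracy(scores, labels, cth = 0), correct / 10)
  # perfectly separated
  expect_equal(classification_accuracy(c(-1, -2, 3, 4), c(0, 0, 1, 1), 0), 1)
  # flipping k labels drops accuracy by exactly k/n
  set.seed(3)
  s <- rnorm(50); g <- s > 0
  flip <- sample(50, 7)
  g2 <- g; g2[flip] <- !g2[flip]
  expect_equal(classification_accuracy(s, g2, 0), (50 - 7) / 50)
  expect_error(classification_accuracy(numeric(0), logical(0)), "empty")
})

test_that("leave-one-out accuracy matches a fold-by-fold oracle at n = 4", {
  x <- matrix(c(0.0, 0.9, 1.1, 0.4), ncol = 1)
  g <- c(FALSE, FALSE, TRUE, TRUE)
  oracle <- vapply(1:4, function(i) {
    fit <- MASS::lda(x[-i, , drop = FALSE], grouping = g[-i],
                     prior = c(0.5, 0.5))
    pred <- stats::predict(fit, x[i, , drop = FALSE])$class
    as.logical(as.character(pred)) == g[i]
  }, logical(1))
  expect_equal(loocv_accuracy(x, g), mean(oracle))
})

test_that("leave-one-out accuracy behaves at the extremes", {
  sim <- generate_two_group_features(30, c(6, 6), diag(2), seed = 8)
  expect_equal(loocv_accuracy(sim$features, sim$labels), 1)
  # permuted labels on a null cohort: near chance
  set.seed(17)
  xn <- matrix(rnorm(400), ncol = 2)
  gn <- rep(c(FALSE, TRUE), each = 100)[sample(200)]
  expect_lt(abs(loocv_accuracy(xn, gn) - 0.5), 0.1)
})

test_that("axis configs round-trip through plain text bit-exactly", {
  axes <- trichotomy_axes()
  for (ax in axes) {
    path1 <- withr::local_tempfile(fileext = ".txt")
    path2 <- withr::local_tempfile(fileext = ".txt")
    write_axis_config(ax, path1)
    ax2 <- read_axis_config(path1)
    write_axis_config(ax2, path2)
    expect_identical(readLines(path1), readLines(path2))
    d <- data.frame(ptau = 25, abeta42 = 800, mfw = 0.3, psmd = 3e-4,
                    adni_mem = -0.2, adni_ef = 0.4)
    expect_identical(compute_raw_score(ax, d), compute_raw_score(ax2, d))
  }
})
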