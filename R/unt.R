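#' Tabulated empirical CDF of a raw composite score
#'
#' Empirical CDF with midrank tie handling, tabulated at the sorted unique
#' values and linearly interpolated between them. CDF values use the
#' `(rank - 0.5)/n` convention, so tabulated values are strictly inside
#' (0, 1) — the open range the normalized scores must live in.
#'
#' @param raw_scores numeric vector of raw composite scores from the
#'   calibration sample; at least 20 finite values.
#' @return An object of class `tab_cdf` with elements `knots`, `F`, `n`.
#' @export
estimate_cdf <- function(raw_scores) {
  if (any(!is.finite(raw_scores))) stopf("raw scores must be finite")
  n <- length(raw_scores)
  if (n < 20L) stopf("insufficient calibration sample (n=%d < 20)", n)
  knots <- sort(unique(raw_scores))
  if (length(knots) < 2L) stopf("degenerate support: all scores identical")
  midrank <- tapply(rank(raw_scores), factor(raw_scores, levels = knots), mean)
  structure(list(knots = as.numeric(knots),
                 F = as.numeric((midrank - 0.5) / n),
                 n = n),
            class = "tab_cdf")
}

interp_cdf <- function(cdf, x) {
  approx(cdf$knots, cdf$F, xout = x, rule = 2)$y
}

#' Build a uniform normalization transform table
#'
#' The uniform normalization transform (UNT) maps a raw composite score to
#' (0, 1) monotonically, sending the clinical cutoff `cth` exactly to 0.5
#' and each side of the cutoff approximately uniformly onto its half
#' interval. With `F` the interpolated calibration CDF and `F0 = F(cth)`:
#' \deqn{CSnorm(x) = 0.5 F(x)/F0  (x \le cth);\quad
#'       0.5 + 0.5 (F(x)-F0)/(1-F0)  (x > cth).}
#' This piecewise-affine rescaling of the empirical CDF is the minimal
#' monotone table-based map with the three required properties (open range,
#' cutoff anchored at 0.5, conditional uniformity).
#'
#' @param cdf a `tab_cdf` from [estimate_cdf()], or a numeric vector of raw
#'   calibration scores (converted internally).
#' @param cth_raw cutoff on the raw scale; must lie strictly inside the
#'   calibration range.
#' @param name axis name stored in the table.
#' @return An object of class `unt_table` with knot vectors `knots_raw`,
#'   `knots_norm`, plus `cth_raw`, `n_calibration` and the clamping margin
#'   `epsilon = 1/(2 n)`.
#' @export
build_unt <- function(cdf, cth_raw, name = "axis") {
  if (is.numeric(cdf)) cdf <- estimate_cdf(cdf)
  if (!inherits(cdf, "tab_cdf")) stopf("cdf must be a tab_cdf or numeric vector")
  rng <- range(cdf$knots)
  if (cth_raw <= rng[1] || cth_raw >= rng[2])
    stopf("cutoff not bracketed: cth_raw=%g outside calibration range (%g, %g)",
          cth_raw, rng[1], rng[2])
  knots_raw <- sort(unique(c(cdf$knots, cth_raw)))
  Fk <- interp_cdf(cdf, knots_raw)
  F0 <- interp_cdf(cdf, cth_raw)
  knots_norm <- ifelse(knots_raw <= cth_raw,
                       0.5 * Fk / F0,
                       0.5 + 0.5 * (Fk - F0) / (1 - F0))
  structure(list(name = name,
                 knots_raw = knots_raw, knots_norm = knots_norm,
                 cth_raw = cth_raw, n_calibration = cdf$n,
                 epsilon = 1 / (2 * cdf$n)),
            class = "unt_table")
}

#' Fit a UNT on a calibration sample
#'
#' Convenience wrapper: [estimate_cdf()] then [build_unt()]. Tables are
#' fitted once on a calibration cohort and can then be serialized
#' ([write_unt_table()]) and applied to new subjects without refitting.
#'
#' @param raw_scores calibration raw scores (NA dropped with a message).
#' @inheritParams build_unt
#' @return An `unt_table`.
#' @export
fit_unt <- function(raw_scores, cth_raw, name = "axis") {
  keep <- !is.na(raw_scores)
  if (!all(keep))
    message(sprintf("UNT %s: dropping %d missing calibration scores",
                    name, sum(!keep)))
  build_unt(estimate_cdf(raw_scores[keep]), cth_raw, name = name)
}

#' Apply a UNT table to raw scores
#'
#' Linear interpolation between the table knots; strictly order-preserving
#' within the calibration range. Values below the calibration range clamp
#' to `epsilon`, values above to `1 - epsilon` (with a warning), keeping
#' outputs strictly inside (0, 1).
#'
#' @param table an `unt_table`.
#' @param x raw scores to normalize (NA passes through).
#' @return Normalized scores in (0, 1).
#' @export
apply_unt <- function(table, x) {
  stopifnot(inherits(table, "unt_table"))
  y <- approx(table$knots_raw, table$knots_norm, xout = x, rule = 1)$y
  lo <- !is.na(x) & x < table$knots_raw[1]
  hi <- !is.na(x) & x > table$knots_raw[length(table$knots_raw)]
  n_out <- sum(lo) + sum(hi)
  if (n_out > 0)
    warnf("%d score(s) outside the calibration range were clamped", n_out)
  y[lo] <- table$epsilon
  y[hi] <- 1 - table$epsilon
  y
}

#' @export
print.unt_table <- function(x, ...) {
  cat(sprintf("<unt_table> %s: %d knots, cth_raw = %g -> 0.5, n = %d\n",
              x$name, length(x$knots_raw), x$cth_raw, x$n_calibration))
  invisible(x)
}

#' Serialize a UNT table to plain text
#'
#' Header lines (`# key: value`) followed by two whitespace-separated
#' columns (raw knot, normalized knot). Numbers carry 17 significant
#' digits, so a loaded table reproduces applied values bit-exactly.
#'
#' @param table an `unt_table`.
#' @param path output file path.
#' @export
write_unt_table <- function(table, path) {
  hdr <- c(sprintf("# axis: %s", table$name),
           sprintf("# cth_raw: %s", fmt_num(table$cth_raw)),
           sprintf("# n_calibration: %d", table$n_calibration),
           sprintf("# epsilon: %s", fmt_num(table$epsilon)))
  body <- paste(fmt_num(table$knots_raw), fmt_num(table$knots_norm))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Load a UNT table written by [write_unt_table()]
#'
#' @param path file path.
#' @return An `unt_table`.
#' @export
read_unt_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(sprintf("^# %s: ", key), hdr, value = TRUE)
    if (length(m) != 1L) stopf("UNT file: expected one '%s' header", key)
    sub(sprintf("^# %s: ", key), "", m)
  }
  body <- lines[!grepl("^# ", lines) & nzchar(lines)]
  kv <- do.call(rbind, strsplit(body, " ", fixed = TRUE))
  structure(list(name = getv("axis"),
                 knots_raw = as.numeric(kv[, 1]),
                 knots_norm = as.numeric(kv[, 2]),
                 cth_raw = as.numeric(getv("cth_raw")),
                 n_calibration = as.integer(getv("n_calibration")),
                 epsilon = as.numeric(getv("epsilon"))),
            class = "unt_table")
}
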