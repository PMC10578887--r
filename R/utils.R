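# Round half away from zero (base round() uses round-half-even, which would
# report 73/538 = 13.57% as 13.6% either way but 2.65 as 2.6 rather than 2.7).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Shortest exact decimal round-trip for serialized numbers.
fmt_num <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
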