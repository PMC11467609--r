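#' Round half away from zero
#'
#' Reporting convention for percentages and coefficients: ties round away
#' from zero (97.55 -> 97.6, -0.365 -> -0.37), unlike base R's
#' round-half-to-even. Internal statistics are never rounded; this is a
#' display/serialisation helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector; `NA` passes through.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values like 0.5749999... stored for
  # 0.575 still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

fmt_num <- function(x, digits = 1) {
  ifelse(is.na(x), "", formatC(round_half_up(x, digits),
                               format = "f", digits = digits))
}

# "97.6 (96.4-98.5)" cells used in the per-symptom table
fmt_pct_ci <- function(pct, lower, upper, digits = 1) {
  ifelse(is.na(pct), "",
         paste0(fmt_num(pct, digits), " (", fmt_num(lower, digits), "-",
                fmt_num(upper, digits), ")"))
}

# deterministic 31-bit hash of a label, for per-symptom RNG substreams
stable_hash <- function(label) {
  vapply(label, function(s) {
    h <- 0
    for (ch in utf8ToInt(enc2utf8(s))) h <- (h * 31 + ch) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}
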