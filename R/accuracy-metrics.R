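#' Construct a binary confusion matrix
#'
#' Cell counts after dichotomising the ordinal triage scale at the urgency
#' boundary, with the nurse as gold standard and "urgent" as the positive
#' class.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `confusion_matrix` (a named list).
#' @export
confusion_matrix <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(abs(cells - round(cells)) > 1e-8)) {
    stop("confusion matrix cells must be non-negative integers",
         call. = FALSE)
  }
  structure(list(tp = as.numeric(round(tp)), fp = as.numeric(round(fp)),
                 tn = as.numeric(round(tn)), fn = as.numeric(round(fn))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(nurse = c("urgent", "non-urgent"),
                              checker = c("urgent", "non-urgent")))
  cat("Confusion matrix (gold = nurse, positive = urgent), n =",
      x$tp + x$fp + x$tn + x$fn, "\n")
  print(m)
  invisible(x)
}

#' Build a confusion matrix from paired triage assessments
#'
#' @param records A cohort data frame with `nurse_triage` and `esc_triage`
#'   columns (see [generate_cohort()]), or a character vector of nurse
#'   levels if `esc` is supplied.
#' @param esc Optional character vector of checker levels, used when
#'   `records` is a vector of nurse levels.
#' @param urgent Urgent level set, see [is_urgent()].
#' @return A `confusion_matrix`. An empty input yields the all-zero
#'   matrix.
#' @export
#' @examples
#' build_confusion_matrix(c("P1", "P4"), c("P2", "P1"))
build_confusion_matrix <- function(records, esc = NULL,
                                   urgent = default_urgent_levels()) {
  if (is.data.frame(records)) {
    nurse <- records$nurse_triage
    esc <- records$esc_triage
  } else {
    nurse <- records
  }
  if (length(nurse) != length(esc)) {
    stop("nurse and checker level vectors must have equal length",
         call. = FALSE)
  }
  if (length(nurse) == 0L) return(confusion_matrix(0, 0, 0, 0))
  nu <- is_urgent(nurse, urgent)
  eu <- is_urgent(esc, urgent)
  confusion_matrix(tp = sum(nu & eu), fp = sum(!nu & eu),
                   tn = sum(!nu & !eu), fn = sum(nu & !eu))
}

ratio_or_na <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

#' Diagnostic accuracy statistics of a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive
#' predictive value `TP/(TP+FP)` and negative predictive value
#' `TN/(TN+FN)`. A zero denominator yields `NA` ("undefined"), never a
#' silent 0 or 1.
#'
#' @param m A `confusion_matrix`.
#' @return A proportion in `[0, 1]`, or `NA` when undefined.
#' @export
sensitivity <- function(m) ratio_or_na(m$tp, m$tp + m$fn)

#' @rdname sensitivity
#' @export
specificity <- function(m) ratio_or_na(m$tn, m$tn + m$fp)

#' @rdname sensitivity
#' @export
ppv <- function(m) ratio_or_na(m$tp, m$tp + m$fp)

#' @rdname sensitivity
#' @export
npv <- function(m) ratio_or_na(m$tn, m$tn + m$fn)

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a
#' balanced correlation of a binary confusion matrix ranging from -1
#' (perfect disagreement) through 0 (no relationship) to +1 (perfect
#' agreement). When any marginal is zero the coefficient is undefined and
#' `NA` is returned.
#'
#' @param m A `confusion_matrix`.
#' @return A value in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' mcc(confusion_matrix(5, 0, 5, 0)) # +1
mcc <- function(m) {
  den <- (m$tp + m$fp) * (m$tp + m$fn) * (m$tn + m$fp) * (m$tn + m$fn)
  if (den == 0) return(NA_real_)
  (m$tp * m$tn - m$fp * m$fn) / sqrt(den)
}

#' Interpretation band of a Matthews correlation coefficient
#'
#' Maps the absolute value onto the conventional bands: negligible
#' `[0, 0.10)`, weak `[0.10, 0.40)`, moderate `[0.40, 0.70)`, strong
#' `[0.70, 0.90)`, very strong `[0.90, 1]`. Half-open intervals resolve
#' the boundary values that verbal band tables leave ambiguous.
#'
#' @param value Numeric vector of MCC values in `[-1, 1]`; `NA` passes
#'   through.
#' @return Character vector of band labels.
#' @export
#' @examples
#' interpret_mcc(c(0.089, 0.253, -0.37))
interpret_mcc <- function(value) {
  ok <- is.na(value) | (value >= -1 - 1e-12 & value <= 1 + 1e-12)
  if (!all(ok)) {
    stop("MCC values must lie in [-1, 1]", call. = FALSE)
  }
  a <- abs(value)
  bands <- c("negligible", "weak", "moderate", "strong", "very strong")
  idx <- findInterval(a, c(0, 0.10, 0.40, 0.70, 0.90), left.open = FALSE)
  out <- bands[idx]
  out[is.na(value)] <- NA_character_
  out
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from Beta quantiles:
#' `lower = qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `upper = qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). At the
#' edges the closed forms hold: `x = n` gives `lower = (alpha/2)^(1/n)`,
#' `x = 0` gives `upper = 1 - (alpha/2)^(1/n)`. Coverage is conservative
#' (at least the nominal level for every true proportion).
#'
#' @param x Integer vector of success counts.
#' @param n Integer vector of trial counts (recycled against `x`).
#' @param conf.level Confidence level in (0, 1); default 0.95.
#' @return A data frame with columns `x`, `n`, `estimate`, `lower`,
#'   `upper`, `conf.level`.
#' @export
#' @examples
#' clopper_pearson_ci(41, 41)       # lower bound 0.914
#' clopper_pearson_ci(471, 877)     # (0.503, 0.570)
clopper_pearson_ci <- function(x, n, conf.level = 0.95) {
  k <- max(length(x), length(n))
  x <- rep_len(x, k)
  n <- rep_len(n, k)
  if (length(conf.level) != 1L || !is.finite(conf.level) ||
      conf.level <= 0 || conf.level >= 1) {
    stop("conf.level must be a single number in (0, 1)", call. = FALSE)
  }
  if (any(n < 1) || any(x < 0) || any(x > n) ||
      any(x != round(x)) || any(n != round(n))) {
    stop("need integer counts with 0 <= x <= n and n >= 1", call. = FALSE)
  }
  alpha <- 1 - conf.level
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  data.frame(x = x, n = n, estimate = x / n, lower = lower, upper = upper,
             conf.level = conf.level)
}

#' Sample size for estimating a proportion to a given CI half-width
#'
#' Planning calculation for a study that must pin down a proportion
#' (e.g. the rate of safe checker advice, anticipated around 97%) to a
#' target confidence-interval half-width. The default is the normal
#' approximation `n = ceil(z^2 p (1 - p) / d^2)`; the `"exact"` method
#' instead searches for the smallest `n` whose Clopper-Pearson interval at
#' the expected count `round(n * p)` has half-width (half the interval
#' length) at most `d`.
#'
#' @param p_expected Anticipated proportion, in (0, 1).
#' @param half_width Target CI half-width, in (0, 1).
#' @param conf.level Confidence level; default 0.95.
#' @param method `"normal"` (default) or `"exact"`.
#' @return A list with `n`, `method`, `p_expected`, `half_width` and
#'   `conf.level`.
#' @export
#' @examples
#' required_sample_size(0.97, 0.01)$n # 1118
required_sample_size <- function(p_expected, half_width,
                                 conf.level = 0.95,
                                 method = c("normal", "exact")) {
  method <- match.arg(method)
  if (!is.finite(p_expected) || p_expected <= 0 || p_expected >= 1) {
    stop("p_expected must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.finite(half_width) || half_width <= 0 || half_width >= 1) {
    stop("half_width must lie strictly in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  n_normal <- ceiling(z^2 * p_expected * (1 - p_expected) / half_width^2)
  n <- n_normal
  if (method == "exact") {
    # exact intervals are wider, so start the search at the normal answer
    n <- max(1, n_normal)
    repeat {
      ci <- clopper_pearson_ci(round(n * p_expected), n, conf.level)
      if ((ci$upper - ci$lower) / 2 <= half_width) break
      n <- n + 1
      if (n > 1e7) stop("exact sample-size search did not converge",
                        call. = FALSE)
    }
  }
  list(n = as.integer(n), method = method, p_expected = p_expected,
       half_width = half_width, conf.level = conf.level)
}

#' Flat statistics row for a confusion matrix
#'
#' Convenience serialisation used by reports: all four cells plus the
#' derived statistics under stable names.
#'
#' @param m A `confusion_matrix`.
#' @return A one-row data frame with columns `tp`, `fp`, `tn`, `fn`,
#'   `sens`, `spec`, `ppv`, `npv`, `mcc`, `mcc_band`.
#' @export
metrics_row <- function(m) {
  v <- mcc(m)
  data.frame(tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
             sens = sensitivity(m), spec = specificity(m),
             ppv = ppv(m), npv = npv(m), mcc = v,
             mcc_band = if (is.na(v)) NA_character_ else interpret_mcc(v),
             stringsAsFactors = FALSE)
}
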