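#' Recover integer confusion matrices from published summary statistics
#'
#' Published validation tables often report only n, PPV, NPV and MCC per
#' stratum, not the underlying confusion matrix. This audit tool
#' enumerates every non-negative integer matrix `(tp, fp, tn, fn)` with
#' cells summing to `n`, scores each against the reported statistics, and
#' returns the best candidates. It both reconstructs matrices from
#' consistent rows and surfaces rows that no integer matrix can satisfy.
#'
#' Constraint semantics: a statistic passed as `NULL` is unconstrained; a
#' statistic passed as `NA` is asserted to be *undefined* in the source
#' (e.g. PPV of `NA` only matches matrices with `tp + fp = 0`). This
#' keeps "PPV = 0" and "PPV undefined" distinct.
#'
#' Scoring: proportions are compared on the percentage scale (1 point of
#' PPV = 1 unit of residual, squared); the MCC is weighted by 100 on its
#' native scale so that an MCC error of 0.01 counts like a 1-point
#' percentage error, matching the relative precision tables print. When
#' `decimals_pct`/`decimals_mcc` are given, computed statistics are first
#' rounded (half away from zero) to that precision, so a source matrix is
#' recoverable from its own rounded summaries with residual 0. Pass
#' `decimals_pct = NULL` and `decimals_mcc = NULL` for full-precision
#' matching. A defined constraint against an undefined computed statistic
#' (or vice versa) incurs a fixed penalty of 1e6.
#'
#' @param n Total count; the enumeration is `O(n^3)` and refused above
#'   `n = 5000`.
#' @param ppv,npv,sens,spec Reported proportions in `[0, 1]`, `NA` for
#'   "undefined in source", or `NULL` to leave unconstrained.
#' @param mcc Reported MCC in `[-1, 1]`, `NA`, or `NULL`.
#' @param decimals_pct Decimal places of the source's percentages
#'   (default 1, i.e. values like 49.4%); `NULL` for full precision.
#' @param decimals_mcc Decimal places of the source's MCC (default 3);
#'   `NULL` for full precision.
#' @param top_k Number of lowest-residual candidates to keep (all
#'   zero-residual candidates are always kept).
#' @return An object of class `recovery_result`: a list with `candidates`
#'   (data frame of cells, computed statistics and `residual`, sorted by
#'   ascending residual with lexicographic `(tp, fp, tn, fn)`
#'   tie-breaking) and `exact` (`TRUE` iff the best residual is 0).
#' @export
#' @examples
#' # a uniquely determined matrix
#' r <- recover_confusion_matrix(12, ppv = 0.75, npv = 0.875, mcc = 0.625,
#'                               decimals_pct = NULL, decimals_mcc = NULL)
#' r$candidates[1, c("tp", "fp", "tn", "fn")]
recover_confusion_matrix <- function(n, ppv = NULL, npv = NULL, mcc = NULL,
                                     sens = NULL, spec = NULL,
                                     decimals_pct = 1, decimals_mcc = 3,
                                     top_k = 25) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop("n must be a single positive integer", call. = FALSE)
  }
  if (n > 5000) {
    stop("n = ", n, " exceeds the enumeration guard (5000); ",
         "exhaustive recovery is O(n^3)", call. = FALSE)
  }
  constraints <- list(ppv = ppv, npv = npv, mcc = mcc,
                      sens = sens, spec = spec)
  given <- !vapply(constraints, is.null, logical(1))
  if (!any(given)) {
    stop("no constraints given: supply at least one of ppv, npv, mcc, ",
         "sens, spec", call. = FALSE)
  }
  for (nm in names(constraints)[given]) {
    v <- constraints[[nm]]
    lim <- if (nm == "mcc") c(-1, 1) else c(0, 1)
    if (length(v) != 1L || (!is.na(v) && (v < lim[1] || v > lim[2]))) {
      stop("constraint ", nm, " must be a single value in [",
           lim[1], ", ", lim[2], "] or NA", call. = FALSE)
    }
  }
  penalty <- 1e6
  score_prop <- function(computed, target) {
    if (is.null(target)) return(0)
    cmp <- if (is.null(decimals_pct)) 100 * computed else
      round_half_up(100 * computed, decimals_pct)
    if (is.na(target)) {
      ifelse(is.na(computed), 0, penalty)
    } else {
      ifelse(is.na(computed), penalty, (cmp - 100 * target)^2)
    }
  }
  score_mcc <- function(computed, target) {
    if (is.null(target)) return(0)
    cmp <- if (is.null(decimals_mcc)) computed else
      round_half_up(computed, decimals_mcc)
    if (is.na(target)) {
      ifelse(is.na(computed), 0, penalty)
    } else {
      ifelse(is.na(computed), penalty, (100 * (cmp - target))^2)
    }
  }

  keep <- vector("list", n + 1L)
  for (tp in 0:n) {
    m <- n - tp
    reps <- (m:0) + 1L
    fp <- rep.int(0:m, reps)
    tn <- sequence(reps) - 1L
    fn <- m - fp - tn
    tpd <- as.numeric(tp); fpd <- as.numeric(fp)
    tnd <- as.numeric(tn); fnd <- as.numeric(fn)
    ppv_c <- ifelse(tpd + fpd == 0, NA_real_, tpd / (tpd + fpd))
    npv_c <- ifelse(tnd + fnd == 0, NA_real_, tnd / (tnd + fnd))
    sen_c <- ifelse(tpd + fnd == 0, NA_real_, tpd / (tpd + fnd))
    spe_c <- ifelse(tnd + fpd == 0, NA_real_, tnd / (tnd + fpd))
    den <- (tpd + fpd) * (tpd + fnd) * (tnd + fpd) * (tnd + fnd)
    mcc_c <- ifelse(den == 0, NA_real_,
                    (tpd * tnd - fpd * fnd) / sqrt(den))
    res <- score_prop(ppv_c, constraints$ppv) +
      score_prop(npv_c, constraints$npv) +
      score_prop(sen_c, constraints$sens) +
      score_prop(spe_c, constraints$spec) +
      score_mcc(mcc_c, constraints$mcc)
    sel <- res <= 1e-12
    if (sum(!sel) > 0 && top_k > 0) {
      k <- min(top_k, sum(!sel))
      thr <- sort.int(res[!sel], partial = k)[k]
      sel <- sel | (res <= thr)
    }
    keep[[tp + 1L]] <- data.frame(
      tp = tp, fp = fp[sel], tn = tn[sel], fn = fn[sel],
      ppv = ppv_c[sel], npv = npv_c[sel], sens = sen_c[sel],
      spec = spe_c[sel], mcc = mcc_c[sel], residual = res[sel])
  }
  cand <- do.call(rbind, keep)
  cand <- cand[order(cand$residual, cand$tp, cand$fp, cand$tn, cand$fn), ,
               drop = FALSE]
  zero <- cand$residual <= 1e-12
  n_keep <- max(sum(zero), min(top_k, nrow(cand)))
  cand <- cand[seq_len(n_keep), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(candidates = cand, exact = any(zero), n = n,
                 constraints = constraints),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("Confusion-matrix recovery for n =", x$n,
      if (x$exact) "(exact match found)" else "(no exact match)", "\n")
  print(utils::head(x$candidates, 5))
  if (nrow(x$candidates) > 5) {
    cat("...", nrow(x$candidates), "candidates kept\n")
  }
  invisible(x)
}
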