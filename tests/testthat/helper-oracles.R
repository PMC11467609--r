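# Independent oracles and fixture builders shared across test files.

# Hand-derived 6x6 concordance table (rows = nurse, cols = checker),
# written out from the category rules independently of the package's
# classifier. Levels in rank order SELF_CARE, P4, P3, P2, P1, P0.
hand_truth_table <- function() {
  E <- "EXACT"; CS <- "CONSERVATIVE_SUITABLE"; OC <- "OVERLY_CONSERVATIVE"
  SU <- "SAFE_UNDER"; PU <- "POTENTIALLY_UNSAFE"
  lv <- c("SELF_CARE", "P4", "P3", "P2", "P1", "P0")
  matrix(c(
    # esc:  SELF_CARE  P4   P3   P2   P1   P0
            E,         CS,  OC,  OC,  OC,  OC,   # nurse SELF_CARE
            SU,        E,   CS,  OC,  OC,  OC,   # nurse P4
            SU,        SU,  E,   CS,  OC,  OC,   # nurse P3
            PU,        PU,  PU,  E,   CS,  OC,   # nurse P2
            PU,        PU,  PU,  SU,  E,   CS,   # nurse P1
            PU,        PU,  PU,  SU,  SU,  E),   # nurse P0
    nrow = 6, byrow = TRUE, dimnames = list(lv, lv))
}

# Clopper-Pearson bounds by bisection on the binomial tail probabilities,
# independent of qbeta.
cp_bisect <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else {
    stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (x == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower = lower, upper = upper)
}

# Random cohort over arbitrary level pairs (not via the package's
# generator), for invariant checks.
random_pair_cohort <- function(n, symptoms = c("a", "b", "c")) {
  lv <- triage_levels()
  cohort_from_pairs(sample(lv, n, replace = TRUE),
                    sample(lv, n, replace = TRUE),
                    symptom = sample(symptoms, n, replace = TRUE))
}

# Random confusion matrix with all cells >= 1 (keeps every statistic
# defined and the matrix uniquely recoverable from full-precision
# summaries).
random_positive_matrix <- function(n_max = 200) {
  n <- sample(8:n_max, 1)
  cells <- as.vector(stats::rmultinom(1, n - 4, prob = stats::runif(4))) + 1L
  confusion_matrix(cells[1], cells[2], cells[3], cells[4])
}

matrix_cells <- function(m) c(m$tp, m$fp, m$tn, m$fn)

# study-level category totals implied by the published counts:
# 471 exact, 584 exact-or-suitable, 856 safe, 877 total, 151 undertriaged
study_category_counts <- function() {
  c(EXACT = 471, CONSERVATIVE_SUITABLE = 113, OVERLY_CONSERVATIVE = 142,
    SAFE_UNDER = 130, POTENTIALLY_UNSAFE = 21)
}
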