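test_that("confusion matrix construction dichotomises at the boundary", {
  expect_identical(matrix_cells(build_confusion_matrix(character(0),
                                                       character(0))),
                   c(0, 0, 0, 0))
  expect_identical(matrix_cells(build_confusion_matrix("P1", "P0")),
                   c(1, 0, 0, 0))
  m <- build_confusion_matrix(c("P1", "P4", "SELF_CARE", "P2"),
                              c("P2", "P1", "SELF_CARE", "P4"))
  expect_identical(matrix_cells(m), c(1, 1, 1, 1))
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("cells always sum to the record count", {
  set.seed(42)
  for (i in 1:25) {
    coh <- random_pair_cohort(sample(0:80, 1))
    m <- build_confusion_matrix(coh)
    expect_equal(sum(matrix_cells(m)), nrow(coh))
  }
})

test_that("predictive values and rates return NA on zero denominators", {
  m <- confusion_matrix(0, 6, 10, 5)
  expect_equal(ppv(m), 0)
  expect_equal(npv(m), 10 / 15)
  expect_equal(sensitivity(confusion_matrix(8, 0, 0, 2)), 0.8)
  expect_true(is.na(ppv(confusion_matrix(0, 0, 5, 0))))
  expect_true(is.na(sensitivity(confusion_matrix(0, 3, 5, 0))))
  expect_true(is.na(npv(confusion_matrix(2, 3, 0, 0))))
  expect_true(is.na(specificity(confusion_matrix(2, 0, 0, 3))))
})

test_that("MCC endpoints, worked value, and undefined cases", {
  expect_equal(mcc(confusion_matrix(1, 1, 1, 1)), 0)
  expect_equal(mcc(confusion_matrix(5, 0, 5, 0)), 1)
  expect_equal(mcc(confusion_matrix(0, 5, 0, 5)), -1)
  # direct formula evaluation: -sqrt(30 / (16 * 15))
  expect_equal(mcc(confusion_matrix(0, 6, 10, 5)), -0.35355,
               tolerance = 1e-4)
  expect_true(is.na(mcc(confusion_matrix(0, 0, 10, 5))))
})

test_that("MCC is label-swap invariant and prediction-swap antisymmetric", {
  set.seed(7)
  for (i in 1:50) {
    m <- random_positive_matrix(150)
    v <- mcc(m)
    expect_true(v >= -1 && v <= 1)
    swapped_labels <- confusion_matrix(m$tn, m$fn, m$tp, m$fp)
    expect_equal(mcc(swapped_labels), v)
    swapped_pred <- confusion_matrix(m$fp, m$tp, m$fn, m$tn)
    expect_equal(mcc(swapped_pred), -v)
  }
})

test_that("MCC interpretation bands use half-open decade boundaries", {
  expect_identical(interpret_mcc(0.089), "negligible")
  expect_identical(interpret_mcc(0.253), "weak")
  expect_identical(interpret_mcc(1.0), "very strong")
  expect_identical(interpret_mcc(c(-0.37, 0.10, 0.40, 0.70, 0.90)),
                   c("weak", "weak", "moderate", "strong", "very strong"))
  expect_identical(interpret_mcc(-1), "very strong")
  expect_true(is.na(interpret_mcc(NA_real_)))
  expect_error(interpret_mcc(1.2), "\\[-1, 1\\]")
})

test_that("Clopper-Pearson edge closed forms agree with the Beta quantiles", {
  for (n in c(1, 5, 10, 24, 41, 81, 877)) {
    full <- clopper_pearson_ci(n, n)
    expect_equal(full$lower, 0.025^(1 / n), tolerance = 1e-10)
    expect_equal(full$upper, 1)
    none <- clopper_pearson_ci(0, n)
    expect_equal(none$upper, 1 - 0.025^(1 / n), tolerance = 1e-10)
    expect_equal(none$lower, 0)
  }
  # symmetry of the two edges
  expect_equal(clopper_pearson_ci(0, 41)$upper,
               1 - clopper_pearson_ci(41, 41)$lower, tolerance = 1e-12)
})

test_that("CI bounds match a bisection oracle on binomial tails, n <= 30", {
  for (n in 1:30) {
    ci <- clopper_pearson_ci(0:n, n)
    for (x in 0:n) {
      oracle <- cp_bisect(x, n)
      expect_equal(ci$lower[x + 1], oracle[["lower"]], tolerance = 1e-8)
      expect_equal(ci$upper[x + 1], oracle[["upper"]], tolerance = 1e-8)
    }
  }
})

test_that("exact intervals are conservative: analytic coverage >= nominal", {
  for (p in c(0.5, 0.9, 0.97)) {
    for (n in c(20, 100, 877)) {
      ci <- clopper_pearson_ci(0:n, n)
      covered <- ci$lower <= p & p <= ci$upper
      coverage <- sum(stats::dbinom(0:n, n, p)[covered])
      expect_gte(coverage, 0.95)
      # a seeded simulation agrees with the analytic coverage
      set.seed(n + round(1000 * p))
      draws <- stats::rbinom(2000, n, p)
      expect_equal(mean(covered[draws + 1]), coverage, tolerance = 0.03)
    }
  }
})

test_that("proportion CI output respects its own invariants", {
  set.seed(11)
  x <- stats::rbinom(50, 60, 0.4)
  ci <- clopper_pearson_ci(x, 60)
  expect_true(all(ci$lower >= 0 & ci$lower <= ci$estimate))
  expect_true(all(ci$estimate <= ci$upper & ci$upper <= 1))
  expect_error(clopper_pearson_ci(5, 4), "x <= n")
  expect_error(clopper_pearson_ci(2, 10, conf.level = 1.2), "conf.level")
})

test_that("sample-size planning reproduces the normal-approximation sizes", {
  expect_identical(required_sample_size(0.97, 0.01)$n, 1118L)
  expect_identical(required_sample_size(0.97, 0.05)$n, 45L)
  expect_identical(required_sample_size(0.97, 0.01)$method, "normal")
  # monotone: wider target half-width never needs more subjects
  widths <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  sizes <- vapply(widths, function(w) required_sample_size(0.97, w)$n,
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
  # the exact-width search can only ask for as many or more
  expect_gte(required_sample_size(0.97, 0.05, method = "exact")$n, 45L)
  expect_error(required_sample_size(1.2, 0.01), "p_expected")
  expect_error(required_sample_size(0.97, 0), "half_width")
})

test_that("flat metrics rows serialise undefined statistics as NA", {
  row <- metrics_row(confusion_matrix(0, 0, 5, 0))
  expect_true(is.na(row$ppv) && is.na(row$mcc) && is.na(row$mcc_band))
  expect_equal(row$spec, 1)
  row2 <- metrics_row(confusion_matrix(3, 1, 7, 1))
  expect_identical(row2$mcc_band, "moderate")
  expect_identical(names(row2),
                   c("tp", "fp", "tn", "fn", "sens", "spec", "ppv", "npv",
                     "mcc", "mcc_band"))
})
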