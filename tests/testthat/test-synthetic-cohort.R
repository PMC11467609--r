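test_that("kernels are row-stochastic after truncation to the scale", {
  w <- rep(1, 11) # uniform weights incl. impossible offsets
  k <- mistriage_kernel(w)
  expect_equal(unname(rowSums(k)), rep(1, 6))
  # SELF_CARE (rank 0) cannot move down: negative offsets carry no mass
  expect_equal(sum(k["SELF_CARE", as.character(-5:-1)]), 0)
  # P0 (rank 5) cannot move up
  expect_equal(sum(k["P0", as.character(1:5)]), 0)
  expect_error(mistriage_kernel(matrix(1, 2, 2)), "6 x 11")
  expect_error(mistriage_kernel(-w), "non-negative")
})

test_that("configuration validation names the offending fields", {
  expect_error(cohort_config(nurse_level_probs = rep(0.2, 6)),
               "nurse_level_probs")
  expect_error(cohort_config(p_walk_in = 1.5), "probabilities")
  expect_error(cohort_config(seed = 1.5), "seed")
  bad <- table1_symptoms()
  bad$n[1] <- -1
  expect_error(cohort_config(symptoms = bad), "symptoms")
})

test_that("a degenerate identity kernel yields an all-exact cohort", {
  coh <- generate_cohort(cohort_config(kernel = identity_kernel(),
                                       seed = 3))
  cats <- classify_concordance(coh$nurse_triage, coh$esc_triage)
  expect_true(all(cats == "EXACT"))
})

test_that("default cohorts reproduce the study's symptom sizes", {
  coh <- generate_cohort(cohort_config(seed = 9))
  expect_identical(nrow(coh), 877L)
  sizes <- table(coh$symptom)
  want <- table1_symptoms()
  expect_identical(unname(as.integer(sizes[want$symptom])), want$n)
  expect_silent(validate_cohort(coh, symptoms = want$symptom))
})

test_that("generation is reproducible and per-symptom substreamed", {
  cfg <- cohort_config(seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(a, generate_cohort(cohort_config(seed = 22))))
  # dropping a symptom leaves the draws of the others untouched
  sub <- table1_symptoms()[3:7, ]
  c2 <- generate_cohort(cohort_config(symptoms = sub, seed = 21))
  for (s in sub$symptom) {
    expect_equal(c2[c2$symptom == s, ], a[a$symptom == s, ],
                 ignore_attr = TRUE)
  }
  unlink(c(f1, f2))
})

test_that("the generator leaves the caller's RNG state alone", {
  set.seed(500)
  before <- .Random.seed
  invisible(generate_cohort(cohort_config(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("cohort CSV round-trips, reading level tokens case-insensitively", {
  coh <- generate_cohort(cohort_config(seed = 4))
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_identical(back, coh)
  # lower-case tokens on disk parse to canonical form
  txt <- readLines(f)
  writeLines(gsub("P1", "p1", gsub("SELF_CARE", "self_care", txt)), f)
  relaxed <- read_cohort(f)
  expect_identical(relaxed$nurse_triage, coh$nurse_triage)
  unlink(f)
})

test_that("kernel calibration hits requested category rates exactly", {
  ident <- calibrate_kernel(c(EXACT = 1))
  expect_equal(unname(induced_category_rates(ident)["EXACT"]), 1)
  targets <- study_category_counts() / 877
  k <- calibrate_kernel(targets)
  induced <- induced_category_rates(k)
  expect_equal(unname(induced[names(targets)]), unname(targets),
               tolerance = 1e-6)
  expect_equal(unname(induced["POTENTIALLY_UNSAFE"]), 21 / 877,
               tolerance = 1e-6)
})

test_that("infeasible calibration targets are reported explicitly", {
  # nothing sits below self-care, so safe-under cannot be expressed
  probs <- c(1, 0, 0, 0, 0, 0) # all nurse mass on SELF_CARE
  expect_error(calibrate_kernel(c(EXACT = 0.5, SAFE_UNDER = 0.5),
                                nurse_level_probs = probs),
               "SAFE_UNDER")
  # unsafe assessments need urgent nurse mass
  expect_error(
    calibrate_kernel(c(EXACT = 0.9, POTENTIALLY_UNSAFE = 0.1),
                     nurse_level_probs = c(0.5, 0.5, 0, 0, 0, 0)),
    "POTENTIALLY_UNSAFE")
  expect_error(calibrate_kernel(c(EXACT = 0.5)), "sum to 1")
})

test_that("empirical category frequencies converge to the induced rates", {
  targets <- study_category_counts() / 877
  k <- calibrate_kernel(targets)
  cfg <- cohort_config(
    symptoms = data.frame(symptom = "bulk", n = 100000L),
    kernel = k, seed = 77)
  coh <- generate_cohort(cfg)
  cats <- classify_concordance(coh$nurse_triage, coh$esc_triage)
  emp <- table(factor(cats, levels = concordance_categories())) / nrow(coh)
  induced <- induced_category_rates(k)
  expect_true(all(abs(as.numeric(emp) - induced) <= 0.005))
})
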