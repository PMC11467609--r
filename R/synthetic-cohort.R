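#' The fifteen chief symptoms of the validation study
#'
#' Symptom labels and per-symptom numbers of completed matched
#' assessments (877 in total) as collected in the multi-centre walk-in
#' primary-care study the package models.
#'
#' @return A data frame with columns `symptom` and `n`.
#' @export
#' @examples
#' sum(table1_symptoms()$n) # 877
table1_symptoms <- function() {
  data.frame(
    symptom = c(
      "Anal region symptom", "Cough", "Dental or oral symptoms or trauma",
      "Diarrhea", "Discharge from the eye, watery or reddish eye",
      "Headache", "Heartburn", "Knee symptom or injury",
      "Lower back pain or injury", "Painful or blocked ear",
      "Respiratory tract infection", "Sexually transmitted disease",
      "Shoulder pain, stiffness, or injury",
      "Sore throat or throat symptom", "Urinary tract infection"),
    n = c(41L, 71L, 62L, 21L, 65L, 41L, 24L, 55L, 65L, 81L, 104L, 39L,
          47L, 101L, 60L),
    stringsAsFactors = FALSE)
}

kernel_offsets <- function() -5:5

#' Mis-triage kernel
#'
#' For each nurse triage level, a categorical distribution over the
#' checker-minus-nurse rank offset `d` in `-5..+5`. Offsets that would
#' leave the six-level scale are zeroed and each row renormalised, so a
#' kernel is always usable for any nurse level.
#'
#' @param probs A 6 x 11 numeric matrix (rows = nurse levels in
#'   [triage_levels()] order, columns = offsets -5..+5) of non-negative
#'   weights, or a single 11-long offset weight vector applied to every
#'   row.
#' @return An object of class `mistriage_kernel`: the row-stochastic
#'   truncated matrix.
#' @export
#' @examples
#' identity_kernel() # all mass on offset 0
mistriage_kernel <- function(probs) {
  lv <- triage_levels()
  off <- kernel_offsets()
  if (is.vector(probs) && length(probs) == length(off)) {
    probs <- matrix(probs, nrow = length(lv), ncol = length(off),
                    byrow = TRUE)
  }
  if (!is.matrix(probs) || !all(dim(probs) == c(length(lv), length(off)))) {
    stop("probs must be a 6 x 11 matrix (levels x offsets -5..+5)",
         call. = FALSE)
  }
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop("kernel weights must be finite and non-negative", call. = FALSE)
  }
  dimnames(probs) <- list(lv, as.character(off))
  for (i in seq_along(lv)) {
    rank <- i - 1L
    valid <- rank + off >= 0L & rank + off <= 5L
    probs[i, !valid] <- 0
    s <- sum(probs[i, ])
    if (s <= 0) {
      stop("kernel row for ", lv[i],
           " has no mass on offsets that stay on the scale", call. = FALSE)
    }
    probs[i, ] <- probs[i, ] / s
  }
  structure(probs, class = c("mistriage_kernel", "matrix"))
}

#' @rdname mistriage_kernel
#' @export
identity_kernel <- function() {
  w <- numeric(length(kernel_offsets()))
  w[kernel_offsets() == 0L] <- 1
  mistriage_kernel(w)
}

#' Cohort generator configuration
#'
#' Bundles and validates everything [generate_cohort()] needs. The
#' defaults emulate the study conditions: the fifteen chief symptoms with
#' their observed sizes (877 cases), a nurse "changed triage after seeing
#' the checker" rate of 19/877, a doctor-consultation rate of 80/877, and
#' a 3-in-10 walk-in arrival rate.
#'
#' @param symptoms Data frame with `symptom` and `n` columns; default
#'   [table1_symptoms()].
#' @param nurse_level_probs Probabilities of the six nurse levels in
#'   [triage_levels()] order (the study reports no nurse-level marginal;
#'   the default is uniform and analyses should configure it explicitly).
#' @param kernel A [mistriage_kernel()]; default [identity_kernel()].
#' @param p_nurse_changed,p_doctor_consulted,p_walk_in Bernoulli rates of
#'   the per-case flags.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(symptoms = table1_symptoms(),
                          nurse_level_probs = rep(1 / 6, 6),
                          kernel = identity_kernel(),
                          p_nurse_changed = 19 / 877,
                          p_doctor_consulted = 80 / 877,
                          p_walk_in = 0.3,
                          seed = 1L) {
  problems <- character(0)
  if (!is.data.frame(symptoms) ||
      !all(c("symptom", "n") %in% names(symptoms)) ||
      anyDuplicated(symptoms$symptom) ||
      any(symptoms$n < 0) || any(symptoms$n != round(symptoms$n))) {
    problems <- c(problems,
                  "symptoms: need unique labels and integer n >= 0")
  }
  if (length(nurse_level_probs) != 6 || any(nurse_level_probs < 0) ||
      abs(sum(nurse_level_probs) - 1) > 1e-9) {
    problems <- c(problems,
                  "nurse_level_probs: six non-negative values summing to 1")
  }
  if (!inherits(kernel, "mistriage_kernel")) {
    problems <- c(problems, "kernel: not a mistriage_kernel")
  }
  for (p in c(p_nurse_changed = p_nurse_changed,
              p_doctor_consulted = p_doctor_consulted,
              p_walk_in = p_walk_in)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      problems <- c(problems, "flag probabilities must lie in [0, 1]")
      break
    }
  }
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    problems <- c(problems, "seed: single integer required")
  }
  if (length(problems) > 0) {
    stop("invalid cohort configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  structure(list(symptoms = symptoms,
                 nurse_level_probs = as.numeric(nurse_level_probs),
                 kernel = kernel,
                 p_nurse_changed = p_nurse_changed,
                 p_doctor_consulted = p_doctor_consulted,
                 p_walk_in = p_walk_in,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic paired-triage cohort
#'
#' For each configured symptom, draws nurse levels from the nurse-level
#' distribution, then checker levels by adding a rank offset drawn from
#' the mis-triage kernel row of the nurse level; per-case flags are drawn
#' independently. Each symptom uses its own RNG substream (derived from
#' the seed and a stable hash of the label), so adding or removing a
#' symptom does not perturb the draws of the others. The caller's global
#' RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per case and columns `case_id`,
#'   `symptom`, `nurse_triage`, `esc_triage`, `nurse_changed`,
#'   `doctor_consulted`, `arrival`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' nrow(cohort) # 877
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config object", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  lv <- triage_levels()
  off <- kernel_offsets()
  pieces <- vector("list", nrow(config$symptoms))
  for (i in seq_len(nrow(config$symptoms))) {
    label <- config$symptoms$symptom[i]
    n <- config$symptoms$n[i]
    set.seed((config$seed + stable_hash(label)) %% 2147483647)
    if (n == 0L) next
    nurse <- sample(lv, n, replace = TRUE, prob = config$nurse_level_probs)
    rank <- match(nurse, lv) - 1L
    d <- integer(n)
    for (j in seq_along(lv)) {
      idx <- which(rank == j - 1L)
      if (length(idx) > 0) {
        d[idx] <- sample(off, length(idx), replace = TRUE,
                         prob = config$kernel[j, ])
      }
    }
    esc <- lv[rank + d + 1L]
    slug <- gsub("[^a-z0-9]+", "_", tolower(label))
    pieces[[i]] <- data.frame(
      case_id = sprintf("%s_%04d", slug, seq_len(n)),
      symptom = label,
      nurse_triage = nurse,
      esc_triage = esc,
      nurse_changed = stats::runif(n) < config$p_nurse_changed,
      doctor_consulted = stats::runif(n) < config$p_doctor_consulted,
      arrival = ifelse(stats::runif(n) < config$p_walk_in,
                       "walk_in", "telephone"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(case_id = character(0), symptom = character(0),
                      nurse_triage = character(0),
                      esc_triage = character(0),
                      nurse_changed = logical(0),
                      doctor_consulted = logical(0),
                      arrival = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Exact concordance-category rates induced by a kernel
#'
#' Sums kernel mass over the category map of [classify_concordance()],
#' weighted by the nurse-level distribution: the exact distribution of
#' categories a cohort generated with this kernel converges to.
#'
#' @param kernel A [mistriage_kernel()].
#' @param nurse_level_probs Nurse-level probabilities in
#'   [triage_levels()] order.
#' @param urgent Urgent level set.
#' @return Named numeric vector over [concordance_categories()], summing
#'   to 1.
#' @export
induced_category_rates <- function(kernel,
                                   nurse_level_probs = rep(1 / 6, 6),
                                   urgent = default_urgent_levels()) {
  lv <- triage_levels()
  off <- kernel_offsets()
  rates <- stats::setNames(numeric(5), concordance_categories())
  for (i in seq_along(lv)) {
    if (nurse_level_probs[i] == 0) next
    rank <- i - 1L
    for (k in seq_along(off)) {
      p <- kernel[i, k]
      if (p == 0) next
      esc_rank <- rank + off[k]
      cat <- classify_concordance(lv[i], lv[esc_rank + 1L], urgent = urgent)
      rates[cat] <- rates[cat] + nurse_level_probs[i] * p
    }
  }
  rates
}

#' Calibrate a mis-triage kernel to target concordance-category rates
#'
#' Constructs a kernel whose induced category distribution (see
#' [induced_category_rates()]) matches the requested rates exactly, given
#' a nurse-level distribution. Categories are allocated in safety-first
#' priority order (potentially unsafe, safe-under, overly conservative,
#' conservative-suitable, exact): each category's mass is spread over the
#' nurse levels that can express it in proportion to their remaining
#' capacity, then uniformly over that level's offsets in the category.
#' Infeasible targets (e.g. unsafe mass requested while the nurse-level
#' distribution puts no mass on urgent levels) raise an error naming the
#' category and the mass available.
#'
#' @param target_rates Named numeric vector over (a subset of)
#'   [concordance_categories()], summing to 1; omitted categories get 0.
#' @param nurse_level_probs Nurse-level probabilities in
#'   [triage_levels()] order.
#' @param urgent Urgent level set.
#' @return A [mistriage_kernel()].
#' @export
#' @examples
#' k <- calibrate_kernel(c(EXACT = 1))
#' induced_category_rates(k)["EXACT"] # 1
calibrate_kernel <- function(target_rates,
                             nurse_level_probs = rep(1 / 6, 6),
                             urgent = default_urgent_levels()) {
  cats <- concordance_categories()
  targets <- stats::setNames(numeric(5), cats)
  if (is.null(names(target_rates)) ||
      !all(names(target_rates) %in% cats)) {
    stop("target_rates must be named with concordance categories",
         call. = FALSE)
  }
  targets[names(target_rates)] <- target_rates
  if (any(targets < 0) || abs(sum(targets) - 1) > 1e-9) {
    stop("target rates must be non-negative and sum to 1", call. = FALSE)
  }
  if (length(nurse_level_probs) != 6 || any(nurse_level_probs < 0) ||
      abs(sum(nurse_level_probs) - 1) > 1e-9) {
    stop("nurse_level_probs must be six non-negative values summing to 1",
         call. = FALSE)
  }
  lv <- triage_levels()
  off <- kernel_offsets()
  # category of each feasible (level, offset) cell
  cellcat <- matrix(NA_character_, length(lv), length(off),
                    dimnames = list(lv, as.character(off)))
  for (i in seq_along(lv)) {
    rank <- i - 1L
    for (k in seq_along(off)) {
      r2 <- rank + off[k]
      if (r2 >= 0L && r2 <= 5L) {
        cellcat[i, k] <- classify_concordance(lv[i], lv[r2 + 1L],
                                              urgent = urgent)
      }
    }
  }
  kern <- matrix(0, length(lv), length(off),
                 dimnames = list(lv, as.character(off)))
  cap <- rep(1, length(lv))
  priority <- c("POTENTIALLY_UNSAFE", "SAFE_UNDER", "OVERLY_CONSERVATIVE",
                "CONSERVATIVE_SUITABLE", "EXACT")
  for (cat in priority) {
    t_c <- targets[cat]
    if (t_c == 0) next
    feas <- vapply(seq_along(lv), function(i) {
      nurse_level_probs[i] > 0 && any(cellcat[i, ] == cat, na.rm = TRUE)
    }, logical(1))
    avail <- sum(nurse_level_probs[feas] * cap[feas])
    if (t_c > avail + 1e-12) {
      stop("infeasible target: category ", cat, " requests mass ",
           signif(t_c, 6), " but at most ", signif(avail, 6),
           " is reachable under the given nurse-level distribution",
           call. = FALSE)
    }
    for (i in which(feas)) {
      x <- t_c * cap[i] / avail
      cells <- which(cellcat[i, ] == cat)
      kern[i, cells] <- kern[i, cells] + x / length(cells)
      cap[i] <- cap[i] - x
    }
  }
  # levels with zero nurse probability never fire; give them an identity
  # row so the kernel stays row-stochastic
  for (i in seq_along(lv)) {
    if (nurse_level_probs[i] == 0 || sum(kern[i, ]) == 0) {
      if (sum(kern[i, ]) == 0) kern[i, off == 0L] <- 1
    }
  }
  mistriage_kernel(kern)
}

#' Write or read a cohort CSV
#'
#' The on-disk format is a plain comma-separated file with header
#' `case_id, symptom, nurse_triage, esc_triage, nurse_changed,
#' doctor_consulted, arrival`; level tokens are written upper-case and
#' read case-insensitively.
#'
#' @param records A cohort data frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the validated cohort data frame.
#' @export
write_cohort <- function(records, path) {
  validate_cohort(records)
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in c("nurse_changed", "doctor_consulted")) {
    if (col %in% names(df)) df[[col]] <- toupper(df[[col]]) == "TRUE"
  }
  df$nurse_triage <- parse_triage_level(df$nurse_triage)
  df$esc_triage <- parse_triage_level(df$esc_triage)
  validate_cohort(df)
  df
}
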