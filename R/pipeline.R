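#' Validate a cohort data frame
#'
#' Checks the schema (required columns), level tokens, unique case ids,
#' flag types and, when a symptom list is supplied, symptom membership.
#'
#' @param records Cohort data frame.
#' @param symptoms Optional character vector of allowed symptom labels
#'   (e.g. `table1_symptoms()$symptom`); `NULL` accepts any label.
#' @return `records`, invisibly, after canonicalising level tokens.
#' @export
validate_cohort <- function(records, symptoms = NULL) {
  required <- c("case_id", "symptom", "nurse_triage", "esc_triage",
                "nurse_changed", "doctor_consulted")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_triage_level(records$nurse_triage)
  parse_triage_level(records$esc_triage)
  if (anyDuplicated(records$case_id)) {
    stop("case_id values must be unique within a cohort", call. = FALSE)
  }
  if (!is.logical(records$nurse_changed) ||
      !is.logical(records$doctor_consulted)) {
    stop("nurse_changed and doctor_consulted must be logical",
         call. = FALSE)
  }
  if (!is.null(symptoms)) {
    bad <- setdiff(unique(records$symptom), symptoms)
    if (length(bad) > 0) {
      stop("unknown symptom label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(records)
}

#' Build a cohort from explicit (nurse, checker) pairs
#'
#' Convenience constructor for engineered cohorts used in tests and
#' audits; flags default to `FALSE` and arrival to `"telephone"`.
#'
#' @param nurse,esc Character vectors of level tokens (equal length).
#' @param symptom Symptom label(s), recycled.
#' @param nurse_changed,doctor_consulted Logical flags, recycled.
#' @param arrival Arrival tokens, recycled.
#' @return A cohort data frame.
#' @export
cohort_from_pairs <- function(nurse, esc, symptom = "engineered",
                              nurse_changed = FALSE,
                              doctor_consulted = FALSE,
                              arrival = "telephone") {
  n <- length(nurse)
  if (length(esc) != n) {
    stop("nurse and esc must have equal length", call. = FALSE)
  }
  df <- data.frame(
    case_id = sprintf("case_%05d", seq_len(n)),
    symptom = rep_len(symptom, n),
    nurse_triage = parse_triage_level(nurse),
    esc_triage = parse_triage_level(esc),
    nurse_changed = rep_len(nurse_changed, n),
    doctor_consulted = rep_len(doctor_consulted, n),
    arrival = rep_len(arrival, n),
    stringsAsFactors = FALSE)
  validate_cohort(df)
  df
}

# representative (nurse, esc) pair realising each category
category_pair <- function(category) {
  switch(category,
         EXACT = c("P3", "P3"),
         CONSERVATIVE_SUITABLE = c("P4", "P3"),
         OVERLY_CONSERVATIVE = c("SELF_CARE", "P3"),
         SAFE_UNDER = c("P4", "SELF_CARE"),
         POTENTIALLY_UNSAFE = c("P1", "P3"),
         stop("unknown category: ", category, call. = FALSE))
}

#' Build a cohort realising exact concordance-category counts
#'
#' Produces a deterministic cohort whose five category counts equal the
#' given totals, using one representative level pair per category. Useful
#' for reconstructing published aggregate results from their printed
#' counts.
#'
#' @param counts Named integer vector over (a subset of)
#'   [concordance_categories()].
#' @param symptom Symptom label for all records.
#' @return A cohort data frame with `sum(counts)` rows.
#' @export
#' @examples
#' coh <- cohort_from_category_counts(c(EXACT = 3, SAFE_UNDER = 2))
#' table(classify_concordance(coh$nurse_triage, coh$esc_triage))
cohort_from_category_counts <- function(counts, symptom = "engineered") {
  if (is.null(names(counts)) ||
      !all(names(counts) %in% concordance_categories())) {
    stop("counts must be named with concordance categories", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  nurse <- character(0)
  esc <- character(0)
  for (cat in names(counts)) {
    pr <- category_pair(cat)
    nurse <- c(nurse, rep(pr[1], counts[[cat]]))
    esc <- c(esc, rep(pr[2], counts[[cat]]))
  }
  cohort_from_pairs(nurse, esc, symptom = symptom)
}

#' Summarise the concordance of one symptom's assessments
#'
#' One row of the per-symptom results table: category counts, safe and
#' exact-match proportions with exact binomial confidence intervals, the
#' urgency-dichotomised confusion matrix and its PPV/NPV/MCC.
#'
#' @param records Cohort data frame containing a single symptom.
#' @param conf.level Confidence level of the intervals.
#' @param urgent Urgent level set.
#' @param strict Strict safety mode, see [is_safe()].
#' @return A one-row data frame (see column list in the package report
#'   writers); proportions are unrounded.
#' @export
summarize_symptom <- function(records, conf.level = 0.95,
                              urgent = default_urgent_levels(),
                              strict = FALSE) {
  validate_cohort(records)
  if (nrow(records) == 0) {
    stop("summarize_symptom needs a non-empty record set", call. = FALSE)
  }
  if (length(unique(records$symptom)) != 1L) {
    stop("summarize_symptom expects records for a single symptom; got: ",
         paste(unique(records$symptom), collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  cats <- classify_concordance(records$nurse_triage, records$esc_triage,
                               urgent = urgent)
  counts <- vapply(concordance_categories(),
                   function(cc) sum(cats == cc), numeric(1))
  safe_count <- sum(is_safe(records$nurse_triage, records$esc_triage,
                            strict = strict, urgent = urgent))
  exact_count <- counts[["EXACT"]]
  safe_ci <- clopper_pearson_ci(safe_count, n, conf.level)
  exact_ci <- clopper_pearson_ci(exact_count, n, conf.level)
  m <- build_confusion_matrix(records, urgent = urgent)
  cbind(
    data.frame(symptom = records$symptom[1], n = n,
               safe_count = safe_count,
               safe_pct = 100 * safe_ci$estimate,
               safe_lower = 100 * safe_ci$lower,
               safe_upper = 100 * safe_ci$upper,
               exact_count = exact_count,
               exact_pct = 100 * exact_ci$estimate,
               exact_lower = 100 * exact_ci$lower,
               exact_upper = 100 * exact_ci$upper,
               exact = counts[["EXACT"]],
               conservative_suitable = counts[["CONSERVATIVE_SUITABLE"]],
               overly_conservative = counts[["OVERLY_CONSERVATIVE"]],
               safe_under = counts[["SAFE_UNDER"]],
               potentially_unsafe = counts[["POTENTIALLY_UNSAFE"]],
               stringsAsFactors = FALSE),
    metrics_row(m))
}

#' Over/under-triage ratio per 100 suitable evaluations
#'
#' Expresses the category counts as "100 suitable : x overtriage : y
#' undertriage". By default suitable = exact + conservative-but-suitable,
#' overtriage = overly conservative, undertriage = safe-under +
#' potentially-unsafe; the grouping is configurable.
#'
#' @param category_counts Named counts over [concordance_categories()].
#' @param suitable,over,under Category labels making up each group.
#' @return Named numeric triple `c(suitable = 100, over = , under = )`,
#'   or all-`NA` when the suitable count is 0.
#' @export
#' @examples
#' triage_ratio(c(EXACT = 150, CONSERVATIVE_SUITABLE = 50,
#'                OVERLY_CONSERVATIVE = 50, SAFE_UNDER = 40,
#'                POTENTIALLY_UNSAFE = 4))
triage_ratio <- function(category_counts,
                         suitable = c("EXACT", "CONSERVATIVE_SUITABLE"),
                         over = "OVERLY_CONSERVATIVE",
                         under = c("SAFE_UNDER", "POTENTIALLY_UNSAFE")) {
  get_sum <- function(labels) {
    sum(category_counts[intersect(labels, names(category_counts))],
        na.rm = TRUE)
  }
  s <- get_sum(suitable)
  if (s == 0) {
    return(c(suitable = NA_real_, over = NA_real_, under = NA_real_))
  }
  c(suitable = 100, over = 100 * get_sum(over) / s,
    under = 100 * get_sum(under) / s)
}

#' Tally the nurse-form flags of a cohort
#'
#' Counts of the three per-case flags collected on the nurse's study
#' form: triage changed after seeing the checker, doctor consulted, and
#' walk-in arrival.
#'
#' @param records Cohort data frame.
#' @return Named numeric vector `c(changed = , consulted = , walk_in = )`.
#' @export
tally_nurse_form <- function(records) {
  c(changed = sum(records$nurse_changed),
    consulted = sum(records$doctor_consulted),
    walk_in = if ("arrival" %in% names(records)) {
      sum(records$arrival == "walk_in")
    } else 0)
}

#' Full study analysis of a paired-triage cohort
#'
#' Produces per-symptom summaries, a pooled total row, overall
#' sensitivity and specificity, the acute (nurse-urgent) subset's
#' exact-match accuracy, the non-urgent subset's care-vs-self-care
#' agreement, the over/under-triage ratio and the nurse-form tallies.
#'
#' The non-urgent "match" is agreement on the dichotomy (self-care
#' vs any professional-care level) between nurse and checker, the only
#' care-seeking dichotomy available below the urgency boundary.
#'
#' @param records Cohort data frame.
#' @inheritParams summarize_symptom
#' @return An object of class `study_report`.
#' @export
summarize_study <- function(records, conf.level = 0.95,
                            urgent = default_urgent_levels(),
                            strict = FALSE) {
  validate_cohort(records)
  empty_subset <- list(n = 0, count = 0, prop = NA_real_,
                       lower = NA_real_, upper = NA_real_)
  if (nrow(records) == 0) {
    return(structure(list(per_symptom = NULL, total = NULL,
                          sens = NA_real_, spec = NA_real_,
                          urgent_subset = empty_subset,
                          non_urgent_subset = empty_subset,
                          ratio = triage_ratio(c(EXACT = 0)),
                          nurse_form = c(changed = 0, consulted = 0,
                                         walk_in = 0),
                          conf.level = conf.level, urgent = urgent,
                          strict = strict),
                     class = "study_report"))
  }
  per <- do.call(rbind, lapply(split(records, records$symptom),
                               summarize_symptom, conf.level = conf.level,
                               urgent = urgent, strict = strict))
  per <- per[order(per$symptom), , drop = FALSE]
  rownames(per) <- NULL
  total_rec <- records
  total_rec$symptom <- "In total"
  total <- summarize_symptom(total_rec, conf.level = conf.level,
                             urgent = urgent, strict = strict)
  nurse_urgent <- is_urgent(records$nurse_triage, urgent)
  subset_summary <- function(rows, hit) {
    n <- sum(rows)
    k <- sum(hit & rows)
    if (n == 0) return(empty_subset)
    ci <- clopper_pearson_ci(k, n, conf.level)
    list(n = n, count = k, prop = 100 * ci$estimate,
         lower = 100 * ci$lower, upper = 100 * ci$upper)
  }
  exact_pair <- records$nurse_triage == records$esc_triage
  care_agree <- (records$nurse_triage == "SELF_CARE") ==
    (records$esc_triage == "SELF_CARE")
  counts <- stats::setNames(
    as.numeric(total[, c("exact", "conservative_suitable",
                         "overly_conservative", "safe_under",
                         "potentially_unsafe")]),
    concordance_categories())
  structure(list(
    per_symptom = per,
    total = total,
    sens = total$sens,
    spec = total$spec,
    urgent_subset = subset_summary(nurse_urgent, exact_pair),
    non_urgent_subset = subset_summary(!nurse_urgent, care_agree),
    ratio = triage_ratio(counts),
    nurse_form = tally_nurse_form(records),
    conf.level = conf.level, urgent = urgent, strict = strict),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  if (is.null(x$total)) {
    cat("Study report: empty cohort\n")
    return(invisible(x))
  }
  t <- x$total
  cat("Study report:", t$n, "paired assessments,",
      nrow(x$per_symptom), "symptom(s)\n")
  cat(sprintf("  safe advice: %s%% (%s-%s), %d/%d\n",
              fmt_num(t$safe_pct), fmt_num(t$safe_lower),
              fmt_num(t$safe_upper), t$safe_count, t$n))
  cat(sprintf("  exact match: %s%% (%s-%s), %d/%d\n",
              fmt_num(t$exact_pct), fmt_num(t$exact_lower),
              fmt_num(t$exact_upper), t$exact_count, t$n))
  cat(sprintf("  sensitivity %s%%, specificity %s%% (urgent dichotomy)\n",
              fmt_num(100 * x$sens), fmt_num(100 * x$spec)))
  cat(sprintf("  ratio suitable:over:under = 100:%s:%s\n",
              fmt_num(x$ratio[["over"]], 0),
              fmt_num(x$ratio[["under"]], 0)))
  invisible(x)
}

report_table <- function(report, digits = 1) {
  rows <- rbind(report$per_symptom, report$total)
  data.frame(
    symptom = rows$symptom,
    n = rows$n,
    safe_pct_ci = fmt_pct_ci(rows$safe_pct, rows$safe_lower,
                             rows$safe_upper, digits),
    exact_pct_ci = fmt_pct_ci(rows$exact_pct, rows$exact_lower,
                              rows$exact_upper, digits),
    ppv = fmt_num(100 * rows$ppv, digits),
    npv = fmt_num(100 * rows$npv, digits),
    mcc = fmt_num(rows$mcc, 3),
    stringsAsFactors = FALSE)
}

#' Serialise a study report
#'
#' Three formats: `"csv"` mirrors the published per-symptom table (one
#' row per symptom plus the total row, percentage cells formatted as
#' `"97.6 (96.4-98.5)"`); `"json"` is lossless (unrounded values and all
#' counts; `NA` statistics serialise as `null`); `"markdown"` is a human
#' view. A JSON report re-read with [report_from_json()] serialises back
#' to the identical JSON.
#'
#' @param report A `study_report`.
#' @param format One of `"csv"`, `"json"`, `"markdown"`.
#' @param path Optional output file; when `NULL` the serialised text is
#'   returned.
#' @return The serialised text (character), invisibly when written to
#'   `path`.
#' @export
write_report <- function(report, format = c("csv", "json", "markdown"),
                         path = NULL) {
  if (!inherits(report, "study_report")) {
    stop("report must be a study_report", call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "csv") {
    tab <- report_table(report)
    con <- textConnection("csv_out", "w", local = TRUE)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    text <- paste0(paste(csv_out, collapse = "\n"), "\n")
  } else if (format == "json") {
    payload <- list(
      per_symptom = report$per_symptom,
      total = report$total,
      sens = report$sens, spec = report$spec,
      urgent_subset = report$urgent_subset,
      non_urgent_subset = report$non_urgent_subset,
      ratio = as.list(report$ratio),
      nurse_form = as.list(report$nurse_form),
      conf.level = report$conf.level,
      urgent = report$urgent,
      strict = report$strict)
    text <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                          digits = NA, na = "null",
                                          pretty = TRUE))
  } else {
    tab <- report_table(report)
    header <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    body <- apply(tab, 1, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    })
    nf <- report$nurse_form
    text <- paste(c(
      "# Triage concordance report", "",
      header, sep, body, "",
      sprintf("Sensitivity %s%%, specificity %s%% (urgent dichotomy).",
              fmt_num(100 * report$sens), fmt_num(100 * report$spec)),
      sprintf("Ratio 100 suitable : %s overtriage : %s undertriage.",
              fmt_num(report$ratio[["over"]], 0),
              fmt_num(report$ratio[["under"]], 0)),
      sprintf("Nurse changed triage %d times; doctor consulted %d times.",
              nf[["changed"]], nf[["consulted"]]), ""),
      collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Rebuild a study report from its JSON serialisation
#'
#' @param json JSON text or a path to a JSON file produced by
#'   [write_report()] with `format = "json"`.
#' @return A `study_report`.
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  as_subset <- function(s) {
    s$prop <- if (is.null(s$prop)) NA_real_ else s$prop
    s$lower <- if (is.null(s$lower)) NA_real_ else s$lower
    s$upper <- if (is.null(s$upper)) NA_real_ else s$upper
    s
  }
  structure(list(
    per_symptom = x$per_symptom,
    total = x$total,
    sens = if (is.null(x$sens)) NA_real_ else x$sens,
    spec = if (is.null(x$spec)) NA_real_ else x$spec,
    urgent_subset = as_subset(x$urgent_subset),
    non_urgent_subset = as_subset(x$non_urgent_subset),
    ratio = unlist(x$ratio),
    nurse_form = unlist(x$nurse_form),
    conf.level = x$conf.level,
    urgent = x$urgent,
    strict = x$strict),
    class = "study_report")
}
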