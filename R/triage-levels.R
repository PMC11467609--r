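#' The ordinal triage scale
#'
#' The scale combines the Finnish emergency-care criteria P0 (treat
#' immediately) through P4 (doctor within 72 h) with a single self-care
#' level. The referral sub-classes L2-L4 all prescribe self-care with
#' instructions and carry no analytic distinction, so they are collapsed
#' into one `SELF_CARE` token.
#'
#' @return Character vector of the six level tokens ordered from least
#'   urgent (`SELF_CARE`, rank 0) to most urgent (`P0`, rank 5).
#' @export
#' @examples
#' triage_levels()
triage_levels <- function() {
  c("SELF_CARE", "P4", "P3", "P2", "P1", "P0")
}

#' Urgent levels under the default urgency boundary
#'
#' P0-P2 are emergency-centre ("on-call duty") levels; P3 and P4 are
#' office-hours referrals and self-care is the non-urgent extreme. The
#' boundary is exposed so alternative dichotomies can be explored.
#'
#' @return Character vector of level tokens counted as urgent.
#' @export
default_urgent_levels <- function() {
  c("P0", "P1", "P2")
}

#' Parse triage level tokens
#'
#' Tokens are matched case-insensitively and returned in canonical
#' upper-case form. Unknown tokens raise an error naming the offenders.
#'
#' @param x Character vector of level tokens.
#' @return Character vector of canonical tokens, same length as `x`.
#' @export
#' @examples
#' parse_triage_level(c("p0", "Self_Care"))
parse_triage_level <- function(x) {
  if (length(x) == 0L) return(character(0))
  tok <- toupper(trimws(as.character(x)))
  bad <- !(tok %in% triage_levels()) & !is.na(tok)
  if (any(bad) || anyNA(tok)) {
    offending <- unique(c(tok[bad], if (anyNA(tok)) NA_character_))
    stop("unknown triage level token(s): ",
         paste(offending, collapse = ", "), call. = FALSE)
  }
  tok
}

#' Numeric urgency rank of a triage level
#'
#' Ranks run from 0 (`SELF_CARE`) to 5 (`P0`); a higher rank means more
#' urgent care.
#'
#' @param level Character vector of level tokens (parsed leniently).
#' @return Integer vector of ranks in `0:5`.
#' @export
#' @examples
#' urgency_rank(c("P0", "P3", "SELF_CARE"))
urgency_rank <- function(level) {
  match(parse_triage_level(level), triage_levels()) - 1L
}

#' Is a triage level urgent?
#'
#' @param level Character vector of level tokens.
#' @param urgent Character vector defining the urgent set; defaults to
#'   [default_urgent_levels()].
#' @return Logical vector.
#' @export
is_urgent <- function(level, urgent = default_urgent_levels()) {
  parse_triage_level(level) %in% parse_triage_level(urgent)
}

#' The five concordance categories
#'
#' @return Character vector of category labels, ordered from exact match
#'   to potentially unsafe.
#' @export
concordance_categories <- function() {
  c("EXACT", "CONSERVATIVE_SUITABLE", "OVERLY_CONSERVATIVE",
    "SAFE_UNDER", "POTENTIALLY_UNSAFE")
}

#' Classify a (nurse, checker) triage pair into a concordance category
#'
#' Every pair falls into exactly one of five categories. With
#' `d = urgency_rank(esc) - urgency_rank(nurse)`:
#'
#' * `POTENTIALLY_UNSAFE` - the nurse assessed the case as urgent but the
#'   checker as non-urgent or self-care. This safety rule takes precedence
#'   over the level-difference rules (a pair like (P2, P3) crosses the
#'   urgency boundary even though `d = -1`).
#' * `EXACT` - `d = 0`.
#' * `CONSERVATIVE_SUITABLE` - `d = +1` (overly conservative but suitable).
#' * `OVERLY_CONSERVATIVE` - `d = +2`; more extreme overtriage
#'   (`d >= +3`) is folded in by default as the same phenomenon.
#' * `SAFE_UNDER` - `d <= -1` without crossing the urgency boundary
#'   (safe but under-conservative).
#'
#' @param nurse,esc Character vectors of level tokens (recycled to a
#'   common length); the nurse is the gold standard.
#' @param urgent Urgent level set, see [is_urgent()].
#' @param fold_extreme_overtriage If `TRUE` (default) pairs with
#'   `d >= +3` are classified `OVERLY_CONSERVATIVE`; if `FALSE` they are
#'   returned as `NA` since the category definitions only name `d = +2`.
#' @return Character vector of category labels.
#' @export
#' @examples
#' classify_concordance("P3", "P2")        # CONSERVATIVE_SUITABLE
#' classify_concordance("P1", "SELF_CARE") # POTENTIALLY_UNSAFE
classify_concordance <- function(nurse, esc,
                                 urgent = default_urgent_levels(),
                                 fold_extreme_overtriage = TRUE) {
  nurse <- parse_triage_level(nurse)
  esc <- parse_triage_level(esc)
  k <- max(length(nurse), length(esc))
  if (k == 0L) return(character(0))
  nurse <- rep_len(nurse, k)
  esc <- rep_len(esc, k)
  d <- urgency_rank(esc) - urgency_rank(nurse)
  unsafe <- is_urgent(nurse, urgent) & !is_urgent(esc, urgent)
  out <- character(k)
  out[unsafe] <- "POTENTIALLY_UNSAFE"
  rest <- !unsafe
  out[rest & d == 0L] <- "EXACT"
  out[rest & d == 1L] <- "CONSERVATIVE_SUITABLE"
  if (fold_extreme_overtriage) {
    out[rest & d >= 2L] <- "OVERLY_CONSERVATIVE"
  } else {
    out[rest & d == 2L] <- "OVERLY_CONSERVATIVE"
    out[rest & d >= 3L] <- NA_character_
  }
  out[rest & d <= -1L] <- "SAFE_UNDER"
  out
}

#' Is a checker assessment safe relative to the nurse's?
#'
#' In the default mode an assessment is unsafe exactly when the pair is
#' `POTENTIALLY_UNSAFE` (urgent nurse, non-urgent checker), so a study's
#' unsafe count equals its urgency-crossing count. The strict mode
#' additionally marks pairs two or more levels under-triaged as unsafe,
#' the literal "at most one level less urgent" reading, even when no
#' urgency boundary is crossed.
#'
#' @inheritParams classify_concordance
#' @param strict Logical; enable the strict one-level rule.
#' @return Logical vector; `TRUE` when safe.
#' @export
is_safe <- function(nurse, esc, strict = FALSE,
                    urgent = default_urgent_levels()) {
  cat <- classify_concordance(nurse, esc, urgent = urgent)
  safe <- cat != "POTENTIALLY_UNSAFE"
  if (strict) {
    d <- urgency_rank(rep_len(parse_triage_level(esc), length(cat))) -
      urgency_rank(rep_len(parse_triage_level(nurse), length(cat)))
    safe <- safe & d >= -1L
  }
  safe
}
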