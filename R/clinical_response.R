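#' Mayo score assessment
#'
#' Bundles the three clinical Mayo subscores (stool frequency, rectal
#' bleeding, physician global assessment, each 0-3) with the optional
#' endoscopic subscore. The endoscopic grade 1 is split into 1a (erythema
#' without friability) and 1b (with friability); both carry numeric value 1
#' in the full Mayo sum, but 1b > 1a on the ordered severity scale
#' 0 < 1a < 1b < 2 < 3, so a change from 1b to 1a counts as a one-step
#' endoscopic improvement.
#'
#' @param stool_frequency,rectal_bleeding,physician_global integers 0-3.
#' @param endoscopic one of `"0"`, `"1a"`, `"1b"`, `"2"`, `"3"`, or `NA` for
#'   visits assessed by partial Mayo only.
#' @param week integer study week of the assessment.
#' @return a `mayo_assessment` list.
#' @export
mayo_assessment <- function(stool_frequency, rectal_bleeding, physician_global,
                            endoscopic = NA_character_, week = NA_integer_) {
  sub <- c(stool_frequency = stool_frequency, rectal_bleeding = rectal_bleeding,
           physician_global = physician_global)
  if (any(is.na(sub)) || any(sub < 0 | sub > 3) || any(sub != round(sub)))
    stop("clinical Mayo subscores must be integers in 0-3")
  endoscopic <- as.character(endoscopic)
  if (!is.na(endoscopic) && !endoscopic %in% names(.endo_rank))
    stop("endoscopic subscore must be one of 0, 1a, 1b, 2, 3")
  structure(list(stool_frequency = as.integer(stool_frequency),
                 rectal_bleeding = as.integer(rectal_bleeding),
                 physician_global = as.integer(physician_global),
                 endoscopic = endoscopic, week = as.integer(week)),
            class = "mayo_assessment")
}

.endo_rank <- c("0" = 1L, "1a" = 2L, "1b" = 3L, "2" = 4L, "3" = 5L)
.endo_value <- c("0" = 0L, "1a" = 1L, "1b" = 1L, "2" = 2L, "3" = 3L)

#' Partial Mayo score
#'
#' Sum of the three clinical subscores, range 0-9.
#'
#' @param a a [mayo_assessment()].
#' @return integer in 0-9.
#' @export
partial_mayo <- function(a) {
  a$stool_frequency + a$rectal_bleeding + a$physician_global
}

#' Full Mayo score
#'
#' Partial Mayo plus the numeric value of the endoscopic subscore (1a and 1b
#' both count as 1).
#'
#' @param a a [mayo_assessment()] with an endoscopic subscore.
#' @return integer in 0-12.
#' @export
full_mayo <- function(a) {
  if (is.na(a$endoscopic)) stop("endoscopic subscore required for full Mayo")
  partial_mayo(a) + .endo_value[[a$endoscopic]]
}

.clinical_remission <- function(a, subscore_max) {
  partial_mayo(a) <= 2 &&
    max(a$stool_frequency, a$rectal_bleeding, a$physician_global) <= subscore_max
}

.response_call <- function(subject_id, week, call, reason) {
  structure(list(subject_id = subject_id, week = as.integer(week),
                 call = call, reason = reason), class = "response_call")
}

#' Clinical response at week 10 (partial Mayo rules)
#'
#' Remission: partial Mayo <= 2 with no individual clinical subscore above
#' `remission_subscore_max` (the trial stated "no individual sub score of >2"
#' and that literal reading is the default; set 1 for the conventional
#' stricter variant). Partial response: decrease of at least 3 points in the
#' partial Mayo from baseline. Anything else, or dropout for progressive
#' disease, is no response.
#'
#' @param baseline,wk10 [mayo_assessment()] objects.
#' @param dropped_out logical; dropout due to progressive symptoms forces
#'   no-response.
#' @param subject_id optional label.
#' @param remission_subscore_max per-subscore cap inside the remission rule
#'   (default 2, as printed in the trial definition).
#' @return a `response_call` with `call` in remission/partial/none and a
#'   human-readable `reason`.
#' @export
classify_week10 <- function(baseline, wk10, dropped_out = FALSE,
                            subject_id = NA_character_,
                            remission_subscore_max = 2L) {
  if (missing(baseline) || is.null(baseline)) stop("baseline assessment required")
  if (dropped_out)
    return(.response_call(subject_id, 10L, "none",
                          "dropout for progressive disease = treatment failure"))
  if (.clinical_remission(wk10, remission_subscore_max))
    return(.response_call(subject_id, 10L, "remission",
                          "partial Mayo <= 2, all clinical subscores within cap"))
  if (partial_mayo(baseline) - partial_mayo(wk10) >= 3)
    return(.response_call(subject_id, 10L, "partial",
                          "partial Mayo decreased by >= 3 from baseline"))
  .response_call(subject_id, 10L, "none", "neither remission nor >= 3-point decrease")
}

#' Clinical response at week 14 (full Mayo rules)
#'
#' Remission: the week-10-style clinical remission criterion plus an
#' endoscopic Mayo score of 0 or 1a. Partial remission: a decrease of at
#' least 3 points in the partial Mayo and at least one step down the ordered
#' endoscopic scale 0 < 1a < 1b < 2 < 3 (so 1b to 1a qualifies). Dropout for
#' progressive disease is no response.
#'
#' @inheritParams classify_week10
#' @param wk14 [mayo_assessment()] with an endoscopic subscore (required
#'   unless `dropped_out`).
#' @return a `response_call`.
#' @export
classify_week14 <- function(baseline, wk14, dropped_out = FALSE,
                            subject_id = NA_character_,
                            remission_subscore_max = 2L) {
  if (missing(baseline) || is.null(baseline)) stop("baseline assessment required")
  if (dropped_out)
    return(.response_call(subject_id, 14L, "none",
                          "dropout for progressive disease = treatment failure"))
  if (is.na(wk14$endoscopic))
    stop("week-14 classification requires an endoscopic subscore")
  if (is.na(baseline$endoscopic))
    stop("baseline endoscopic subscore required for week-14 classification")
  if (.clinical_remission(wk14, remission_subscore_max) &&
      wk14$endoscopic %in% c("0", "1a"))
    return(.response_call(subject_id, 14L, "remission",
                          "clinical remission with endoscopic Mayo 0-1a"))
  clin_drop <- partial_mayo(baseline) - partial_mayo(wk14) >= 3
  endo_drop <- .endo_rank[[baseline$endoscopic]] - .endo_rank[[wk14$endoscopic]] >= 1
  if (clin_drop && endo_drop)
    return(.response_call(subject_id, 14L, "partial",
                          "partial Mayo decreased >= 3 and endoscopic score decreased >= 1 step"))
  .response_call(subject_id, 14L, "none",
                 "no remission and no combined clinical + endoscopic improvement")
}

#' Responder flag
#'
#' Responders pool remission and partial remission; no-response (including
#' dropouts for progression) are non-responders.
#'
#' @param call a `response_call` or its `call` string.
#' @return logical.
#' @export
responder_flag <- function(call) {
  if (inherits(call, "response_call")) call <- call$call
  call %in% c("remission", "partial")
}

#' Classify a cohort Mayo table
#'
#' @param mayo data.frame with columns `subject_id`, `week`,
#'   `stool_frequency`, `rectal_bleeding`, `physician_global`, `endoscopic`
#'   (NA allowed pre week 14), `dropped_out` (logical, optional); one row per
#'   subject per assessed week, with a baseline row (the smallest week per
#'   subject).
#' @param remission_subscore_max see [classify_week10()].
#' @return data.frame with one row per subject and week in \{10, 14\}:
#'   `subject_id`, `week`, `call`, `responder`, `reason`.
#' @export
classify_mayo_table <- function(mayo, remission_subscore_max = 2L) {
  if (is.null(mayo$dropped_out)) mayo$dropped_out <- FALSE
  as_assessment <- function(r) {
    mayo_assessment(r$stool_frequency, r$rectal_bleeding, r$physician_global,
                    r$endoscopic, r$week)
  }
  out <- list()
  for (s in unique(mayo$subject_id)) {
    rows <- mayo[mayo$subject_id == s, , drop = FALSE]
    rows <- rows[order(rows$week), , drop = FALSE]
    base <- as_assessment(rows[1, ])
    dropped <- any(rows$dropped_out)
    for (wk in c(10L, 14L)) {
      fu_row <- rows[rows$week == wk, , drop = FALSE]
      if (!nrow(fu_row)) {
        if (!dropped) next
        cl <- if (wk == 10L)
          classify_week10(base, base, dropped_out = TRUE, subject_id = s)
        else classify_week14(base, base, dropped_out = TRUE, subject_id = s)
      } else {
        fu <- as_assessment(fu_row[1, ])
        cl <- if (wk == 10L)
          classify_week10(base, fu, dropped_out = fu_row$dropped_out[1],
                          subject_id = s,
                          remission_subscore_max = remission_subscore_max)
        else
          classify_week14(base, fu, dropped_out = fu_row$dropped_out[1],
                          subject_id = s,
                          remission_subscore_max = remission_subscore_max)
      }
      out[[length(out) + 1L]] <- data.frame(
        subject_id = s, week = cl$week, call = cl$call,
        responder = responder_flag(cl), reason = cl$reason)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
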