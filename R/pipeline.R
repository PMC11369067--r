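#' End-to-end FMT engraftment analysis
#'
#' Runs the full pipeline on an abundance table + metadata (and optionally a
#' Mayo assessment table): relative-abundance closure, detection
#' thresholding, donor core and donor-derived sets, per-subject engraftment
#' metrics and total scores, clinical response classification, and the
#' standard cohort comparisons (total score by donor via Wilcoxon rank-sum;
#' pretreatment and donor effects via two-way ANOVA; donor x week-14
#' response via Fisher's exact test when clinical data are supplied).
#'
#' @param profiles abundance matrix, samples x species (counts or fractions).
#' @param meta cohort metadata (see [validate_cohort_metadata()]).
#' @param mayo optional Mayo table (see [classify_mayo_table()]).
#' @param tau detection limit (default 0.001).
#' @param min_samples donor core prevalence cutoff (default 6).
#' @param windows window list from [window_specs()].
#' @param ... passed to [compute_engraftment()].
#' @return list with `retained` (per-sample retained abundance after
#'   thresholding), `core_sets`, `donor_derived`, `scores` (subject x window
#'   with `total_score`), `normalization`, `responses` (or NULL), and
#'   `comparisons` (named list of test results per window).
#' @export
run_fmt_pipeline <- function(profiles, meta, mayo = NULL, tau = 0.001,
                             min_samples = 6L, windows = window_specs(), ...) {
  rel <- to_relative(profiles)
  thr <- apply_detection_threshold(rel, tau = tau)
  retained <- retained_fraction(thr)

  eng <- compute_engraftment(rel, meta, windows = windows, tau = tau,
                             min_samples = min_samples, ...)
  tot <- total_engraftment_scores(eng$metrics)
  scores <- tot$scores

  responses <- if (!is.null(mayo)) classify_mayo_table(mayo) else NULL

  subj <- unique(scores[, c("subject_id", "donor_id")])
  arm <- meta$arm[match(subj$subject_id, meta$subject_id)]
  comparisons <- list()
  for (wn in unique(scores$window)) {
    sub <- scores[scores$window == wn & !is.na(scores$total_score), ,
                  drop = FALSE]
    d <- sub$donor_id
    a <- meta$arm[match(sub$subject_id, meta$subject_id)]
    cmp <- list()
    if (length(unique(d)) == 2)
      cmp$total_by_donor <- wilcoxon_rank_sum_exact(
        sub$total_score[d == unique(d)[1]], sub$total_score[d == unique(d)[2]])
    if (length(unique(a)) == 2 && length(unique(d)) == 2)
      cmp$pretreatment_and_donor <- two_way_anova(sub$total_score, a, d)
    comparisons[[wn]] <- cmp
  }
  if (!is.null(responses)) {
    r14 <- responses[responses$week == 14, , drop = FALSE]
    d <- meta$donor_id[match(r14$subject_id, meta$subject_id)]
    d <- ifelse(is.na(d), "unknown", d)
    if (length(unique(d)) == 2) {
      tab <- table(factor(d), factor(r14$responder, levels = c(TRUE, FALSE)))
      comparisons$week14_response_by_donor <-
        fisher_exact_2x2(matrix(as.integer(tab), 2))
    }
  }
  list(retained = retained, core_sets = eng$core_sets,
       donor_derived = eng$donor_derived, scores = scores,
       normalization = tot$normalization, responses = responses,
       comparisons = comparisons)
}
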