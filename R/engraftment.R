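#' Centred log-ratio transform with multiplicative zero replacement
#'
#' Zeros are replaced by a small pseudocount (by default half the detection
#' limit, tying the imputation to the smallest abundance that counts as
#' present), the vector is re-closed to unit sum, logged, and centred by its
#' mean log. The output always sums to zero.
#'
#' @param x nonnegative composition vector (length >= 2).
#' @param pseudocount replacement for zero entries (default `5e-4`, i.e.
#'   tau/2 at the standard 0.1% detection limit).
#' @return clr-transformed numeric vector, sum 0.
#' @export
clr_transform <- function(x, pseudocount = 5e-4) {
  if (length(x) < 2) stop("composition must have length >= 2")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (all(x == 0)) stop("all-zero composition cannot be clr-transformed")
  if (any(x < 0)) stop("negative entries in composition")
  x[x == 0] <- pseudocount
  x <- x / sum(x)
  lx <- log(x)
  lx - mean(lx)
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between the clr transforms of the two compositions,
#' the standard metric for compositional microbiome data. With
#' `union_universe = TRUE` (the convention used for recipient-donor
#' comparisons) the two vectors are first restricted to the species detected
#' in at least one of them; zeros arising from the union fill receive the
#' pseudocount inside [clr_transform()].
#'
#' @param a,b nonnegative compositions over the same species universe (equal
#'   length; named vectors are matched positionally).
#' @param pseudocount zero replacement passed to [clr_transform()].
#' @param union_universe drop species absent from both vectors before
#'   transforming (default TRUE).
#' @return nonnegative distance; 0 iff the clr vectors coincide.
#' @export
aitchison_distance <- function(a, b, pseudocount = 5e-4, union_universe = TRUE) {
  if (length(a) != length(b))
    stop("compositions have mismatched dimensions: ", length(a), " vs ", length(b))
  if (union_universe) {
    keep <- a > 0 | b > 0
    if (sum(keep) < 2) stop("fewer than two species detected in either sample")
    a <- a[keep]; b <- b[keep]
  }
  sqrt(sum((clr_transform(a, pseudocount) - clr_transform(b, pseudocount))^2))
}

#' Aitchison distance matrix for a set of samples
#'
#' Computes clr transforms on the shared universe of species detected in at
#' least one sample, then the Euclidean distance matrix. Used for PERMANOVA
#' and ordination on thresholded profiles.
#'
#' @param profiles relative abundance matrix (samples x species).
#' @param pseudocount zero replacement.
#' @return a `dist` object over the samples.
#' @export
aitchison_distance_matrix <- function(profiles, pseudocount = 5e-4) {
  keep <- colSums(profiles) > 0
  m <- profiles[, keep, drop = FALSE]
  clr <- t(apply(m, 1, clr_transform, pseudocount = pseudocount))
  stats::dist(clr)
}

#' Species Engraftment Index for one sample
#'
#' Sum of the relative abundances of the donor-derived species detected (at
#' or above `tau`) in a single post-FMT sample: the extent to which the
#' recipient microbiome has been displaced by donor-derived taxa.
#'
#' @param sample_abund named abundance vector for one thresholded sample.
#' @param dd_species character vector of donor-derived species.
#' @param tau detection limit.
#' @return fraction in \[0, 1\].
#' @export
sei_per_sample <- function(sample_abund, dd_species, tau = 0.001) {
  if (!length(dd_species)) return(0)
  v <- sample_abund[intersect(dd_species, names(sample_abund))]
  sum(v[v >= tau])
}

#' Median convention used throughout
#'
#' Even-length medians are the mean of the two central order statistics
#' (the base R default); kept as one named helper so the convention is
#' stated once.
#' @noRd
window_median <- function(x) stats::median(x)

#' Per-subject engraftment metrics across windows
#'
#' For one recipient, computes the three engraftment metrics in each study
#' window:
#' \describe{
#'   \item{sei}{median over the window's samples of the per-sample Species
#'     Engraftment Index.}
#'   \item{sef}{Species Engraftment Fraction: the fraction of the
#'     donor-derived set detected in at least one window sample.}
#'   \item{similarity}{baseline-normalised Aitchison similarity to the donor:
#'     for each window sample the median Aitchison distance to all donor
#'     samples is taken, the median of those per-timepoint distances is the
#'     window distance, and similarity = baseline distance / window distance,
#'     where the baseline is the recipient's final pre-FMT sample (week 3,
#'     after pretreatment and lavage). Values above 1 mean the recipient
#'     moved toward the donor.}
#' }
#'
#' @param recipient_profiles thresholded abundance matrix of the recipient's
#'   samples (row names are sample ids).
#' @param recipient_weeks integer week per row of `recipient_profiles`.
#' @param donor_profiles thresholded abundance matrix of the assigned donor's
#'   samples.
#' @param dd a `donor_derived_set` for this recipient.
#' @param windows window list from [window_specs()].
#' @param tau detection limit.
#' @param pseudocount clr zero replacement (default tau/2).
#' @param baseline_week week of the pre-FMT reference sample for the
#'   similarity metric (default 3; falls back to the latest pre-FMT week
#'   present if week 3 is absent).
#' @param pool_pairwise if TRUE, pool all recipient-sample x donor-sample
#'   distances in a window and take one median, instead of the default
#'   median-per-timepoint-then-median-over-timepoints.
#' @return data.frame with one row per window: `window`, `sei`, `sef`,
#'   `similarity`, `n_samples_in_window`, `n_donor_derived`. Windows without
#'   samples get NA metrics.
#' @export
engraftment_metrics <- function(recipient_profiles, recipient_weeks,
                                donor_profiles, dd,
                                windows = window_specs(), tau = 0.001,
                                pseudocount = tau / 2, baseline_week = 3L,
                                pool_pairwise = FALSE) {
  stopifnot(nrow(recipient_profiles) == length(recipient_weeks))
  first_post <- min(vapply(windows, `[`, integer(1), 1))
  pre_weeks <- recipient_weeks[recipient_weeks < first_post]
  if (!length(pre_weeks)) stop("recipient has no pre-FMT sample")
  bw <- if (baseline_week %in% pre_weeks) baseline_week else max(pre_weeks)
  base_vec <- recipient_profiles[which(recipient_weeks == bw)[1], ]

  dist_to_donor <- function(vec) {
    apply(donor_profiles, 1, function(d)
      aitchison_distance(vec, d, pseudocount = pseudocount))
  }
  d_base <- window_median(dist_to_donor(base_vec))
  if (d_base == 0)
    stop("baseline sample is compositionally identical to the donor; ",
         "similarity is undefined")

  out <- lapply(names(windows), function(wn) {
    r <- windows[[wn]]
    idx <- which(recipient_weeks >= r[1] & recipient_weeks <= r[2])
    if (!length(idx))
      return(data.frame(window = wn, sei = NA_real_, sef = NA_real_,
                        similarity = NA_real_, n_samples_in_window = 0L,
                        n_donor_derived = dd$n_species))
    sub <- recipient_profiles[idx, , drop = FALSE]
    seis <- apply(sub, 1, sei_per_sample, dd_species = dd$species, tau = tau)
    sef <- if (dd$n_species == 0) NA_real_ else {
      det <- colSums(sub[, intersect(dd$species, colnames(sub)),
                         drop = FALSE] >= tau) > 0
      sum(det) / dd$n_species
    }
    dmat <- t(apply(sub, 1, dist_to_donor))
    wdist <- if (pool_pairwise) window_median(as.numeric(dmat))
             else window_median(apply(dmat, 1, window_median))
    data.frame(window = wn, sei = window_median(seis), sef = sef,
               similarity = d_base / wdist,
               n_samples_in_window = length(idx),
               n_donor_derived = dd$n_species)
  })
  do.call(rbind, out)
}

#' Cohort-wide engraftment metrics
#'
#' Runs the full per-recipient engraftment computation for a cohort: donor
#' core sets, donor-derived sets, and the SEI/SEF/similarity triplet per
#' subject and window.
#'
#' @param profiles relative abundance matrix for all samples (donors and
#'   recipients), thresholded or not (thresholding at `tau` is applied here).
#' @param meta metadata data.frame (see [validate_cohort_metadata()]).
#' @param windows window list.
#' @param tau detection limit.
#' @param min_samples donor core prevalence cutoff (absolute count).
#' @param pseudocount clr zero replacement.
#' @param ... passed on to [engraftment_metrics()].
#' @return list with `core_sets` (per donor), `donor_derived` (per recipient),
#'   and `metrics`, a data.frame of subject x window rows.
#' @export
compute_engraftment <- function(profiles, meta, windows = window_specs(),
                                tau = 0.001, min_samples = 6L,
                                pseudocount = tau / 2, ...) {
  validate_cohort_metadata(meta, profiles,
                           first_post_fmt_week = min(vapply(windows, `[`,
                                                            integer(1), 1)))
  profiles <- apply_detection_threshold(profiles[meta$sample_id, , drop = FALSE],
                                        tau = tau)
  first_post <- min(vapply(windows, `[`, integer(1), 1))
  donors <- unique(meta$subject_id[meta$role == "donor"])
  core_sets <- lapply(donors, function(d) {
    ids <- meta$sample_id[meta$subject_id == d]
    donor_core_species(profiles[ids, , drop = FALSE], tau = tau,
                       min_samples = min_samples, donor_id = d)
  })
  names(core_sets) <- donors

  recips <- unique(meta$subject_id[meta$role == "recipient"])
  dd_sets <- list()
  rows <- list()
  for (s in recips) {
    mrows <- meta[meta$subject_id == s, , drop = FALSE]
    d <- mrows$donor_id[1]
    pre_ids <- mrows$sample_id[mrows$week < first_post]
    dd <- donor_derived_species(core_sets[[d]],
                                profiles[pre_ids, , drop = FALSE],
                                tau = tau, subject_id = s)
    dd_sets[[s]] <- dd
    donor_ids <- meta$sample_id[meta$subject_id == d]
    em <- engraftment_metrics(profiles[mrows$sample_id, , drop = FALSE],
                              mrows$week,
                              profiles[donor_ids, , drop = FALSE],
                              dd, windows = windows, tau = tau,
                              pseudocount = pseudocount, ...)
    em <- cbind(subject_id = s, donor_id = d, em)
    rows[[s]] <- em
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(core_sets = core_sets, donor_derived = dd_sets, metrics = metrics)
}

#' Total engraftment score with cohort-level normalisation
#'
#' The three metrics live on different scales, so before summing, SEI and
#' similarity are rescaled per window so that each metric's cohort median
#' equals the cohort median SEF; the total engraftment score is then
#' `sef + scale_sei * sei + scale_similarity * similarity`. The scales are
#' returned so results are reproducible and so scaled medians can be
#' verified to be exactly equal.
#'
#' @param metrics data.frame from [compute_engraftment()]`$metrics` (columns
#'   `subject_id`, `window`, `sei`, `sef`, `similarity`).
#' @return list with `scores` (input plus `total_score`) and `normalization`
#'   (per window: `reference_median`, `scale_sei`, `scale_similarity`).
#'   A metric with cohort median zero gets scale 0 (its contribution is
#'   dropped) with a warning.
#' @export
total_engraftment_scores <- function(metrics) {
  norms <- list(); scored <- list()
  for (wn in unique(metrics$window)) {
    sub <- metrics[metrics$window == wn, , drop = FALSE]
    ok <- stats::complete.cases(sub[, c("sei", "sef", "similarity")])
    if (sum(ok) < 2)
      stop("need >= 2 subjects with complete metric triplets in window ", wn)
    ref <- window_median(sub$sef[ok])
    med_sei <- window_median(sub$sei[ok])
    med_sim <- window_median(sub$similarity[ok])
    scale_of <- function(med, nm) {
      if (med == 0) {
        warning("cohort median ", nm, " is zero in window ", wn,
                "; its contribution to the total score is dropped")
        0
      } else ref / med
    }
    s_sei <- scale_of(med_sei, "SEI")
    s_sim <- scale_of(med_sim, "similarity")
    sub$total_score <- sub$sef + s_sei * sub$sei + s_sim * sub$similarity
    scored[[wn]] <- sub
    norms[[wn]] <- data.frame(window = wn, reference_median = ref,
                              scale_sei = s_sei, scale_similarity = s_sim)
  }
  list(scores = do.call(rbind, c(scored, make.row.names = FALSE)),
       normalization = do.call(rbind, c(norms, make.row.names = FALSE)))
}
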