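#' Donor core species by prevalence filtering
#'
#' A species belongs to a donor's core microbiome when it is detected (at or
#' above the detection limit `tau`) in at least `min_samples` of that donor's
#' longitudinal stool samples. The trial's rule used a fixed count of six out
#' of the 13 or 14 samples available per donor, so the absolute count takes
#' precedence; `min_prevalence` offers the equivalent fractional cutoff for
#' donors with different sampling depth.
#'
#' @param donor_profiles relative abundance matrix of one donor's samples
#'   (rows) by species (columns), already thresholded or not (thresholding at
#'   `tau` is applied by the presence test itself).
#' @param tau detection limit (default 0.001).
#' @param min_samples minimum number of samples a species must be detected in
#'   (default 6). Overrides `min_prevalence` when both are given.
#' @param min_prevalence optional fractional prevalence cutoff in (0, 1];
#'   translated to `ceiling(min_prevalence * n_samples)`.
#' @param donor_id optional donor label carried in the result.
#' @return a `core_species_set`: list with `donor_id`, `species` (character),
#'   `prevalence` (named detection counts for core members), `min_samples`,
#'   `n_donor_samples`, and `core_abundance` (per-sample cumulative relative
#'   abundance of the core set, an observed property that is reported, never
#'   enforced).
#' @export
donor_core_species <- function(donor_profiles, tau = 0.001, min_samples = 6L,
                               min_prevalence = NULL, donor_id = NULL) {
  n <- nrow(donor_profiles)
  if (is.null(n) || n < 1) stop("need at least one donor sample")
  if (is.null(min_samples)) {
    if (is.null(min_prevalence)) stop("supply min_samples or min_prevalence")
    min_samples <- as.integer(ceiling(min_prevalence * n))
  }
  if (min_samples > n)
    stop(sprintf("min_samples (%d) exceeds donor sample count (%d)",
                 min_samples, n))
  present <- donor_profiles >= tau
  prev <- colSums(present)
  core <- names(prev)[prev >= min_samples]
  core_ab <- if (length(core))
    rowSums(donor_profiles[, core, drop = FALSE] *
              present[, core, drop = FALSE])
  else stats::setNames(numeric(n), rownames(donor_profiles))
  structure(list(donor_id = donor_id, species = core,
                 prevalence = prev[core], min_samples = as.integer(min_samples),
                 n_donor_samples = n, core_abundance = core_ab),
            class = "core_species_set")
}

#' Putatively donor-derived species for one recipient
#'
#' Starting from the donor's core set, every species already detected in any
#' of the recipient's pre-FMT samples is excluded: species present before
#' transplant cannot be claimed as engrafted. The remainder is the universe
#' within which engraftment is tracked for that recipient. Using the union of
#' all pre-FMT samples is the conservative exclusion.
#'
#' @param core a `core_species_set` from [donor_core_species()].
#' @param recipient_pre_profiles relative abundance matrix of the recipient's
#'   pre-FMT samples (rows) by species.
#' @param tau detection limit (default 0.001).
#' @param subject_id optional recipient label carried in the result.
#' @return a `donor_derived_set`: list with `subject_id`, `donor_id`,
#'   `species`, `n_species`, `n_pre_fmt_samples_used`.
#' @export
donor_derived_species <- function(core, recipient_pre_profiles, tau = 0.001,
                                  subject_id = NULL) {
  if (is.null(nrow(recipient_pre_profiles)) || nrow(recipient_pre_profiles) < 1)
    stop("cannot define a pre-FMT baseline: no pre-FMT samples")
  seen <- colnames(recipient_pre_profiles)[
    colSums(recipient_pre_profiles >= tau) > 0]
  dd <- setdiff(core$species, seen)
  structure(list(subject_id = subject_id, donor_id = core$donor_id,
                 species = dd, n_species = length(dd),
                 n_pre_fmt_samples_used = nrow(recipient_pre_profiles)),
            class = "donor_derived_set")
}

#' @export
print.core_species_set <- function(x, ...) {
  cat(sprintf("Donor core set%s: %d species (detected in >= %d of %d samples)\n",
              if (is.null(x$donor_id)) "" else paste0(" [", x$donor_id, "]"),
              length(x$species), x$min_samples, x$n_donor_samples))
  cat(sprintf("  core cumulative abundance per sample: median %.3f (range %.3f-%.3f)\n",
              stats::median(x$core_abundance), min(x$core_abundance),
              max(x$core_abundance)))
  invisible(x)
}

#' @export
print.donor_derived_set <- function(x, ...) {
  cat(sprintf("Donor-derived set%s: %d species (donor %s core, absent from %d pre-FMT sample(s))\n",
              if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
              x$n_species, if (is.null(x$donor_id)) "?" else x$donor_id,
              x$n_pre_fmt_samples_used))
  invisible(x)
}
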