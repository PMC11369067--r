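#' Configuration for the synthetic FMT cohort generator
#'
#' Defaults mirror the trial layout the package targets: two donors sampled
#' 13 and 14 times, 24 recipients with pre-FMT samples at weeks 0 and 3
#' (inclusion and post-pretreatment/lavage) and post-FMT samples at weeks 4,
#' 5, 6, 7, 8, 10, and 14; species-level profiles in which part of each
#' donor's species pool already overlaps the recipient baseline; and a
#' tunable engraftment mixing fraction lambda per recipient.
#'
#' @param n_donors number of donors (default 2).
#' @param donor_samples samples per donor (recycled; default `c(13, 14)`).
#' @param n_recipients number of recipients (default 24).
#' @param species_pool_size size of the global species pool (default 500).
#' @param donor_species species per donor (recycled; default `c(250, 180)`).
#' @param recipient_baseline_species species per recipient baseline
#'   (default 120).
#' @param donor_recipient_overlap_frac fraction of the donor's species set
#'   already present in the recipient baseline (default 0.4).
#' @param lambda engraftment mixing fraction: a scalar, one value per
#'   recipient, or a recipients x post-FMT-weeks matrix. `NULL` (default)
#'   spreads recipients evenly over 0.05-0.70, constant across weeks, so the
#'   cohort spans weak to strong engraftment.
#' @param pre_fmt_weeks,post_fmt_weeks integer sampling weeks
#'   (defaults `c(0, 3)` and `c(4, 5, 6, 7, 8, 10, 14)`).
#' @param dispersion Dirichlet concentration scaling for per-sample noise;
#'   larger is less noisy (default 300).
#' @param species_dropout per-sample probability that a present species
#'   drops below detection entirely (default 0.05), so donor core prevalence
#'   filtering is actually exercised.
#' @param baseline_min_abund detectability floor for recipient baseline
#'   species (default 0.005): species declared present in a recipient before
#'   FMT are seeded at a reliably detectable abundance, since "presence" is
#'   only meaningful relative to the detection limit. Donor profiles keep
#'   their full heavy tail, including sub-detection species.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_donors = 2L, donor_samples = c(13L, 14L),
                              n_recipients = 24L, species_pool_size = 500L,
                              donor_species = c(250L, 180L),
                              recipient_baseline_species = 120L,
                              donor_recipient_overlap_frac = 0.4,
                              lambda = NULL,
                              pre_fmt_weeks = c(0L, 3L),
                              post_fmt_weeks = c(4L, 5L, 6L, 7L, 8L, 10L, 14L),
                              dispersion = 300, species_dropout = 0.05,
                              baseline_min_abund = 0.005, seed = 1L) {
  donor_samples <- rep_len(as.integer(donor_samples), n_donors)
  donor_species <- rep_len(as.integer(donor_species), n_donors)
  if (any(donor_species > species_pool_size))
    stop("species_pool_size smaller than a donor's species count")
  stopifnot(n_donors >= 1, n_recipients >= 1,
            donor_recipient_overlap_frac >= 0, donor_recipient_overlap_frac <= 1,
            species_dropout >= 0, species_dropout < 1, dispersion > 0)
  if (is.null(lambda))
    lambda <- if (n_recipients == 1) 0.4 else
      seq(0.05, 0.70, length.out = n_recipients)
  if (is.matrix(lambda)) {
    stopifnot(nrow(lambda) == n_recipients,
              ncol(lambda) == length(post_fmt_weeks))
  } else {
    lambda <- matrix(rep_len(lambda, n_recipients), nrow = n_recipients,
                     ncol = length(post_fmt_weeks))
  }
  if (any(lambda < 0 | lambda > 1)) stop("lambda must lie in [0, 1]")
  structure(list(n_donors = as.integer(n_donors), donor_samples = donor_samples,
                 n_recipients = as.integer(n_recipients),
                 species_pool_size = as.integer(species_pool_size),
                 donor_species = donor_species,
                 recipient_baseline_species = as.integer(recipient_baseline_species),
                 donor_recipient_overlap_frac = donor_recipient_overlap_frac,
                 lambda = lambda, pre_fmt_weeks = as.integer(pre_fmt_weeks),
                 post_fmt_weeks = as.integer(post_fmt_weeks),
                 dispersion = dispersion, species_dropout = species_dropout,
                 baseline_min_abund = baseline_min_abund,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Dirichlet-style resample of a base composition plus per-species dropout;
# rows always re-close to unit sum.
.noisy_sample <- function(base, dispersion, dropout) {
  g <- stats::rgamma(length(base), shape = dispersion * base)
  if (dropout > 0) {
    keep <- stats::runif(length(base)) >= dropout
    if (!any(keep & g > 0)) keep[which.max(base)] <- TRUE
    g[!keep] <- 0
  }
  g / sum(g)
}

# log-normal base composition over a species subset; optional abundance
# floor (exact: floored species fixed at `floor_at`, remainder rescaled)
.base_profile <- function(n, sdlog = 1.5, floor_at = 0) {
  v <- exp(stats::rnorm(n, 0, sdlog))
  v <- v / sum(v)
  if (floor_at > 0) {
    if (n * floor_at >= 1) stop("abundance floor infeasible for ", n, " species")
    low <- v < floor_at
    repeat {
      v[low] <- 0
      v[!low] <- v[!low] / sum(v[!low]) * (1 - sum(low) * floor_at)
      newly <- v < floor_at & !low
      if (!any(newly)) break
      low <- low | newly
    }
    v[low] <- floor_at
  }
  v
}

#' Simulate one donor's longitudinal samples
#'
#' The donor gets a fixed log-normal base composition over its species
#' subset; each stool sample is a Dirichlet-style resample at the configured
#' dispersion, with independent per-species dropout so detection prevalence
#' varies across samples and the core-species prevalence rule has something
#' to filter.
#'
#' @param cfg a [simulation_config()].
#' @param donor_index which donor (1-based).
#' @param species_pool character vector of all species ids.
#' @param donor_id label for sample ids.
#' @return list with `profiles` (samples x full pool matrix), `species`
#'   (the donor's species subset), `base` (named base composition).
#' @export
simulate_donor <- function(cfg, donor_index, species_pool,
                           donor_id = sprintf("D%02d", donor_index + 6L)) {
  sp <- sort(sample(species_pool, cfg$donor_species[donor_index]))
  base <- stats::setNames(.base_profile(length(sp)), sp)
  n <- cfg$donor_samples[donor_index]
  m <- matrix(0, nrow = n, ncol = length(species_pool),
              dimnames = list(sprintf("%s_s%02d", donor_id, seq_len(n)),
                              species_pool))
  for (i in seq_len(n))
    m[i, sp] <- .noisy_sample(base, cfg$dispersion, cfg$species_dropout)
  list(profiles = m, species = sp, base = base, donor_id = donor_id)
}

#' Simulate one recipient's longitudinal samples with known ground truth
#'
#' The recipient baseline shares `donor_recipient_overlap_frac` of the
#' donor's species set; pre-FMT samples are noisy draws from the baseline
#' composition, and each post-FMT week-w sample is a noisy draw from the
#' re-closed mixture `(1 - lambda_w) * baseline + lambda_w * donor base`.
#' The ground truth records lambda per week and the transferred species the
#' recipient did not already carry; "transferred" is restricted to species
#' present at or above the standard 0.1% detection limit in the donor base
#' composition, since species below it enter the mixture at untrackable
#' abundance.
#'
#' @param cfg a [simulation_config()].
#' @param recipient_index which recipient (1-based).
#' @param donor result of [simulate_donor()] for the assigned donor.
#' @param species_pool character vector of all species ids.
#' @return list with `profiles` (samples x pool), `weeks`, `ground_truth`
#'   (list: `lambda` named by post-FMT week, `engrafted_species`,
#'   `baseline_species`).
#' @export
simulate_recipient <- function(cfg, recipient_index, donor, species_pool) {
  n_overlap <- round(cfg$donor_recipient_overlap_frac * length(donor$species))
  if (n_overlap > cfg$recipient_baseline_species)
    stop("recipient_baseline_species too small for the requested overlap")
  shared <- if (n_overlap > 0) sample(donor$species, n_overlap) else character(0)
  outside <- setdiff(species_pool, donor$species)
  n_own <- cfg$recipient_baseline_species - n_overlap
  if (n_own > length(outside)) {
    if (cfg$donor_recipient_overlap_frac == 1)
      warning("no species outside the donor pool; donor-derived set will be empty")
    n_own <- length(outside)
  }
  own <- if (n_own > 0) sample(outside, n_own) else character(0)
  bsp <- sort(c(shared, own))
  base <- stats::setNames(.base_profile(length(bsp),
                                        floor_at = cfg$baseline_min_abund), bsp)

  weeks <- c(cfg$pre_fmt_weeks, cfg$post_fmt_weeks)
  sid <- sprintf("R%02d", recipient_index)
  m <- matrix(0, nrow = length(weeks), ncol = length(species_pool),
              dimnames = list(sprintf("%s_w%02d", sid, weeks), species_pool))
  lam <- cfg$lambda[recipient_index, ]
  union_sp <- sort(union(bsp, donor$species))
  base_u <- stats::setNames(numeric(length(union_sp)), union_sp)
  base_u[bsp] <- base
  donor_u <- stats::setNames(numeric(length(union_sp)), union_sp)
  donor_u[donor$species] <- donor$base

  for (i in seq_along(weeks)) {
    w <- weeks[i]
    if (w %in% cfg$pre_fmt_weeks) {
      m[i, bsp] <- .noisy_sample(base, cfg$dispersion, cfg$species_dropout)
    } else {
      l <- lam[match(w, cfg$post_fmt_weeks)]
      mix <- (1 - l) * base_u + l * donor_u
      mix <- mix / sum(mix)
      m[i, union_sp] <- .noisy_sample(mix, cfg$dispersion, cfg$species_dropout)
    }
  }
  list(profiles = m, weeks = weeks, subject_id = sid,
       ground_truth = list(
         lambda = stats::setNames(lam, cfg$post_fmt_weeks),
         engrafted_species = setdiff(names(donor$base)[donor$base >= 0.001],
                                     bsp),
         baseline_species = bsp))
}

#' Simulate a full synthetic FMT cohort
#'
#' Builds donors, recipients, a metadata table and per-recipient ground
#' truth, fully deterministic under `cfg$seed`. Recipients alternate between
#' donors and between budesonide and placebo arms so both two-level factors
#' are balanced.
#'
#' @param cfg a [simulation_config()].
#' @return list with `profiles` (all samples x species pool, rows sum to 1),
#'   `metadata` (sample_id, subject_id, role, donor_id, week, arm),
#'   `ground_truth` (per recipient), `donors` (per-donor simulation output),
#'   and `config`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  pool <- sprintf("sp%04d", seq_len(cfg$species_pool_size))
  donors <- lapply(seq_len(cfg$n_donors), simulate_donor, cfg = cfg,
                   species_pool = pool)
  names(donors) <- vapply(donors, `[[`, character(1), "donor_id")

  donor_of <- rep_len(names(donors), cfg$n_recipients)
  # arms alternate in pairs so pretreatment is crossed with donor
  arm_of <- rep_len(rep(c("budesonide", "placebo"), each = 2),
                    cfg$n_recipients)
  recips <- lapply(seq_len(cfg$n_recipients), function(i)
    simulate_recipient(cfg, i, donors[[donor_of[i]]], pool))

  prof_list <- c(lapply(donors, `[[`, "profiles"),
                 lapply(recips, `[[`, "profiles"))
  profiles <- do.call(rbind, prof_list)

  meta_d <- do.call(rbind, lapply(donors, function(d)
    data.frame(sample_id = rownames(d$profiles), subject_id = d$donor_id,
               role = "donor", donor_id = d$donor_id,
               week = seq_len(nrow(d$profiles)), arm = NA_character_)))
  meta_r <- do.call(rbind, lapply(seq_along(recips), function(i) {
    r <- recips[[i]]
    data.frame(sample_id = rownames(r$profiles), subject_id = r$subject_id,
               role = "recipient", donor_id = donor_of[i], week = r$weeks,
               arm = arm_of[i])
  }))
  metadata <- rbind(meta_d, meta_r)
  rownames(metadata) <- NULL

  gt <- lapply(recips, `[[`, "ground_truth")
  names(gt) <- vapply(recips, `[[`, character(1), "subject_id")
  list(profiles = abundance_table(profiles), metadata = metadata,
       ground_truth = gt, donors = donors, config = cfg)
}

#' Construct synthetic Mayo trajectories realising requested outcome counts
#'
#' Works backwards from the requested response calls to Mayo component
#' scores, so that [classify_week10()] and [classify_week14()] reproduce the
#' requested remission / partial / no-response counts exactly. Every subject
#' starts from the same moderate baseline (clinical subscores 2/2/2, partial
#' Mayo 6, endoscopic 2); follow-up components are chosen per requested
#' call. A configurable number of week-14 non-responders (defaulting to 3,
#' and requiring no response at both weeks) drop out for progressive disease
#' and carry no follow-up assessments.
#'
#' @param donor donor label per recipient (length defines the cohort size).
#' @param week10 named counts for week-10 calls, e.g.
#'   `c(remission = 10, partial = 2, none = 12)` (the default trial outcome
#'   structure when 24 subjects are supplied); remainder is no-response.
#' @param week14 named counts for week-14 calls (default
#'   `c(remission = 9, partial = 1, none = 14)` at 24 subjects).
#' @param week14_responders_by_donor named counts allocating the week-14
#'   responders to donors (default: 80% of them on the second donor label,
#'   the rest on the first, mirroring the trial's donor-dependent response).
#' @param n_dropouts number of double non-responders flagged as dropouts
#'   (default `min(3, available)`).
#' @param seed seed for the allocation shuffling.
#' @return list with `mayo` (long-format assessment table for
#'   [classify_mayo_table()]), `requested` (per-subject requested calls), and
#'   `calls` (the classifier's output, verified to equal the request).
#' @export
simulate_clinical <- function(donor,
                              week10 = NULL, week14 = NULL,
                              week14_responders_by_donor = NULL,
                              n_dropouts = 3L, seed = 1L) {
  n <- length(donor)
  subjects <- sprintf("R%02d", seq_len(n))
  set.seed(seed)
  prop_counts <- function(x, total) {
    cnt <- c(remission = unname(round(total * x[1] / sum(x))),
             partial = unname(round(total * x[2] / sum(x))))
    cnt
  }
  if (is.null(week10))
    week10 <- prop_counts(c(10, 2, 12), n)
  if (is.null(week14))
    week14 <- prop_counts(c(9, 1, 14), n)
  w10_resp <- sum(week10[c("remission", "partial")])
  w14_resp <- sum(week14[c("remission", "partial")])
  if (w10_resp > n || w14_resp > n)
    stop("requested more responders than subjects")

  dlev <- unique(donor)
  if (is.null(week14_responders_by_donor)) {
    week14_responders_by_donor <- if (length(dlev) >= 2)
      stats::setNames(c(round(0.2 * w14_resp), w14_resp - round(0.2 * w14_resp)),
                      dlev[1:2])
    else stats::setNames(w14_resp, dlev[1])
  }
  if (sum(week14_responders_by_donor) != w14_resp)
    stop("week14_responders_by_donor counts do not sum to the requested responders")

  # allocate week-14 responders per donor, then calls within responders
  w14_call <- rep("none", n)
  resp_idx <- integer(0)
  for (d in names(week14_responders_by_donor)) {
    cand <- which(donor == d)
    k <- week14_responders_by_donor[[d]]
    if (k > length(cand))
      stop("donor ", d, " has fewer recipients than requested responders")
    resp_idx <- c(resp_idx, sample(cand, k))
  }
  rem_idx <- resp_idx[seq_len(week14[["remission"]])]
  par_idx <- setdiff(resp_idx, rem_idx)
  w14_call[rem_idx] <- "remission"; w14_call[par_idx] <- "partial"

  # week-10 responders spread evenly across donors
  w10_call <- rep("none", n)
  ord <- order(stats::ave(seq_len(n), donor, FUN = seq_along))
  w10_resp_idx <- ord[seq_len(w10_resp)]
  w10_call[w10_resp_idx[seq_len(week10[["remission"]])]] <- "remission"
  w10_call[setdiff(w10_resp_idx,
                   w10_resp_idx[seq_len(week10[["remission"]])])] <- "partial"

  dbl_none <- which(w10_call == "none" & w14_call == "none")
  n_dropouts <- min(n_dropouts, length(dbl_none))
  drop_idx <- if (n_dropouts > 0) sample(dbl_none, n_dropouts) else integer(0)

  comp10 <- list(remission = c(1L, 0L, 1L), partial = c(1L, 1L, 1L),
                 none = c(2L, 2L, 1L))
  comp14 <- list(remission = list(c(1L, 0L, 1L), "1a"),
                 partial = list(c(1L, 1L, 1L), "1b"),
                 none = list(c(2L, 2L, 1L), "2"))
  rows <- list()
  add <- function(s, wk, comp, endo, dropped) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = s, week = wk, stool_frequency = comp[1],
      rectal_bleeding = comp[2], physician_global = comp[3],
      endoscopic = endo, dropped_out = dropped)
  }
  for (i in seq_len(n)) {
    s <- subjects[i]
    dropped <- i %in% drop_idx
    add(s, 0L, c(2L, 2L, 2L), "2", dropped)
    if (!dropped) {
      add(s, 10L, comp10[[w10_call[i]]], NA_character_, FALSE)
      add(s, 14L, comp14[[w14_call[i]]][[1]], comp14[[w14_call[i]]][[2]], FALSE)
    }
  }
  mayo <- do.call(rbind, c(rows, make.row.names = FALSE))
  requested <- data.frame(subject_id = subjects, donor = donor,
                          week10 = w10_call, week14 = w14_call,
                          dropped_out = seq_len(n) %in% drop_idx)
  calls <- classify_mayo_table(mayo)
  chk <- merge(requested,
               stats::reshape(calls[, c("subject_id", "week", "call")],
                              idvar = "subject_id", timevar = "week",
                              direction = "wide"))
  if (!all(chk$week10 == chk$call.10) || !all(chk$week14 == chk$call.14))
    stop("constructive clinical generator failed to realise the requested calls")
  list(mayo = mayo, requested = requested, calls = calls)
}
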