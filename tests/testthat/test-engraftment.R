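test_that("clr transform matches hand-computed values and centres to zero", {
  expect_equal(clr_transform(c(0.5, 0.5)), c(0, 0))
  expect_equal(clr_transform(rep(0.25, 4)), rep(0, 4))
  expect_equal(clr_transform(c(0.9, 0.1)), c(log(3), -log(3)), tolerance = 1e-12)
  # zero replacement + re-closure keeps sum-zero output
  set.seed(5)
  for (i in 1:20) {
    v <- random_composition(30)
    v[sample(30, 5)] <- 0
    expect_equal(sum(clr_transform(v)), 0, tolerance = 1e-9)
  }
  expect_error(clr_transform(numeric(1)), "length")
  expect_error(clr_transform(c(0, 0, 0)), "all-zero")
})

test_that("Aitchison distance has its closed-form values and metric behaviour", {
  a <- c(0.9, 0.1); b <- c(0.1, 0.9)
  expect_equal(aitchison_distance(a, b), 2 * sqrt(2) * log(3), tolerance = 1e-12)
  expect_equal(aitchison_distance(a, a), 0)
  expect_error(aitchison_distance(a, c(1, 2, 3)), "mismatch")

  set.seed(17)
  for (i in 1:200) {
    x <- random_composition(25); y <- random_composition(25)
    z <- random_composition(25)
    dxy <- aitchison_distance(x, y)
    expect_equal(dxy, aitchison_distance(y, x), tolerance = 1e-12)  # symmetry
    expect_gte(dxy, 0)
    expect_lte(dxy, aitchison_distance(x, z) + aitchison_distance(z, y) + 1e-9)
    # scale invariance: closure removes any positive multiplicative constant
    expect_equal(aitchison_distance(3.7 * x, y), dxy, tolerance = 1e-9)
  }
})

test_that("per-sample SEI sums donor-derived abundance above the detection limit", {
  s <- c(A = 0.05, B = 0.002, C = 0.948)
  expect_equal(sei_per_sample(s, c("A", "B")), 0.052)
  expect_equal(sei_per_sample(s, character(0)), 0)
  expect_equal(sei_per_sample(c(A = 0.0004, B = 0.0002, C = 0.9), c("A", "B")), 0)
})

test_that("window metrics follow the median conventions and window membership", {
  # recipient: weeks 0,3 baseline; 4,5,6 acute; 8,10 durable
  sp <- c("dd1", "dd2", "base1", "base2")
  rows <- rbind(
    w0  = c(0,    0,    0.6, 0.4),
    w3  = c(0,    0,    0.5, 0.5),
    w4  = c(0.10, 0,    0.5, 0.40),
    w5  = c(0.20, 0.05, 0.4, 0.35),
    w6  = c(0.60, 0,    0.2, 0.20),
    w8  = c(0.10, 0,    0.5, 0.40),
    w10 = c(0.30, 0,    0.4, 0.30))
  colnames(rows) <- sp
  donor <- matrix(c(0.3, 0.3, 0.2, 0.2), 1, dimnames = list("d1", sp))
  dd <- structure(list(subject_id = "R01", donor_id = "D", species = c("dd1", "dd2"),
                       n_species = 2L, n_pre_fmt_samples_used = 2L),
                  class = "donor_derived_set")
  em <- engraftment_metrics(rows, c(0, 3, 4, 5, 6, 8, 10), donor, dd)
  acute <- em[em$window == "acute", ]
  durable <- em[em$window == "durable", ]
  # odd count: middle per-sample SEI; even count: mean of the two middle
  expect_equal(acute$sei, 0.25)              # median of 0.10, 0.25, 0.60
  expect_equal(durable$sei, 0.20)            # mean of 0.10 and 0.30
  # dd2 detected at week 5 only: counts for acute, not durable
  expect_equal(acute$sef, 1)
  expect_equal(durable$sef, 0.5)
  expect_equal(acute$n_samples_in_window, 3L)

  # empty donor-derived set flags SEF as missing
  dd0 <- structure(list(subject_id = "R01", donor_id = "D", species = character(0),
                        n_species = 0L, n_pre_fmt_samples_used = 2L),
                   class = "donor_derived_set")
  em0 <- engraftment_metrics(rows, c(0, 3, 4, 5, 6, 8, 10), donor, dd0)
  expect_true(all(is.na(em0$sef)))
  expect_equal(em0$sei[em0$window == "acute"], 0)
})

test_that("donor similarity is the baseline-normalised reciprocal distance", {
  # identical pre and post compositions: window distance = baseline, similarity 1
  sp <- paste0("s", 1:6)
  base <- random_composition(6); names(base) <- sp
  donor <- matrix(random_composition(6), 1, dimnames = list("d1", sp))
  rows <- rbind(w3 = base, w5 = base)
  em <- engraftment_metrics(rows, c(3, 5), donor,
                            structure(list(species = character(0), n_species = 0L),
                                      class = "donor_derived_set"))
  expect_equal(em$similarity[em$window == "acute"], 1, tolerance = 1e-9)

  # moving exactly to the donor's composition gives a window distance of ~0;
  # halving the distance doubles similarity on a geometric path
  clr_mid <- function(a, b, t) {
    # point at fraction t along the Aitchison geodesic from a to b
    v <- exp((1 - t) * log(a) + t * log(b))
    v / sum(v)
  }
  d_vec <- donor[1, ]
  mid <- clr_mid(base, d_vec, 0.5)
  rows2 <- rbind(w3 = base, w5 = mid)
  em2 <- engraftment_metrics(rows2, c(3, 5), donor,
                             structure(list(species = character(0), n_species = 0L),
                                       class = "donor_derived_set"))
  expect_equal(em2$similarity[em2$window == "acute"], 2, tolerance = 1e-6)

  # similarity increases with the mixing fraction toward the donor
  sims <- vapply(c(0.2, 0.5, 0.8), function(t) {
    r <- rbind(w3 = base, w5 = clr_mid(base, d_vec, t))
    e <- engraftment_metrics(r, c(3, 5), donor,
                             structure(list(species = character(0), n_species = 0L),
                                       class = "donor_derived_set"))
    e$similarity[e$window == "acute"]
  }, numeric(1))
  expect_true(all(diff(sims) > 0))
})

test_that("total engraftment scores equalise cohort medians before summing", {
  # degenerate cohort: identical triplets give identical totals of 3x the median
  m <- data.frame(subject_id = c("a", "b"), window = "overall",
                  sei = 0.2, sef = 0.4, similarity = 2.0)
  tot <- total_engraftment_scores(m)
  expect_equal(tot$scores$total_score, c(1.2, 1.2))

  # hand-computed two-subject cohort
  m2 <- data.frame(subject_id = c("a", "b"), window = "overall",
                   sei = c(0.1, 0.3), sef = c(0.2, 0.4), similarity = c(1, 3))
  tot2 <- total_engraftment_scores(m2)
  expect_equal(tot2$normalization$scale_sei, 1.5)
  expect_equal(tot2$normalization$scale_similarity, 0.15)
  expect_equal(tot2$scores$total_score, c(0.5, 1.3))

  # scaled medians agree exactly by construction
  set.seed(23)
  m3 <- data.frame(subject_id = sprintf("r%02d", 1:15), window = "overall",
                   sei = runif(15, 0, 0.4), sef = runif(15),
                   similarity = runif(15, 0.5, 3))
  tot3 <- total_engraftment_scores(m3)
  nz <- tot3$normalization
  expect_equal(median(m3$sei) * nz$scale_sei, nz$reference_median,
               tolerance = 1e-12)
  expect_equal(median(m3$similarity) * nz$scale_similarity,
               nz$reference_median, tolerance = 1e-12)

  # ranking of totals is invariant to rescaling all similarities
  m4 <- m3; m4$similarity <- m3$similarity * 100
  tot4 <- total_engraftment_scores(m4)
  expect_equal(order(tot4$scores$total_score), order(tot3$scores$total_score))
  expect_equal(tot4$scores$total_score, tot3$scores$total_score,
               tolerance = 1e-9)

  # zero-median metric is dropped with a warning
  m5 <- data.frame(subject_id = c("a", "b", "c"), window = "overall",
                   sei = 0, sef = c(0.2, 0.4, 0.6), similarity = c(1, 2, 3))
  expect_warning(tot5 <- total_engraftment_scores(m5), "SEI")
  expect_equal(tot5$normalization$scale_sei, 0)

  expect_error(total_engraftment_scores(m2[1, ]), ">= 2 subjects")
})
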