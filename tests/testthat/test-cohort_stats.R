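test_that("Fisher's exact test follows the point-probability convention", {
  expect_equal(fisher_exact_2x2(c(5, 5, 5, 5))$p_value, 1)
  # matches the enumeration oracle on assorted tables
  set.seed(9)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 fisher_enum_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
  expect_warning(res <- fisher_exact_2x2(c(0, 0, 3, 4)), "degenerate")
  expect_equal(res$p_value, 1)
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "nonnegative")
})

test_that("chi-square on a 2x2 table is the Pearson statistic", {
  null <- chi_square_2x2(c(10, 10, 10, 10))
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)
  # hand computation: n (ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(chi_square_2x2(c(20, 0, 0, 20))$statistic, 40)
  tab <- matrix(c(12, 5, 3, 9), 2)
  expect_equal(chi_square_2x2(tab)$statistic, chi_square_2x2(t(tab))$statistic)
  expect_error(chi_square_2x2(c(1, 2, 0, 0)), "zero margin")
  # Yates correction shrinks the statistic
  expect_lt(chi_square_2x2(tab, yates = TRUE)$statistic,
            chi_square_2x2(tab)$statistic)
})

test_that("Wilcoxon rank-sum p is exact for small untied samples", {
  expect_equal(wilcoxon_rank_sum_exact(c(1, 2), c(3, 4))$p_value, 1 / 3)
  res <- wilcoxon_rank_sum_exact(c(1, 2), c(3, 4))
  expect_match(res$method, "exact")
  # degenerate tied singletons fall back to the approximation with p = 1
  tied <- wilcoxon_rank_sum_exact(1, 1)
  expect_equal(tied$p_value, 1)
  expect_match(tied$method, "approximation")
  # symmetry under group exchange
  set.seed(31)
  x <- rnorm(6); y <- rnorm(8)
  expect_equal(wilcoxon_rank_sum_exact(x, y)$p_value,
               wilcoxon_rank_sum_exact(y, x)$p_value, tolerance = 1e-12)
  # matches the enumeration oracle
  for (i in 1:20) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    x <- rnorm(n); y <- rnorm(m)
    expect_equal(wilcoxon_rank_sum_exact(x, y)$p_value, wilcox_enum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("two-way ANOVA reports per-factor Type II effects", {
  a <- rep(c("bud", "plc"), each = 12)
  b <- rep(rep(c("D07", "D08"), each = 6), 2)
  # constant response: no variance, F = 0, p = 1
  z <- two_way_anova(rep(1, 24), a, b)
  expect_equal(z$F, c(0, 0)); expect_equal(z$p_value, c(1, 1))
  expect_error(two_way_anova(rnorm(24), rep("x", 24), b), "two observed levels")
  # additive effects are both recovered at p < 0.01
  set.seed(12)
  score <- 2 * (a == "bud") + 3 * (b == "D07") + rnorm(24, sd = 0.5)
  res <- two_way_anova(score, a, b)
  expect_true(all(res$p_value < 0.01))
  # unbalanced design: drop 5 subjects, effects still detected
  keep <- -c(1, 2, 3, 13, 14)
  res_u <- two_way_anova(score[keep], a[keep], b[keep])
  expect_true(all(res_u$p_value < 0.01))
})

test_that("diversity reports detected richness and Shannon entropy", {
  u <- diversity_profile(c(a = 0.25, b = 0.25, c = 0.25, d = 0.25))
  expect_equal(u$observed_species, 4)
  expect_equal(u$shannon, log(4), tolerance = 1e-9)
  expect_equal(diversity_profile(c(a = 1))$shannon, 0)
  expect_equal(diversity_profile(c(a = 0.5, b = 0.25, c = 0.25))$shannon,
               1.0397, tolerance = 1e-4)
  # sub-tau species are excluded from richness
  expect_equal(diversity_profile(c(a = 0.9995, b = 0.0005))$observed_species, 1)
  expect_error(diversity_profile(c(a = 0.0001)), "no species")
  # uniform composition maximises Shannon at fixed richness
  set.seed(2)
  for (i in 1:20) {
    p <- random_composition(10)
    expect_lte(diversity_profile(p / sum(p), tau = 0)$shannon, log(10) + 1e-12)
  }
})

test_that("PERMANOVA is seed-reproducible and relabel-invariant", {
  set.seed(4)
  x <- rbind(matrix(rnorm(20, 0), 5), matrix(rnorm(20, 3), 5))
  lab <- rep(c("g1", "g2"), each = 5)
  r1 <- permanova(dist(x), lab, n_perm = 199, seed = 99)
  r2 <- permanova(dist(x), lab, n_perm = 199, seed = 99)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$statistic, r2$statistic)
  expect_gte(r1$p_value, 1 / 200)
  # permuting samples together with labels leaves the pseudo-F unchanged
  perm <- sample(10)
  r3 <- permanova(dist(x[perm, ]), lab[perm], n_perm = 199, seed = 99)
  expect_equal(r3$statistic, r1$statistic, tolerance = 1e-9)
  expect_error(permanova(dist(x), rep("g1", 10)), "two distinct groups")
  expect_error(permanova(dist(x), c("a", rep("b", 9))), "at least two samples")
})

test_that("donor family clustering is complete linkage on Euclidean distance", {
  # identical donors merge at height zero
  two <- matrix(c(1, 2, 1, 2), 2, byrow = TRUE,
                dimnames = list(c("D07", "D08"), c("f1", "f2")))
  expect_equal(donor_family_clustering(two)$height, 0)
  # mutual distances 1, 1, 10: first merge at 1, second at 10 (complete linkage)
  three <- matrix(c(0, 0, 1, 0, 10, 0), 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), c("f1", "f2")))
  d <- as.matrix(dist(three))
  h <- donor_family_clustering(three)$height
  expect_equal(h[1], 1)
  expect_equal(h[2], max(d["a", "c"], d["b", "c"]))
  expect_true(all(diff(h) >= 0))
  # merge heights equal the brute-force agglomeration oracle for small trees
  set.seed(6)
  for (i in 1:10) {
    m <- matrix(rnorm(8 * 5), 8, dimnames = list(paste0("d", 1:8), NULL))
    expect_equal(sort(donor_family_clustering(m)$height),
                 sort(complete_linkage_heights(as.matrix(dist(m)))),
                 tolerance = 1e-9)
  }
  expect_error(donor_family_clustering(two[1, , drop = FALSE]), "two donors")
})
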