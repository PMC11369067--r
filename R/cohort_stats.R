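#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value under the point-probability convention: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability does not exceed that of the observed table (up to a
#' relative tolerance of 1e-7 in the comparison). A table with a zero row or
#' column margin carries no information and returns p = 1 with a warning.
#'
#' @param tab 2x2 integer matrix, rows = groups, columns = outcomes; or the
#'   four counts `c(a, b, c, d)` filled by row.
#' @return an `engraft_test` list: `statistic` (odds-ratio estimate when
#'   defined), `p_value`, `method`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- .as_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin in 2x2 table; p = 1")
    return(.test_result(NA_real_, 1, "Fisher's exact test (degenerate margin)"))
  }
  ht <- stats::fisher.test(tab)
  .test_result(unname(ht$estimate), ht$p.value,
               "Fisher's exact test (two-sided, point-probability rule)")
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param tab 2x2 matrix or `c(a, b, c, d)` by row.
#' @param yates apply the continuity correction (default FALSE).
#' @return an `engraft_test` with the X-squared statistic and its p-value on
#'   1 degree of freedom. Zero margins are an error.
#' @export
chi_square_2x2 <- function(tab, yates = FALSE) {
  tab <- .as_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test undefined for a table with a zero margin")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  .test_result(unname(ht$statistic), ht$p.value,
               paste0("Pearson chi-square", if (yates) " with Yates correction"))
}

#' Wilcoxon rank-sum test, exact for small untied samples
#'
#' Exact two-sided p by enumeration of the rank-sum null distribution when
#' both groups have at most 12 observations and there are no ties; otherwise
#' the mid-rank normal approximation with tie correction and continuity
#' correction, with the method used recorded in the result.
#'
#' @param x,y numeric vectors, both nonempty.
#' @return an `engraft_test` with the Mann-Whitney W statistic and p-value.
#' @export
wilcoxon_rank_sum_exact <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  if (length(unique(c(x, y))) == 1)
    return(.test_result(length(x) * length(y) / 2, 1,
                        "Wilcoxon rank sum test, normal approximation with tie correction (degenerate: all values tied)"))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 12 && length(y) <= 12
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  .test_result(unname(ht$statistic), ht$p.value,
               if (exact) "Wilcoxon rank sum exact test"
               else "Wilcoxon rank sum test, normal approximation with tie correction")
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Fits the additive two-factor model and reports each factor's effect while
#' controlling for the other, using Type II sums of squares so that the
#' unbalanced designs typical of small trials are handled sensibly. A score
#' vector with zero variance yields F = 0, p = 1 for both factors.
#'
#' @param score numeric response, one value per subject.
#' @param factor_a,factor_b grouping factors (each must have >= 2 observed
#'   levels).
#' @return data.frame with one row per factor: `factor`, `F`, `p_value`,
#'   `df`, `sum_sq`.
#' @export
two_way_anova <- function(score, factor_a, factor_b) {
  factor_a <- factor(factor_a); factor_b <- factor(factor_b)
  if (nlevels(droplevels(factor_a)) < 2 || nlevels(droplevels(factor_b)) < 2)
    stop("each factor needs at least two observed levels")
  if (stats::var(score) == 0)
    return(data.frame(factor = c("factor_a", "factor_b"), F = c(0, 0),
                      p_value = c(1, 1), df = NA_integer_, sum_sq = c(0, 0)))
  fit <- stats::lm(score ~ factor_a + factor_b)
  aov2 <- car::Anova(fit, type = 2)
  rows <- c("factor_a", "factor_b")
  data.frame(factor = rows, F = aov2[rows, "F value"],
             p_value = aov2[rows, "Pr(>F)"], df = aov2[rows, "Df"],
             sum_sq = aov2[rows, "Sum Sq"], row.names = NULL)
}

#' Richness and Shannon diversity of one sample
#'
#' Observed species is the count of taxa at or above the detection limit;
#' Shannon diversity (natural-log units) is computed on the detected taxa
#' re-closed to unit sum.
#'
#' @param sample_abund abundance vector for one sample.
#' @param tau detection limit (default 0.001).
#' @return list with `observed_species` and `shannon`.
#' @export
diversity_profile <- function(sample_abund, tau = 0.001) {
  v <- sample_abund[sample_abund >= tau]
  if (!length(v)) stop("no species detected in sample")
  p <- v / sum(v)
  list(observed_species = length(v),
       shannon = as.numeric(vegan::diversity(p, index = "shannon")))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' from the distance-based between/within sum-of-squares decomposition, with
#' p = (1 + number of permuted F >= observed F) / (1 + n_perm). The seed makes
#' the permutation p-value bit-reproducible.
#'
#' @param d `dist` object or square symmetric distance matrix.
#' @param labels group label per sample (>= 2 groups, each with >= 2 samples).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer RNG seed.
#' @return an `engraft_test` with pseudo-F, `p_value`, `n_permutations`,
#'   `seed`.
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L) {
  d <- stats::as.dist(d)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("PERMANOVA needs at least two distinct groups")
  if (any(table(labels) < 2))
    stop("every group needs at least two samples")
  set.seed(seed)
  df <- data.frame(group = labels)
  fit <- vegan::adonis2(d ~ group, data = df, permutations = n_perm)
  res <- .test_result(fit$F[1], fit$`Pr(>F)`[1],
                      sprintf("PERMANOVA (%d permutations)", n_perm))
  res$n_permutations <- as.integer(n_perm)
  res$seed <- as.integer(seed)
  res
}

#' Complete-linkage clustering of donor family profiles
#'
#' Donors are clustered by their mean relative abundance of taxonomic
#' families using Euclidean distance and complete linkage, so each merge
#' height equals the maximum pairwise distance between the merged clusters.
#'
#' @param mean_family_abundances numeric matrix, donors x families.
#' @return an `hclust` tree (method `"complete"`); merge heights are
#'   nondecreasing.
#' @export
donor_family_clustering <- function(mean_family_abundances) {
  if (nrow(mean_family_abundances) < 2)
    stop("clustering needs at least two donors")
  stats::hclust(stats::dist(mean_family_abundances, method = "euclidean"),
                method = "complete")
}

.as_2x2 <- function(tab) {
  if (!is.matrix(tab)) {
    if (length(tab) != 4) stop("need a 2x2 table or four counts a,b,c,d")
    tab <- matrix(tab, nrow = 2, byrow = TRUE)
  }
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (sum(tab) < 1) stop("table total must be >= 1")
  storage.mode(tab) <- "integer"
  tab
}

.test_result <- function(statistic, p_value, method) {
  structure(list(statistic = statistic, p_value = p_value, method = method),
            class = "engraft_test")
}

#' @export
print.engraft_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic)) cat("  statistic:", format(x$statistic), "\n")
  cat("  p-value:  ", format(x$p_value), "\n")
  invisible(x)
}
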