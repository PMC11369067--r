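# Independent oracles used by the property and acceptance tests. These are
# deliberately naive (full enumeration, brute-force counting) and never call
# the implementation paths they check.

# Two-sided Fisher p by full enumeration of the hypergeometric support:
# sum of point probabilities of all tables with the observed margins that are
# no more probable than the observed table (relative tolerance on the
# comparison).
fisher_enum_p <- function(a, b, c, d, tol = 1e-7) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(pr[pr <= p0 * (1 + tol)])
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of the
# pooled ranks to group x (no ties assumed).
wilcox_enum_p <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(N, n)
  u_all <- colSums(matrix(sort(r)[sets], nrow = n)) - n * (n + 1) / 2
  pl <- mean(u_all <= u_obs); pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}

# Brute-force restatement of the clinical response rules, written as flat
# logical expressions over raw subscores.
endo_levels <- c("0", "1a", "1b", "2", "3")
oracle_week10 <- function(b1, b2, b3, f1, f2, f3, dropped = FALSE) {
  if (dropped) return("none")
  if (f1 + f2 + f3 <= 2 && f1 <= 2 && f2 <= 2 && f3 <= 2) return("remission")
  if ((b1 + b2 + b3) - (f1 + f2 + f3) >= 3) return("partial")
  "none"
}
oracle_week14 <- function(b1, b2, b3, be, f1, f2, f3, fe, dropped = FALSE) {
  if (dropped) return("none")
  if (f1 + f2 + f3 <= 2 && f1 <= 2 && f2 <= 2 && f3 <= 2 &&
      fe %in% c("0", "1a")) return("remission")
  if ((b1 + b2 + b3) - (f1 + f2 + f3) >= 3 &&
      match(be, endo_levels) - match(fe, endo_levels) >= 1) return("partial")
  "none"
}

# Naive complete-linkage agglomeration; returns sorted merge heights.
complete_linkage_heights <- function(dmat) {
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(dmat[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Random composition on the simplex (strictly positive).
random_composition <- function(k) {
  v <- stats::rgamma(k, shape = 1)
  v / sum(v)
}

# Tiny abundance fixture: 3 samples x 4 species relative table.
tiny_profiles <- function() {
  m <- matrix(c(0.50, 0.30, 0.15, 0.05,
                0.25, 0.25, 0.25, 0.25,
                0.90, 0.05, 0.04, 0.01),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), paste0("sp", 1:4)))
  abundance_table(m)
}
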