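#' Two-sided correlation p value from the t transform
#'
#' p from t = r*sqrt(n-2)/sqrt(1-r^2) on n-2 degrees of freedom — the
#' t-distribution statistic `cor.test()` uses for both Pearson r and (as an
#' approximation with average ranks) Spearman rho.
#'
#' @param r correlation estimate(s).
#' @param n number of complete pairs.
#' @return two-sided p value(s); NA where n < 3 or r is NA.
#' @export
cor_p_from_t <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n >= 3
  rr <- pmin(pmax(r[ok], -1), 1)
  tt <- rr * sqrt((n[ok] - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n[ok] - 2)
  p
}

#' Fisher z transform with clipping at |r| = 1
#' @param r correlation(s); values with |r| = 1 are clipped to 1 - 1e-12
#'   (with a warning) so the transform stays finite.
#' @return atanh(r).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("correlations with |r| >= 1 clipped before Fisher z")
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  atanh(r)
}

#' Pairwise-complete correlation between the rows of two matrices
#'
#' Row i of `a` against row i of `b` (same rownames), over samples where both
#' are observed. Vectorized complete-pair count included.
#'
#' @keywords internal
row_pair_cor <- function(a, b, method = "pearson") {
  stopifnot(nrow(a) == nrow(b), ncol(a) == ncol(b))
  n <- rowSums(!is.na(a) & !is.na(b))
  r <- vapply(seq_len(nrow(a)), function(i) {
    ok <- !is.na(a[i, ]) & !is.na(b[i, ])
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(stats::cor(a[i, ok], b[i, ok], method = method))
  }, numeric(1))
  list(r = r, n = n)
}

#' Adjusted Rand index between two labelings
#' @param a,b cluster label vectors of equal length.
#' @return ARI in [-1, 1]; 1 means identical partitions up to renaming.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# internal: derive a reproducible sub-seed (kept < 2^31) from a master seed
sub_seed <- function(seed, i) (as.integer(seed) %% 100000L) * 13L + 7919L * i %% 2101870147L
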