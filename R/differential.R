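#' Minimum PSM count per protein over contributing TMT sets
#'
#' The per-set PSM sums are reduced to a per-gene minimum over the sets that
#' contribute samples to the analysis, ignoring zero and missing sums; genes
#' with no quantified PSM in any contributing set are excluded.
#'
#' @param psm genes x sets count matrix (as from [simulate_psm_counts()]).
#' @param contributing_sets column names of the sets entering the analysis
#'   (default all).
#' @return named integer vector of min counts; excluded genes are absent.
#' @export
min_psm_per_protein <- function(psm, contributing_sets = colnames(psm)) {
  if (!length(contributing_sets)) stop("contributing_sets is empty")
  x <- psm[, contributing_sets, drop = FALSE]
  mins <- apply(x, 1L, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) NA_real_ else min(v)
  })
  mins[!is.na(mins)]
}

#' PSM-count moderated two-group differential abundance
#'
#' Per-gene two-group contrast on log2 values with residual variance pooled
#' across all strata (the two contrasted groups plus an optional combined
#' "other" stratum). Across genes, a loess trend of the log residual variance
#' on the log min-PSM count is fitted (with the chi-square log-bias per gene's
#' residual df removed, and clamped at the observed count range); each gene's
#' variance is shrunk toward its trend value with an empirical-Bayes prior of
#' `prior_df` degrees of freedom, giving a moderated t on d_g + prior_df df.
#' This is the documented core of PSM-moderated empirical-Bayes testing, not a
#' port of any package's internals. Genes are kept when every group has at
#' least one quantified value.
#'
#' @param matrix [omics_matrix()] of log2 protein ratios.
#' @param groups named vector sample -> label; exactly two labels are
#'   contrasted (`contrast`), any remaining samples form the "other" stratum
#'   when `include_other = TRUE`.
#' @param contrast character(2): the labels to compare (A vs B, log2FC =
#'   mean(A) - mean(B)). Defaults to the first two labels.
#' @param psm_min named per-gene min PSM vector from [min_psm_per_protein()];
#'   `NULL` disables the trend (flat prior at the mean variance).
#' @param prior_df prior degrees of freedom d0 (default 3); `0` reproduces the
#'   ordinary two-sample pooled t exactly.
#' @param q_cut,fc_cut significance cut-offs (defaults 0.01 and log2(1.5)).
#' @param trend_span loess span for the variance trend.
#' @return data.frame of class `de_result`: gene, logFC, mean_a, mean_b,
#'   n_a, n_b, s2, df, s2_prior, s2_mod, t, t_ordinary, p, q, min_psm,
#'   significant; attribute `n_dropped`.
#' @export
moderated_ttest <- function(matrix, groups, contrast = NULL, psm_min = NULL,
                            prior_df = 3, q_cut = 0.01, fc_cut = log2(1.5),
                            include_other = TRUE, trend_span = 0.75) {
  g <- groups[colnames(matrix)]
  keep_s <- !is.na(g)
  x <- matrix[, keep_s, drop = FALSE]
  g <- as.character(g[keep_s])
  labs <- unique(g)
  if (is.null(contrast)) contrast <- labs[1:2]
  if (!all(contrast %in% labs)) stop("contrast labels not present in groups")
  stratum <- ifelse(g %in% contrast, g, "other")
  if (!include_other) {
    x <- x[, stratum != "other", drop = FALSE]
    stratum <- stratum[stratum != "other"]
  }
  strata <- unique(stratum)
  G <- nrow(x)
  mean_by <- function(lbl) rowMeans(x[, stratum == lbl, drop = FALSE],
                                    na.rm = TRUE)
  n_by <- function(lbl) rowSums(!is.na(x[, stratum == lbl, drop = FALSE]))
  means <- vapply(strata, mean_by, numeric(G))
  ns <- vapply(strata, n_by, numeric(G))
  colnames(means) <- colnames(ns) <- strata
  # pooled residual variance across all strata
  rss <- base::matrix(0, G, 1)
  for (lbl in strata) {
    sub <- x[, stratum == lbl, drop = FALSE]
    rss <- rss + rowSums((sub - means[, lbl])^2, na.rm = TRUE)
  }
  df_resid <- rowSums(ns) - rowSums(ns > 0)
  other_ok <- if ("other" %in% strata) ns[, "other"] > 0 else TRUE
  valid <- rowSums(ns[, contrast, drop = FALSE] > 0) == 2 & other_ok
  n_dropped <- sum(!valid)
  keep <- valid & df_resid >= 1
  genes <- rownames(x)[keep]
  s2 <- as.numeric(rss)[keep] / df_resid[keep]
  d <- df_resid[keep]
  # variance trend on log min PSM, chi-square log-bias removed per gene
  bias <- digamma(d / 2) - log(d / 2)
  y <- log(pmax(s2, 1e-12)) - bias
  if (!is.null(psm_min)) {
    mp <- psm_min[genes]
    mp[is.na(mp)] <- stats::median(psm_min, na.rm = TRUE)
    lx <- log(pmax(mp, 1))
    lx_cl <- pmin(pmax(lx, stats::quantile(lx, 0.01)),
                  stats::quantile(lx, 0.99))
    tr <- stats::loess(y ~ lx_cl, span = trend_span, degree = 1)
    s2_prior <- exp(stats::predict(tr, lx_cl))
  } else {
    mp <- rep(NA_real_, length(genes))
    s2_prior <- rep(exp(mean(y)), length(genes))
  }
  if (prior_df > 0) {
    s2_mod <- (prior_df * s2_prior + d * s2) / (prior_df + d)
    df_mod <- d + prior_df
  } else {
    s2_mod <- s2
    df_mod <- d
  }
  na <- ns[keep, contrast[1]]; nb <- ns[keep, contrast[2]]
  fc <- means[keep, contrast[1]] - means[keep, contrast[2]]
  se_scale <- sqrt(1 / na + 1 / nb)
  t_mod <- fc / (sqrt(s2_mod) * se_scale)
  t_ord <- fc / (sqrt(s2) * se_scale)
  p <- 2 * stats::pt(-abs(t_mod), df = df_mod)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = genes, logFC = fc, mean_a = means[keep, contrast[1]],
                    mean_b = means[keep, contrast[2]], n_a = na, n_b = nb,
                    s2 = s2, df = d, s2_prior = s2_prior, s2_mod = s2_mod,
                    t = t_mod, t_ordinary = t_ord, p = p, q = q,
                    min_psm = unname(mp),
                    significant = q <= q_cut & abs(fc) >= fc_cut,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", "data.frame")
  out
}

#' Welch t contrast on log2(TPM + 1) mRNA (labeled stand-in)
#'
#' Transcript-level differential expression here is a plain Welch t-test on
#' log2 values, provided for symmetry with the protein contrast; it is a
#' clearly labeled stand-in, not a count-model test.
#'
#' @param matrix mRNA [omics_matrix()].
#' @param groups,contrast as in [moderated_ttest()].
#' @return data.frame gene, logFC, t, p, q.
#' @export
mrna_welch_test <- function(matrix, groups, contrast = NULL) {
  g <- groups[colnames(matrix)]
  keep <- !is.na(g)
  x <- matrix[, keep, drop = FALSE]
  g <- as.character(g[keep])
  if (is.null(contrast)) contrast <- unique(g)[1:2]
  a <- x[, g == contrast[1], drop = FALSE]
  b <- x[, g == contrast[2], drop = FALSE]
  res <- t(vapply(seq_len(nrow(x)), function(i) {
    tt <- tryCatch(stats::t.test(a[i, ], b[i, ]),
                   error = function(e) NULL)
    if (is.null(tt)) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(a[i, ], na.rm = TRUE) - mean(b[i, ], na.rm = TRUE),
      unname(tt$statistic), tt$p.value)
  }, numeric(3)))
  out <- data.frame(gene = rownames(x), logFC = res[, 1], t = res[, 2],
                    p = res[, 3], stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
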