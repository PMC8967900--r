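#' Gene-wise correlation between two sample-aligned omics layers
#'
#' One record per shared feature: correlation across pairwise-complete
#' samples, two-sided p from the t transform (t = r*sqrt(n-2)/sqrt(1-r^2) on
#' n-2 df; for Spearman the same transform applied to rho with average-rank
#' ties), and Benjamini-Hochberg q over the table. Features with fewer than
#' `min_n` complete pairs are dropped and counted. With `complete_only = TRUE`
#' only features observed in every sample of both layers enter (the
#' complete-case filter); default is pairwise filtering.
#'
#' @param a,b [omics_matrix()] objects sharing sample columns.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_n minimum pairwise-complete samples (default 10).
#' @param complete_only restrict to complete-case features.
#' @return data.frame of class `correlation_table` (id_a, id_b, method, r,
#'   n_pairs, p, q) with attributes `median_r` and `n_dropped`.
#' @export
paired_feature_correlation <- function(a, b, method = c("spearman", "pearson"),
                                       min_n = 10, complete_only = FALSE) {
  method <- match.arg(method)
  al <- align_samples(a, b)
  shared <- intersect(rownames(al$a), rownames(al$b))
  if (!length(shared)) stop("no shared features")
  A <- al$a[shared, , drop = FALSE]
  B <- al$b[shared, , drop = FALSE]
  if (complete_only) {
    keep <- rowSums(is.na(A)) == 0 & rowSums(is.na(B)) == 0
    A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
    shared <- shared[keep]
  }
  rc <- row_pair_cor(A, B, method = method)
  keep <- !is.na(rc$r) & rc$n >= min_n
  tab <- data.frame(id_a = shared[keep], id_b = shared[keep], method = method,
                    r = rc$r[keep], n_pairs = rc$n[keep],
                    stringsAsFactors = FALSE)
  tab$p <- cor_p_from_t(tab$r, tab$n_pairs)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  attr(tab, "median_r") <- stats::median(tab$r)
  attr(tab, "n_dropped") <- sum(!keep)
  class(tab) <- c("correlation_table", "data.frame")
  message(sprintf("%s correlation for %d features (median r = %.3f, %d dropped)",
                  method, nrow(tab), attr(tab, "median_r"), sum(!keep)))
  tab
}

# internal: all within-complex pairs after restricting members to available
# features; excludes complexes on the blocklist (matched by name, fixed = TRUE)
complex_pairs <- function(catalog, features, blocklist = character()) {
  keep <- rep(TRUE, nrow(catalog))
  for (b in blocklist)
    keep <- keep & !grepl(b, catalog$name, ignore.case = TRUE, fixed = FALSE)
  excluded <- catalog$complex_id[!keep]
  out <- list()
  for (i in which(keep)) {
    m <- intersect(catalog$members[[i]], features)
    if (length(m) >= 2) {
      cmb <- utils::combn(sort(m), 2)
      out[[length(out) + 1L]] <- data.frame(
        complex_id = catalog$complex_id[i], a = cmb[1, ], b = cmb[2, ],
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(complex_id = character(), a = character(), b = character())
  attr(pairs, "excluded") <- excluded
  pairs
}

#' Default complex blocklist: the four very large complexes whose members
#' would dominate the pair population.
#' @export
default_complex_blocklist <- function()
  c("spliceosome", "Nop56p-associated pre-rRNA", "ribosome", "proteasome")

#' Within-complex vs random-pair co-regulation test
#'
#' Pearson correlations of all within-complex feature pairs (pairwise-complete
#' samples, `min_n` enforced) are compared to an equal number (default) of
#' uniformly sampled non-complex pairs by a two-sided unpaired t-test.
#' Complexes whose name matches the blocklist are excluded.
#'
#' @param matrix [omics_matrix()].
#' @param catalog `complex_catalog`.
#' @param n_random random pairs to draw (without replacement); `NULL` matches
#'   the within-complex pair count.
#' @param blocklist character patterns of complex names to exclude.
#' @param min_n minimum pairwise-complete samples per pair.
#' @param seed RNG seed for the random pairs.
#' @return list of class `complex_coregulation`: `within` / `random`
#'   correlation vectors, `mean_within`, `mean_random`, `p` (t-test),
#'   `excluded_complexes`, `n_pairs`.
#' @export
complex_coregulation_test <- function(matrix, catalog, n_random = NULL,
                                      blocklist = default_complex_blocklist(),
                                      min_n = 10, seed = 1) {
  pairs <- complex_pairs(catalog, rownames(matrix), blocklist)
  if (!nrow(pairs)) stop("no complex with >= 2 quantified members")
  pair_r <- function(a, b) {
    rc <- row_pair_cor(matrix[a, , drop = FALSE], matrix[b, , drop = FALSE])
    ifelse(rc$n >= min_n, rc$r, NA_real_)
  }
  within <- pair_r(pairs$a, pairs$b)
  within <- within[!is.na(within)]
  if (!length(within)) stop("no within-complex pair with enough complete samples")
  set.seed(seed)
  n_random <- if (is.null(n_random)) length(within) else n_random
  feats <- rownames(matrix)
  all_pairs <- complex_pairs(catalog, rownames(matrix), character(0))
  in_complex_key <- paste(all_pairs$a, all_pairs$b)
  rnd <- character(0)
  got <- 0L; guard <- 0L
  random_r <- numeric(0)
  while (got < n_random && guard < 50L) {
    guard <- guard + 1L
    i <- sample(feats, 2L * (n_random - got) * 2L, replace = TRUE)
    a <- i[seq_len(length(i) / 2)]; b <- i[-seq_len(length(i) / 2)]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    key <- paste(a, b)
    ok <- a != b & !(key %in% in_complex_key) & !duplicated(key) &
      !(key %in% rnd)
    a <- a[ok]; b <- b[ok]; key <- key[ok]
    if (!length(a)) next
    r <- pair_r(a, b)
    keep <- !is.na(r)
    take <- seq_len(min(sum(keep), n_random - got))
    random_r <- c(random_r, r[keep][take])
    rnd <- c(rnd, key[keep][take])
    got <- length(random_r)
  }
  tt <- stats::t.test(within, random_r)
  res <- list(within = within, random = random_r,
              mean_within = mean(within), mean_random = mean(random_r),
              p = tt$p.value, statistic = unname(tt$statistic),
              excluded_complexes = attr(pairs, "excluded"),
              n_pairs = c(within = length(within), random = length(random_r)))
  class(res) <- "complex_coregulation"
  res
}

#' @export
print.complex_coregulation <- function(x, ...) {
  cat(sprintf(
    "<complex_coregulation> mean r within %.3f vs random %.3f (n = %d/%d), t-test p = %.3g\n",
    x$mean_within, x$mean_random, x$n_pairs[1], x$n_pairs[2], x$p))
  invisible(x)
}

#' Compare groups of correlations on the Fisher-z scale
#'
#' Correlations are mapped by z = atanh(r) (|r| = 1 clipped with a warning);
#' two groups are compared by Welch's two-sided t-test, more than two by
#' one-way ANOVA.
#'
#' @param correlations `correlation_table` (or data.frame with `r` and an id
#'   column `id_a`).
#' @param grouping named vector feature -> group label.
#' @param mode `"auto"` picks by group count; `"two_group"` / `"multi_group"`
#'   force the test.
#' @return list `statistic`, `p`, `method`, `group_means` (z scale), `df`.
#' @export
grouped_correlation_test <- function(correlations, grouping,
                                     mode = c("auto", "two_group",
                                              "multi_group")) {
  mode <- match.arg(mode)
  g <- grouping[correlations$id_a]
  ok <- !is.na(g) & !is.na(correlations$r)
  z <- fisher_z(correlations$r[ok])
  g <- factor(g[ok])
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 3))
    stop("need >= 2 groups with >= 3 members each")
  if (mode == "auto") mode <- if (nlevels(g) == 2) "two_group" else "multi_group"
  if (mode == "two_group") {
    if (nlevels(g) != 2) stop("two_group mode needs exactly 2 groups")
    tt <- stats::t.test(z ~ g)  # Welch by default
    out <- list(statistic = unname(tt$statistic), p = tt$p.value,
                method = "welch_t", df = unname(tt$parameter))
  } else {
    fit <- stats::aov(z ~ g)
    an <- summary(fit)[[1]]
    out <- list(statistic = an$`F value`[1], p = an$`Pr(>F)`[1],
                method = "anova_f", df = an$Df)
  }
  out$group_means <- tapply(z, g, mean)
  out
}

#' Rank features by correlation (descending, lexicographic tie-break)
#'
#' The resulting named score vector feeds [preranked_gsea()] directly.
#'
#' @param correlations `correlation_table`.
#' @return named numeric vector of r, ordered.
#' @export
rank_genes <- function(correlations) {
  if (!nrow(correlations)) stop("empty correlation table")
  ord <- order(-correlations$r, correlations$id_a)
  stats::setNames(correlations$r[ord], correlations$id_a[ord])
}
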