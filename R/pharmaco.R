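#' Filter to effective drugs
#'
#' Retains drugs reaching sDSS >= `threshold` in at least `min_lines` cell
#' lines (missing entries never qualify). The drug-protein correlation layer
#' of the study used >= 8 in >= 2 lines; the embedding layer >= 8 in >= 1.
#'
#' @param sdss [drug_response_matrix()].
#' @param threshold sDSS cut (default 8).
#' @param min_lines minimum qualifying cell lines (default 2).
#' @return character vector of retained drug ids.
#' @export
filter_effective_drugs <- function(sdss, threshold = 8, min_lines = 2) {
  stopifnot(is.finite(threshold), min_lines >= 1)
  n_hit <- rowSums(sdss >= threshold, na.rm = TRUE)
  kept <- rownames(sdss)[n_hit >= min_lines]
  message(sprintf("effective drugs: %d / %d at sDSS >= %g in >= %d lines",
                  length(kept), nrow(sdss), threshold, min_lines))
  kept
}

# internal: pairwise-complete Pearson between rows of a (drugs) and rows of b
# (features), with complete-pair counts; entries with n < min_n set missing
cross_cor <- function(a, b, min_n = 10) {
  r <- base::matrix(NA_real_, nrow(a), nrow(b),
                    dimnames = list(rownames(a), rownames(b)))
  n <- r
  tb <- t(b)
  for (i in seq_len(nrow(a))) {
    x <- a[i, ]
    ok_x <- !is.na(x)
    cnt <- colSums(ok_x & !is.na(tb))
    ri <- suppressWarnings(stats::cor(x, tb, use = "pairwise.complete.obs"))
    ri[cnt < pmax(min_n, 3)] <- NA_real_
    r[i, ] <- ri
    n[i, ] <- cnt
  }
  list(r = r, n = n)
}

#' Drug-protein (or drug-mRNA) correlations with putative-target ranking
#'
#' Pearson r for every (drug, feature) pair over pairwise-complete samples
#' (entries with fewer than `min_n` pairs are missing), companion n and p
#' matrices, and — when annotations are supplied — the rank of each drug's
#' putative target(s) among all features by descending r with lexicographic
#' tie-break, plus a per-drug top-`top_k` table.
#'
#' @param sdss [drug_response_matrix()] (already filtered to effective drugs
#'   if desired).
#' @param features [omics_matrix()].
#' @param min_n minimum complete pairs (default 10).
#' @param annotations drug annotation data.frame with `drug_id` and a
#'   `targets` list-column (optional).
#' @param top_k size of the per-drug top table (default 10).
#' @return list of class `drug_feature_cor`: `r`, `n`, `p` matrices;
#'   `target_ranks` (drug_id, target, r, rank, n_features);
#'   `top_features` (drug_id, feature, r, rank).
#' @export
drug_feature_correlations <- function(sdss, features, min_n = 10,
                                      annotations = NULL, top_k = 10) {
  al <- align_samples(sdss, features)
  cc <- cross_cor(al$a, al$b, min_n = min_n)
  p <- cor_p_from_t(cc$r, cc$n)
  dim(p) <- dim(cc$r); dimnames(p) <- dimnames(cc$r)
  rank_one <- function(drug) {
    r <- cc$r[drug, ]
    ok <- !is.na(r)
    ord <- order(-r[ok], names(r)[ok])
    stats::setNames(seq_along(ord), names(r)[ok][ord])
  }
  top <- NULL; tr <- NULL
  all_ranks <- lapply(rownames(cc$r), rank_one)
  names(all_ranks) <- rownames(cc$r)
  top <- do.call(rbind, lapply(rownames(cc$r), function(d) {
    rk <- all_ranks[[d]]
    k <- utils::head(names(rk), top_k)
    data.frame(drug_id = d, feature = k, r = cc$r[d, k],
               rank = rk[k], stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (!is.null(annotations)) {
    rows <- list()
    for (j in seq_len(nrow(annotations))) {
      d <- annotations$drug_id[j]
      if (!d %in% rownames(cc$r)) next
      for (tg in annotations$targets[[j]]) {
        rk <- all_ranks[[d]]
        rows[[length(rows) + 1L]] <- data.frame(
          drug_id = d, target = tg,
          r = if (tg %in% colnames(cc$r)) cc$r[d, tg] else NA_real_,
          rank = if (tg %in% names(rk)) unname(rk[tg]) else NA_integer_,
          n_features = length(rk), stringsAsFactors = FALSE)
      }
    }
    tr <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  res <- list(r = cc$r, n = cc$n, p = p, target_ranks = tr,
              top_features = top)
  class(res) <- "drug_feature_cor"
  res
}

#' All-pairs drug-drug sDSS correlations
#'
#' @param sdss [drug_response_matrix()].
#' @param min_n minimum complete pairs (default 10).
#' @return `correlation_table` (id_a, id_b, r, n_pairs, p, q) over unordered
#'   drug pairs.
#' @export
drug_drug_correlations <- function(sdss, min_n = 10) {
  if (nrow(sdss) < 2) stop("need >= 2 drugs")
  cc <- suppressWarnings(stats::cor(t(sdss), use = "pairwise.complete.obs"))
  obs <- !is.na(sdss)
  n <- tcrossprod(obs * 1)
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  tab <- data.frame(id_a = rownames(cc)[ut[, 1]], id_b = colnames(cc)[ut[, 2]],
                    method = "pearson", r = cc[ut], n_pairs = n[ut],
                    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$r) & tab$n_pairs >= min_n, ]
  tab$p <- cor_p_from_t(tab$r, tab$n_pairs)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  class(tab) <- c("correlation_table", "data.frame")
  tab
}

#' Do protein levels correlate with drug response more than mRNA levels?
#'
#' For every (drug, gene) pair with correlations in both layers, the absolute
#' drug-feature correlations are paired, mapped to the Fisher-z scale, and the
#' z differences are tested two-sidedly (paired t by default, Wilcoxon
#' signed-rank optionally).
#'
#' @param sdss [drug_response_matrix()] (effective drugs).
#' @param protein,mrna [omics_matrix()] layers.
#' @param min_n minimum complete pairs per correlation.
#' @param test `"t"` (paired t) or `"wilcoxon"`.
#' @return list `p`, `statistic`, `mean_diff` (mean z(|r_protein|) -
#'   z(|r_mrna|)), `n_pairs`, `direction`.
#' @export
compare_protein_vs_rna_correlation <- function(sdss, protein, mrna,
                                               min_n = 10,
                                               test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  genes <- intersect(rownames(protein), rownames(mrna))
  if (!length(genes)) stop("no shared genes between the layers")
  cp <- drug_feature_correlations(sdss, protein[genes, , drop = FALSE],
                                  min_n = min_n)
  cm <- drug_feature_correlations(sdss, mrna[genes, , drop = FALSE],
                                  min_n = min_n)
  ok <- !is.na(cp$r) & !is.na(cm$r)
  if (!any(ok)) stop("no (drug, gene) pair with correlations in both layers")
  zp <- fisher_z(abs(cp$r[ok]))
  zm <- fisher_z(abs(cm$r[ok]))
  if (stats::sd(zp - zm) < 1e-12) {  # identical layers: exact null
    return(list(p = 1, statistic = 0, mean_diff = mean(zp - zm),
                n_pairs = sum(ok), direction = "none"))
  }
  if (test == "t") {
    tt <- stats::t.test(zp, zm, paired = TRUE)
  } else {
    tt <- stats::wilcox.test(zp, zm, paired = TRUE)
  }
  diff <- mean(zp - zm)
  list(p = tt$p.value, statistic = unname(tt$statistic), mean_diff = diff,
       n_pairs = sum(ok),
       direction = if (diff > 0) "protein_higher" else "mrna_higher")
}

#' Embed drug correlation profiles in 2-D
#'
#' The drugs x features correlation matrix is completed (missing correlations
#' imputed to 0, count logged), feature-standardized (center + unit scale),
#' reduced by PCA to `n_pcs` components, and embedded by UMAP with the
#' configured neighborhood parameters under a fixed seed.
#'
#' @param corr `drug_feature_cor` (or a plain drugs x features r matrix).
#' @param n_pcs principal components kept (default 27; clamped to the matrix
#'   rank with a warning).
#' @param n_neighbors,local_connectivity,spread,min_dist UMAP parameters
#'   (defaults 25, 1, 3.5, 0.05).
#' @param seed RNG seed.
#' @return data.frame drug, dim1, dim2; attributes `n_pcs`, `n_imputed`,
#'   `params`.
#' @export
embed_drug_profiles <- function(corr, n_pcs = 27, n_neighbors = 25,
                                local_connectivity = 1, spread = 3.5,
                                min_dist = 0.05, seed = 42) {
  r <- if (is.list(corr) && !is.data.frame(corr)) corr$r else corr
  n_imputed <- sum(is.na(r))
  if (n_imputed) message(sprintf("imputing %d missing correlations to 0",
                                 n_imputed))
  r[is.na(r)] <- 0
  if (nrow(r) < n_neighbors + 1)
    stop("need at least n_neighbors + 1 retained drugs")
  keep <- apply(r, 2L, stats::sd) > 0
  z <- scale(r[, keep, drop = FALSE])
  max_pcs <- min(nrow(z) - 1L, ncol(z))
  if (n_pcs > max_pcs) {
    warning("n_pcs clamped from ", n_pcs, " to ", max_pcs)
    n_pcs <- max_pcs
  }
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                           drop = FALSE]
  set.seed(seed)
  emb <- uwot::umap(pc, n_neighbors = n_neighbors,
                    local_connectivity = local_connectivity, spread = spread,
                    min_dist = min_dist, metric = "euclidean",
                    init = "spectral", n_threads = 1, n_sgd_threads = 1,
                    seed = seed)
  out <- data.frame(drug = rownames(r), dim1 = emb[, 1], dim2 = emb[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_pcs") <- n_pcs
  attr(out, "n_imputed") <- n_imputed
  attr(out, "params") <- list(n_neighbors = n_neighbors,
                              local_connectivity = local_connectivity,
                              spread = spread, min_dist = min_dist,
                              seed = seed)
  out
}

#' Elbow-based choice of the PC count for the embedding
#' @param r completed drugs x features matrix (NAs as 0).
#' @param drop_frac keep PCs until the variance share falls below
#'   `drop_frac` of the first PC's share (default 0.02).
#' @return integer PC count (>= 2).
#' @export
choose_n_pcs <- function(r, drop_frac = 0.02) {
  r[is.na(r)] <- 0
  keep <- apply(r, 2L, stats::sd) > 0
  pv <- stats::prcomp(scale(r[, keep, drop = FALSE]))$sdev^2
  pv <- pv / sum(pv)
  max(2L, sum(pv >= drop_frac * pv[1]))
}

#' Lineage differential correlation of drug-feature pairs
#'
#' Per (drug, feature) pair and sample group (e.g. B vs T lineage): Pearson r
#' within each group after excluding missing and zero values (the quoted
#' differential-correlation setting), Fisher z difference
#' (z_A - z_B) / sqrt(1/(n_A-3) + 1/(n_B-3)) with analytic two-sided normal p,
#' a group-label permutation p, and a nine-cell class label from per-group
#' correlation significance at `alpha` and sign (+/0/- per group). Pairs are
#' scored only when both groups retain at least `min_group_n` samples; results
#' are ranked by |z difference|.
#'
#' @param sdss [drug_response_matrix()].
#' @param features [omics_matrix()].
#' @param grouping named vector sample -> group (exactly 2 levels used).
#' @param n_perm permutations (default 1000; the study's own setting of 10 is
#'   available but cannot resolve p below 1/11, so the analytic p is always
#'   reported alongside).
#' @param alpha per-group significance level for the class label.
#' @param min_group_n minimum samples per group (default 10; z undefined at
#'   n <= 3).
#' @param exclude_zero drop exact zeros as well as missing values.
#' @param seed RNG seed.
#' @return data.frame of class `diffcor_table`: drug, feature, r_a, n_a, r_b,
#'   n_b, z_a, z_b, z_diff, p_analytic, p_perm, class.
#' @export
differential_correlation <- function(sdss, features, grouping, n_perm = 1000,
                                     alpha = 0.05, min_group_n = 10,
                                     exclude_zero = TRUE, seed = 1) {
  al <- align_samples(sdss, features)
  g <- grouping[al$shared]
  lv <- stats::na.omit(unique(g))
  if (length(lv) < 2) stop("grouping needs two levels on the shared samples")
  lv <- lv[1:2]
  set.seed(seed)
  clean <- function(v) { if (exclude_zero) v[v == 0] <- NA; v }
  A <- al$shared[!is.na(g) & g == lv[1]]
  B <- al$shared[!is.na(g) & g == lv[2]]
  cor_in <- function(d, f, cols) {
    x <- clean(al$a[d, cols]); y <- clean(al$b[f, cols])
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 4) return(c(NA_real_, n))
    c(suppressWarnings(stats::cor(x[ok], y[ok])), n)
  }
  rows <- list()
  for (d in rownames(al$a)) for (f in rownames(al$b)) {
    ra <- cor_in(d, f, A); rb <- cor_in(d, f, B)
    if (is.na(ra[1]) || is.na(rb[1])) next
    if (ra[2] < min_group_n || rb[2] < min_group_n) next
    za <- fisher_z(ra[1]); zb <- fisher_z(rb[1])
    se <- sqrt(1 / (ra[2] - 3) + 1 / (rb[2] - 3))
    zd <- (za - zb) / se
    # permutation: reshuffle the group labels over the union
    pool <- c(A, B)
    exceed <- 0L; nperm_ok <- 0L
    for (pp in seq_len(n_perm)) {
      pa <- sample(pool, length(A))
      pb <- setdiff(pool, pa)
      r1 <- cor_in(d, f, pa); r2 <- cor_in(d, f, pb)
      if (is.na(r1[1]) || is.na(r2[1]) || r1[2] < 4 || r2[2] < 4) next
      zp <- (fisher_z(r1[1]) - fisher_z(r2[1])) /
        sqrt(1 / (r1[2] - 3) + 1 / (r2[2] - 3))
      nperm_ok <- nperm_ok + 1L
      if (abs(zp) >= abs(zd)) exceed <- exceed + 1L
    }
    cls <- paste(cor_sign_class(ra[1], ra[2], alpha),
                 cor_sign_class(rb[1], rb[2], alpha), sep = "/")
    rows[[length(rows) + 1L]] <- data.frame(
      drug = d, feature = f, r_a = ra[1], n_a = ra[2], r_b = rb[1],
      n_b = rb[2], z_a = za, z_b = zb, z_diff = zd,
      p_analytic = 2 * stats::pnorm(-abs(zd)),
      p_perm = if (nperm_ok) (1 + exceed) / (1 + nperm_ok) else NA_real_,
      class = cls, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no (drug, feature) pair scored")
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$z_diff)), ]
  rownames(out) <- NULL
  class(out) <- c("diffcor_table", "data.frame")
  out
}

# internal: "+", "0" or "-" by correlation significance (t transform) and sign
cor_sign_class <- function(r, n, alpha) {
  p <- cor_p_from_t(r, n)
  if (is.na(p) || p > alpha) "0" else if (r > 0) "+" else "-"
}
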