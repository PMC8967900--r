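#' Flag samples with no correlated partner
#'
#' A sample is flagged as an outlier when its best Pearson correlation to any
#' other sample is below `r_min`. Correlations use features quantified in all
#' samples (valid values only) when at least `min_complete` such features
#' exist, falling back to pairwise-complete correlation otherwise.
#'
#' @param matrix [omics_matrix()].
#' @param r_min correlation floor (default 0.5).
#' @param min_complete minimum complete-case features before falling back.
#' @return named logical vector (TRUE = outlier).
#' @export
flag_outlier_samples <- function(matrix, r_min = 0.5, min_complete = 10) {
  if (ncol(matrix) < 2) stop("need >= 2 samples")
  complete <- rowSums(is.na(matrix)) == 0
  cc <- if (sum(complete) >= min_complete)
    stats::cor(matrix[complete, , drop = FALSE])
  else
    suppressWarnings(stats::cor(matrix, use = "pairwise.complete.obs"))
  diag(cc) <- NA
  best <- apply(cc, 2L, max, na.rm = TRUE)
  stats::setNames(best < r_min, colnames(matrix))
}

# internal: 1 - correlation distance between sample columns
cor_dist <- function(x, method = "pearson") {
  cc <- suppressWarnings(stats::cor(x, method = method,
                                    use = "pairwise.complete.obs"))
  cc[is.na(cc)] <- 0
  stats::as.dist(1 - cc)
}

#' Subsampled consensus clustering with CDF delta-area model selection
#'
#' For each of `reps` repetitions, `pItem` of the samples and `pFeature` of
#' the features are subsampled, samples are clustered hierarchically with
#' 1 - correlation distance, and the tree is cut at each k in `k_range`. The
#' consensus matrix entry (i, j) is the co-clustering count divided by the
#' co-sampling count. Model selection follows the consensus CDF: area under
#' the CDF per k and the relative delta area ((A(k) - A(k-1)) / A(k-1), A(2)
#' for the first k); the automated elbow picks the largest k whose relative
#' delta area is at least `delta_frac` (a >= 10 percent relative gain by
#' default). Manual override via the returned table is first-class, mirroring
#' how the elbow is read off a plot.
#'
#' @param matrix [omics_matrix()].
#' @param features feature subset (e.g. the HV set) used for clustering.
#' @param k_range candidate cluster numbers (default 2:6).
#' @param reps subsampling repetitions (default 2000).
#' @param pItem,pFeature subsampling proportions (default 0.8 each).
#' @param distance `"pearson"` or `"spearman"` (1 - correlation).
#' @param linkage hclust linkage (default `"ward.D2"`).
#' @param exclude_outliers drop samples flagged by [flag_outlier_samples()]
#'   (and replicate samples listed in `replicate_of`) before the runs.
#' @param r_min outlier correlation floor, evaluated on all features of
#'   `matrix` (default 0.5; synthetic relative matrices carry less pervasive
#'   cross-sample co-regulation than real panels and may need a lower floor).
#' @param metadata optional [sample_metadata()]; its replicates are excluded
#'   from the consensus runs.
#' @param delta_frac elbow sensitivity (default 0.1).
#' @param seed RNG seed.
#' @return object of class `consensus_result`: `consensus` (list of matrices
#'   by k), `area`, `delta_area`, `chosen_k`, `assignments` (list by k, on the
#'   clustered samples), `outliers`, `samples`.
#' @export
consensus_cluster <- function(matrix, features = rownames(matrix),
                              k_range = 2:6, reps = 2000, pItem = 0.8,
                              pFeature = 0.8,
                              distance = c("pearson", "spearman"),
                              linkage = "ward.D2", exclude_outliers = TRUE,
                              metadata = NULL, delta_frac = 0.1, r_min = 0.5,
                              seed = 7) {
  distance <- match.arg(distance)
  feats <- intersect(features, rownames(matrix))
  if (length(feats) < 10) stop("need >= 10 features for consensus clustering")
  drop <- character(0)
  if (!is.null(metadata))
    drop <- metadata$sample_id[!is.na(metadata$replicate_of)]
  keep_s <- setdiff(colnames(matrix), drop)
  outliers <- flag_outlier_samples(matrix[, keep_s, drop = FALSE],
                                   r_min = r_min)
  x <- matrix[feats, keep_s, drop = FALSE]
  if (exclude_outliers) x <- x[, !outliers, drop = FALSE]
  if (ncol(x) < 3) stop("fewer than 3 non-outlier samples; lower r_min")
  n <- ncol(x); m <- nrow(x)
  if (max(k_range) > n - 1 || min(k_range) < 2)
    stop("k_range outside [2, n_samples - 1]")
  set.seed(seed)
  n_item <- ceiling(pItem * n); n_feat <- ceiling(pFeature * m)
  connect <- lapply(k_range, function(k) base::matrix(0, n, n))
  names(connect) <- as.character(k_range)
  co_sampled <- base::matrix(0, n, n)
  for (r in seq_len(reps)) {
    items <- sort(sample.int(n, n_item))
    feats <- sample.int(m, n_feat)
    ind <- base::matrix(0, n, 1); ind[items] <- 1
    co_sampled <- co_sampled + tcrossprod(ind)
    hc <- stats::hclust(cor_dist(x[feats, items, drop = FALSE], distance),
                        method = linkage)
    cuts <- stats::cutree(hc, k = k_range)
    if (is.null(dim(cuts))) cuts <- base::matrix(cuts, ncol = 1)
    for (ki in seq_along(k_range)) {
      lab <- cuts[, ki]
      memb <- outer(lab, lab, "==") * 1
      connect[[ki]][items, items] <- connect[[ki]][items, items] + memb
    }
  }
  consensus <- lapply(connect, function(cm) {
    out <- cm / pmax(co_sampled, 1)
    out[co_sampled == 0] <- 0
    dimnames(out) <- list(colnames(x), colnames(x))
    out
  })
  # CDF area over the upper triangle, 100 bins
  breaks <- seq(0, 1, length.out = 101)
  area <- vapply(consensus, function(cm) {
    v <- cm[upper.tri(cm)]
    cdf <- stats::ecdf(v)(breaks[-1])
    sum(cdf) * 0.01
  }, numeric(1))
  delta <- c(area[1], diff(area) / area[-length(area)])
  names(delta) <- names(area)
  eligible <- k_range[delta >= delta_frac - 1e-12]
  chosen_k <- if (length(eligible)) max(eligible) else k_range[1]
  assignments <- lapply(seq_along(k_range), function(ki) {
    cm <- consensus[[ki]]
    hc <- stats::hclust(stats::as.dist(1 - cm), method = linkage)
    stats::setNames(stats::cutree(hc, k = k_range[ki]), colnames(x))
  })
  names(assignments) <- as.character(k_range)
  res <- list(consensus = consensus, area = area, delta_area = delta,
              chosen_k = chosen_k, assignments = assignments,
              outliers = outliers, samples = colnames(x),
              k_range = k_range, params = list(reps = reps, pItem = pItem,
                                               pFeature = pFeature,
                                               distance = distance,
                                               linkage = linkage, seed = seed))
  class(res) <- "consensus_result"
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k in {%s}, chosen k = %d\n",
              paste(x$k_range, collapse = ","), x$chosen_k))
  cat("  area:", sprintf("%.3f", x$area), "\n")
  cat("  delta:", sprintf("%.3f", x$delta_area), "\n")
  invisible(x)
}

#' Final cluster assignment with replicate propagation and bootstrap support
#'
#' Hierarchical clustering (1 - Pearson, ward.D2) on all features and all
#' samples except replicates, cut at `chosen_k`; replicate samples inherit
#' their parent's cluster. Cluster support is the proportion of `B` feature
#' bootstraps in which the exact member set of each cluster recurs (a plain
#' bootstrap-recurrence simplification of multiscale bootstrap probabilities).
#'
#' @param matrix [omics_matrix()] (all features; outliers included).
#' @param chosen_k number of clusters.
#' @param metadata [sample_metadata()] (for replicate propagation).
#' @param B bootstrap replicates (default 500).
#' @param linkage,distance as in [consensus_cluster()].
#' @param seed RNG seed.
#' @return list of class `cluster_assignment`: `cluster` (named vector over
#'   all samples incl. replicates), `support` (per cluster), `k`.
#' @export
finalize_clusters <- function(matrix, chosen_k, metadata = NULL, B = 500,
                              linkage = "ward.D2", distance = "pearson",
                              seed = 7) {
  reps <- character(0)
  parent <- NULL
  if (!is.null(metadata)) {
    has_rep <- !is.na(metadata$replicate_of)
    reps <- intersect(metadata$sample_id[has_rep], colnames(matrix))
    parent <- stats::setNames(metadata$replicate_of[has_rep],
                              metadata$sample_id[has_rep])
  }
  x <- matrix[, setdiff(colnames(matrix), reps), drop = FALSE]
  if (chosen_k > ncol(x)) stop("chosen_k exceeds sample count")
  hc <- stats::hclust(cor_dist(x, distance), method = linkage)
  cl <- stats::cutree(hc, k = chosen_k)
  names(cl) <- colnames(x)
  set.seed(seed)
  member_sets <- split(names(cl), cl)
  hits <- stats::setNames(numeric(length(member_sets)), names(member_sets))
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(x), replace = TRUE)
    hb <- stats::hclust(cor_dist(x[idx, , drop = FALSE], distance),
                        method = linkage)
    cb <- stats::cutree(hb, k = chosen_k)
    sets_b <- split(colnames(x), cb)
    for (j in seq_along(member_sets)) {
      if (any(vapply(sets_b, function(s) setequal(s, member_sets[[j]]),
                     logical(1))))
        hits[j] <- hits[j] + 1
    }
  }
  cluster <- cl
  if (length(reps)) {
    inherited <- cl[parent[reps]]
    names(inherited) <- reps
    cluster <- c(cluster, inherited)
  }
  res <- list(cluster = cluster, support = hits / B, k = chosen_k)
  class(res) <- "cluster_assignment"
  res
}
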