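#' Weighted Kolmogorov-Smirnov enrichment score of one set
#'
#' Streaming running-sum over the ranked list: hits advance by
#' |score|^weight / sum(|score_hits|^weight), misses by 1 / (N - |S|); the ES
#' is the running-sum value of largest magnitude.
#'
#' @param scores named numeric vector, sorted in decreasing order.
#' @param set member ids.
#' @param weight exponent on |score| (default 1; 0 gives the classic KS).
#' @return list `es`, `peak` (position), `leading_edge` (hit ids contributing
#'   up to the peak for positive ES, from the peak for negative).
#' @export
gsea_enrichment_score <- function(scores, set, weight = 1) {
  ids <- names(scores)
  hit <- ids %in% set
  n_hit <- sum(hit)
  if (n_hit == 0 || n_hit == length(ids))
    stop("set must hit a strict subset of the ranking")
  w <- abs(scores)^weight
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (length(ids) - n_hit))
  run <- cumsum(inc)
  peak <- which.max(abs(run))
  es <- run[peak]
  le <- if (es >= 0) ids[seq_len(peak)][hit[seq_len(peak)]]
  else ids[peak:length(ids)][hit[peak:length(ids)]]
  list(es = unname(es), peak = unname(peak), leading_edge = le)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted-KS enrichment scores with gene-label permutation null: each
#' permutation rescores a random set of the same size, NES is the ES divided
#' by the mean of same-sign permutation ESs, the permutation p is the
#' same-sign exceedance fraction, and BH q is computed within each sign class.
#' Sets outside [min_size, max_size] after intersecting the ranking are
#' excluded.
#'
#' @param ranking named score vector (unique ids); will be sorted decreasing.
#' @param sets named list of member vectors (e.g. from [read_gmt()]).
#' @param weight KS weight (default 1).
#' @param min_size,max_size eligible set sizes (defaults 15 and 500).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return data.frame of class `gsea_result`: set, size, es, nes, p, q,
#'   leading_edge (list-column).
#' @export
preranked_gsea <- function(ranking, sets, weight = 1, min_size = 15,
                           max_size = 500, n_perm = 1000, seed = 1) {
  if (anyDuplicated(names(ranking))) stop("ranking ids must be unique")
  scores <- sort(ranking, decreasing = TRUE)
  sizes <- vapply(sets, function(s) length(intersect(s, names(scores))),
                  integer(1))
  eligible <- sizes >= min_size & sizes <= max_size
  if (!any(eligible)) stop("no eligible gene set in [min_size, max_size]")
  sets <- sets[eligible]; sizes <- sizes[eligible]
  obs <- lapply(sets, function(s) gsea_enrichment_score(scores, s, weight))
  es <- vapply(obs, `[[`, numeric(1), "es")
  set.seed(seed)
  uniq_sizes <- sort(unique(sizes))
  ids <- names(scores)
  # permutation ES per set size (shared across sets of the same size)
  perm_by_size <- lapply(uniq_sizes, function(sz) {
    vapply(seq_len(n_perm), function(p)
      gsea_enrichment_score(scores, sample(ids, sz), weight)$es, numeric(1))
  })
  names(perm_by_size) <- as.character(uniq_sizes)
  nes <- p <- rep(NA_real_, length(sets))
  for (i in seq_along(sets)) {
    pe <- perm_by_size[[as.character(sizes[i])]]
    same <- pe[sign(pe) == sign(es[i])]
    if (length(same)) {
      nes[i] <- es[i] / mean(abs(same))
      p[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    } else {
      nes[i] <- NA_real_
      p[i] <- 1 / (1 + n_perm)
    }
  }
  q <- rep(NA_real_, length(sets))
  pos <- !is.na(nes) & nes >= 0
  q[pos] <- stats::p.adjust(p[pos], method = "BH")
  q[!pos] <- stats::p.adjust(p[!pos], method = "BH")
  out <- data.frame(set = names(sets), size = sizes, es = es, nes = nes,
                    p = p, q = q, stringsAsFactors = FALSE, row.names = NULL)
  out$leading_edge <- lapply(obs, `[[`, "leading_edge")
  class(out) <- c("gsea_result", "data.frame")
  out
}
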