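#' Filter a matched cohort for stability scoring
#'
#' Step 1 of the protein-mRNA deviation procedure: replicate cell lines are
#' collapsed first, then genes are kept when their transcript exceeds 1 TPM
#' (by default: median log2 TPM across samples > log2(1) = 0; `tpm_scope`
#' switches to per-sample/any-sample variants) and their protein is
#' non-missing in at least half of the samples.
#'
#' @param protein,mrna [omics_matrix()] layers.
#' @param metadata [sample_metadata()]; replicates are median-collapsed.
#' @param tpm_threshold TPM cut (linear scale, default 1).
#' @param tpm_scope `"median"` (default), `"all"` (every sample above) or
#'   `"any"` (at least one sample above).
#' @param min_protein_frac minimum fraction of samples with protein quantified.
#' @return list `protein`, `mrna` (aligned, filtered), `kept`, `n_dropped`.
#' @export
stability_filter <- function(protein, mrna, metadata,
                             tpm_threshold = 1,
                             tpm_scope = c("median", "all", "any"),
                             min_protein_frac = 0.5) {
  tpm_scope <- match.arg(tpm_scope)
  protein <- collapse_replicates(protein, metadata)
  mrna <- collapse_replicates(mrna, metadata)
  al <- align_samples(protein, mrna)
  shared <- intersect(rownames(al$a), rownames(al$b))
  P <- al$a[shared, , drop = FALSE]
  M <- al$b[shared, , drop = FALSE]
  cut <- log2(tpm_threshold)
  tpm_ok <- switch(tpm_scope,
    median = apply(M, 1L, stats::median, na.rm = TRUE) > cut,
    all = apply(M, 1L, function(v) all(v > cut, na.rm = TRUE)),
    any = apply(M, 1L, function(v) any(v > cut, na.rm = TRUE)))
  prot_ok <- rowMeans(!is.na(P)) >= min_protein_frac
  keep <- tpm_ok & prot_ok
  if (!any(keep)) stop("no gene passes the stability filters")
  message(sprintf("stability filter: kept %d / %d genes (TPM rule dropped %d, protein missingness dropped %d)",
                  sum(keep), length(keep), sum(!tpm_ok), sum(tpm_ok & !prot_ok)))
  list(protein = P[keep, , drop = FALSE], mrna = M[keep, , drop = FALSE],
       kept = shared[keep], n_dropped = sum(!keep))
}

#' Per-gene, per-sample protein-mRNA stability scores
#'
#' For each gene, protein log2 ratios are regressed on mRNA log2 TPM across
#' samples with a loess smooth (the smooth absorbs lineage-driven transcript
#' differences), residuals are standardized by the gene's residual SD, and
#' samples with |z| > `z_cut` are flagged as decoupled. The residual SD uses
#' the loess equivalent number of parameters (RSS / (n - enp)) so it is an
#' approximately unbiased noise estimate.
#'
#' @param pair list with `protein` and `mrna` from [stability_filter()] (any
#'   pair of aligned matrices with common rownames works).
#' @param loess_span loess span (default 0.75, local quadratic).
#' @param loess_degree polynomial degree (default 2).
#' @param z_cut flag threshold on |standardized residual| (default 3).
#' @param min_samples genes with fewer complete sample pairs are skipped.
#' @return data.frame of class `stability_table`: gene, sample, mrna, protein,
#'   fitted, residual, z, significant; attribute `skipped` lists genes whose
#'   loess fit failed.
#' @export
compute_stability_scores <- function(pair, loess_span = 0.75,
                                     loess_degree = 2, z_cut = 3,
                                     min_samples = 8) {
  P <- pair$protein; M <- pair$mrna
  stopifnot(identical(rownames(P), rownames(M)),
            identical(colnames(P), colnames(M)))
  out <- vector("list", nrow(P))
  skipped <- character(0)
  for (i in seq_len(nrow(P))) {
    ok <- !is.na(P[i, ]) & !is.na(M[i, ])
    if (sum(ok) < min_samples) { skipped <- c(skipped, rownames(P)[i]); next }
    x <- M[i, ok]; y <- P[i, ok]
    fit <- tryCatch(
      stats::loess(y ~ x, span = loess_span, degree = loess_degree,
                   family = "gaussian"),
      error = function(e) NULL)
    if (is.null(fit)) { skipped <- c(skipped, rownames(P)[i]); next }
    res <- stats::residuals(fit)
    df_resid <- max(length(res) - fit$enp, 1)
    s <- sqrt(sum(res^2) / df_resid)
    if (!is.finite(s) || s < 1e-8 * (stats::sd(y) + 1e-8)) {
      z <- rep(0, length(res))  # numerically perfect fit
    } else z <- res / s
    out[[i]] <- data.frame(gene = rownames(P)[i], sample = colnames(P)[ok],
                           mrna = x, protein = y, fitted = stats::fitted(fit),
                           residual = res, z = z,
                           significant = abs(z) > z_cut,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(tab)) stop("no gene could be scored")
  attr(tab, "skipped") <- skipped
  attr(tab, "z_cut") <- z_cut
  class(tab) <- c("stability_table", "data.frame")
  tab
}

#' Mean stability score of a complex in one sample
#'
#' Arithmetic mean of the member genes' standardized residuals in the given
#' sample; requires at least two scored members.
#'
#' @param table `stability_table`.
#' @param catalog `complex_catalog`.
#' @param complex_id complex to aggregate.
#' @param sample sample id.
#' @return list `mean_z`, `n_members`; `mean_z` is `NA` (with a warning) when
#'   fewer than 2 members are scored.
#' @export
complex_sample_deviation <- function(table, catalog, complex_id, sample) {
  members <- catalog$members[[match(complex_id, catalog$complex_id)]]
  if (is.null(members)) stop("unknown complex: ", complex_id)
  z <- table$z[table$gene %in% members & table$sample == sample]
  if (length(z) < 2) {
    warning("fewer than 2 scored members for ", complex_id, " in ", sample)
    return(list(mean_z = NA_real_, n_members = length(z)))
  }
  list(mean_z = mean(z), n_members = length(z))
}
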