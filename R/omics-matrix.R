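#' Omics abundance matrix
#'
#' A validated numeric matrix of features (gene symbols) by samples with a
#' `kind` tag. Protein matrices hold relative log2 ratios and may contain
#' missing values; mRNA matrices hold log2 TPM and are expected complete.
#'
#' @param values numeric matrix, rows = features, columns = samples, with
#'   unique dimnames. `NA` allowed.
#' @param kind one of `"protein_log2ratio"`, `"mrna_log2tpm"`.
#' @return a numeric matrix of class `omics_matrix` carrying a `kind`
#'   attribute.
#' @export
omics_matrix <- function(values, kind = c("protein_log2ratio", "mrna_log2tpm")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate feature identifiers: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample identifiers: ", paste(unique(dup), collapse = ", "))
  structure(values, kind = kind, class = c("omics_matrix", class(values)))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix kind=%s> %d features x %d samples, %.1f%% missing\n",
              attr(x, "kind"), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @rdname omics_matrix
#' @export
omics_kind <- function(values) attr(values, "kind")

#' Drug response (sDSS) matrix
#'
#' Drugs by cell lines matrix of selective drug sensitivity scores; sDSS is a
#' dose-response-derived sensitivity metric normalized against healthy bone
#' marrow, so higher means more selectively potent. Missing entries allowed.
#'
#' @param values numeric matrix, rows = drugs, columns = cell lines/samples.
#' @return matrix of class `drug_response_matrix`.
#' @export
drug_response_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have drug rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate drug identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  bad <- is.infinite(values)
  if (any(bad)) stop("non-finite (infinite) sDSS entries")
  structure(values, class = c("drug_response_matrix", class(values)))
}

#' Sample metadata table
#'
#' @param sample_id character vector of unique sample labels.
#' @param lineage factor/character in `{B, T, other}`.
#' @param subtype free-text cytogenetic subtype.
#' @param replicate_of optional parent sample id (`NA` for primary samples).
#'   Parents must exist and must themselves be primary (no replicate chains).
#' @return data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, lineage, subtype = NA_character_,
                            replicate_of = NA_character_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in metadata")
  lineage <- as.character(lineage)
  if (!all(lineage %in% c("B", "T", "other")))
    stop("lineage must be one of B, T, other")
  md <- data.frame(sample_id = sample_id, lineage = lineage,
                   subtype = rep_len(as.character(subtype), length(sample_id)),
                   replicate_of = rep_len(as.character(replicate_of),
                                          length(sample_id)),
                   stringsAsFactors = FALSE)
  has_parent <- !is.na(md$replicate_of) & md$replicate_of != ""
  md$replicate_of[!has_parent] <- NA_character_
  missing_parent <- setdiff(md$replicate_of[has_parent], md$sample_id)
  if (length(missing_parent))
    stop("replicate_of points to unknown sample(s): ",
         paste(missing_parent, collapse = ", "))
  parents <- md$replicate_of[has_parent]
  chained <- parents[!is.na(md$replicate_of[match(parents, md$sample_id)])]
  if (length(chained))
    stop("replicate chains not allowed (parent has replicate_of): ",
         paste(unique(chained), collapse = ", "))
  class(md) <- c("sample_metadata", "data.frame")
  md
}
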