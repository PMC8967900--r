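#' Read a features-by-samples TSV matrix
#'
#' Dialect: tab-separated, header row of sample IDs, first column the feature
#' (gene or drug) identifier; missing values written as "NA" (empty cells also
#' accepted on read). Gene symbols are uppercased and whitespace-stripped so
#' joins across layers are deterministic.
#'
#' @param path TSV file path.
#' @param kind passed to [omics_matrix()]; use `kind = NULL` for a raw matrix
#'   (e.g. sDSS, PSM counts).
#' @param normalize_ids uppercase/trim row identifiers (default TRUE).
#' @return `omics_matrix` (or plain named matrix when `kind` is NULL).
#' @export
read_matrix_tsv <- function(path, kind = "protein_log2ratio",
                            normalize_ids = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("matrix TSV needs an id column plus >= 1 sample: ", path)
  ids <- df[[1]]
  if (normalize_ids) ids <- toupper(trimws(ids))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature identifiers in ", basename(path), ": ",
         paste(dup, collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                 basename(path), ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(ids, colnames(vals))
  if (is.null(kind)) num else omics_matrix(num, kind)
}

#' Write a matrix in the package TSV dialect (round-trips with
#' [read_matrix_tsv()], missing cells written as "NA").
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @param id_col header for the identifier column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read sample metadata TSV (sample_id, lineage, subtype, replicate_of)
#' @param path TSV path.
#' @return [sample_metadata()] data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  need <- c("sample_id", "lineage")
  if (!all(need %in% colnames(df)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  sample_metadata(df$sample_id, df$lineage,
                  subtype = if ("subtype" %in% colnames(df)) df$subtype else NA,
                  replicate_of = if ("replicate_of" %in% colnames(df))
                    df$replicate_of else NA)
}

#' Load a matched protein + mRNA cohort
#'
#' Reads both layers and the sample metadata, validates the container
#' invariants and emits a summary (feature counts, per-layer sample counts,
#' number of features quantified in every sample).
#'
#' @param protein_path,mrna_path,metadata_path TSV paths.
#' @return list with `protein`, `mrna`, `metadata`, `summary`.
#' @export
load_cohort <- function(protein_path, mrna_path, metadata_path) {
  protein <- read_matrix_tsv(protein_path, kind = "protein_log2ratio")
  mrna <- read_matrix_tsv(mrna_path, kind = "mrna_log2tpm")
  metadata <- read_sample_metadata(metadata_path)
  unknown <- setdiff(colnames(protein), metadata$sample_id)
  if (length(unknown))
    warning("protein samples absent from metadata: ",
            paste(unknown, collapse = ", "))
  summary <- list(
    n_protein_features = nrow(protein),
    n_mrna_features = nrow(mrna),
    n_protein_samples = ncol(protein),
    n_mrna_samples = ncol(mrna),
    n_complete_protein = sum(stats::complete.cases(protein)),
    n_shared_features = length(intersect(rownames(protein), rownames(mrna))))
  message(sprintf(
    "cohort: %d proteins (%d complete-case) x %d samples; %d transcripts x %d samples; %d shared genes",
    summary$n_protein_features, summary$n_complete_protein,
    summary$n_protein_samples, summary$n_mrna_features,
    summary$n_mrna_samples, summary$n_shared_features))
  list(protein = protein, mrna = mrna, metadata = metadata, summary = summary)
}

#' Collapse replicate samples to their parent by protein-wise median
#'
#' Each replicate group (parent plus its `replicate_of` children) becomes a
#' single column named by the parent, holding the per-feature median over the
#' group with missing values ignored. Samples without replicates pass through
#' untouched. A group that is entirely missing for a feature yields a missing
#' value (with a warning the first time).
#'
#' @param matrix an [omics_matrix()] (or plain matrix with dimnames).
#' @param metadata [sample_metadata()].
#' @param mode only `"median"` is offered (the stated combination rule).
#' @return matrix of the same class with replicate columns merged.
#' @export
collapse_replicates <- function(matrix, metadata, mode = c("median")) {
  mode <- match.arg(mode)
  kind <- attr(matrix, "kind")
  md <- metadata[metadata$sample_id %in% colnames(matrix), , drop = FALSE]
  parent <- ifelse(is.na(md$replicate_of), md$sample_id, md$replicate_of)
  names(parent) <- md$sample_id
  miss <- setdiff(colnames(matrix), md$sample_id)
  if (length(miss))
    parent[miss] <- miss  # samples not in metadata kept as-is
  grp <- parent[colnames(matrix)]
  out_ids <- unique(unname(grp))
  out <- base::matrix(NA_real_, nrow(matrix), length(out_ids),
                      dimnames = list(rownames(matrix), out_ids))
  warned <- FALSE
  for (id in out_ids) {
    cols <- which(grp == id)
    if (length(cols) == 1L) {
      out[, id] <- matrix[, cols]
    } else {
      sub <- matrix[, cols, drop = FALSE]
      out[, id] <- apply(sub, 1L, function(v)
        if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
      if (!warned && anyNA(out[, id])) {
        warning("replicate group '", id,
                "' entirely missing for some features; output left missing")
        warned <- TRUE
      }
    }
  }
  if (!is.null(kind)) omics_matrix(out, kind) else out
}

#' Align two matrices on their shared samples
#'
#' Columns of both objects are reordered to the sorted intersection of their
#' sample IDs.
#'
#' @param a,b matrices with sample columns ([omics_matrix()] or
#'   [drug_response_matrix()]).
#' @return list `a`, `b` (columns matched), `shared` (sorted sample ids).
#' @export
align_samples <- function(a, b) {
  shared <- sort(intersect(colnames(a), colnames(b)))
  if (!length(shared)) stop("no shared samples between the two matrices")
  message(sprintf("aligned on %d shared samples", length(shared)))
  list(a = a[, shared, drop = FALSE], b = b[, shared, drop = FALSE],
       shared = shared)
}

#' Read a GMT gene-set file
#' @param path GMT path (set name, description, then member symbols).
#' @return named list of character vectors (uppercased symbols), with a
#'   `description` attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    members <- toupper(trimws(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, " has no members")
    s <- members
    attr(s, "description") <- f[2]
    sets[[f[1]]] <- s
  }
  sets
}

#' Read a protein-complex catalog TSV
#'
#' Columns: complex_id, complex name, members (';'-separated gene symbols) —
#' the layout used for curated complex catalogs such as CORUM exports.
#'
#' @param path TSV path.
#' @return data.frame `complex_id`, `name`, plus a `members` list-column of
#'   uppercased symbols; class `complex_catalog`.
#' @export
read_complex_catalog <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("complex catalog needs 3 columns (id, name, members)")
  colnames(df)[1:3] <- c("complex_id", "name", "members")
  complex_catalog(df$complex_id, df$name,
                  strsplit(as.character(df$members), ";", fixed = TRUE))
}

#' Construct a complex catalog in memory
#' @param complex_id,name vectors; `members` list of symbol vectors (>= 1 each).
#' @return `complex_catalog` data.frame.
#' @export
complex_catalog <- function(complex_id, name, members) {
  members <- lapply(members, function(m) {
    m <- toupper(trimws(m)); m[nzchar(m)]
  })
  if (any(lengths(members) < 1)) stop("every complex needs >= 1 member")
  out <- data.frame(complex_id = as.character(complex_id),
                    name = as.character(name), stringsAsFactors = FALSE)
  out$members <- members
  class(out) <- c("complex_catalog", "data.frame")
  out
}

#' Read drug annotations TSV (drug_id, class, targets ';'-joined, mechanism)
#' @param path TSV path.
#' @return data.frame with `drug_id`, `class`, `mechanism` and a `targets`
#'   list-column (possibly empty per drug).
#' @export
read_drug_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (!"drug_id" %in% colnames(df)) colnames(df)[1] <- "drug_id"
  if (anyDuplicated(df$drug_id)) stop("duplicate drug_id in annotations")
  tg <- if ("targets" %in% colnames(df)) df$targets else rep(NA, nrow(df))
  df$targets <- lapply(tg, function(t) {
    if (is.na(t) || !nzchar(trimws(t))) character(0)
    else toupper(trimws(strsplit(t, ";", fixed = TRUE)[[1]]))
  })
  df
}

#' Load all annotation resources
#' @param gmt_path,complex_path,drug_annotation_path file paths.
#' @return list `gene_sets`, `complexes`, `drugs`.
#' @export
load_annotations <- function(gmt_path, complex_path, drug_annotation_path) {
  gs <- read_gmt(gmt_path)
  cc <- read_complex_catalog(complex_path)
  da <- read_drug_annotations(drug_annotation_path)
  message(sprintf("annotations: %d gene sets, %d complexes, %d drugs",
                  length(gs), nrow(cc), nrow(da)))
  list(gene_sets = gs, complexes = cc, drugs = da)
}
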