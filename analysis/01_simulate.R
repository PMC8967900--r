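#!/usr/bin/env Rscript
# Generate the synthetic multi-omics cohort that the downstream analyses run
# on: matched protein / mRNA layers for 64 cell lines (+4 protein replicates),
# per-gene PSM counts over 8 TMT sets, and a 40-drug sDSS screen over 43
# lines. All ground truth (sample groups, HV genes, complexes, the planted
# 4-member decoupling event, drug-target map) is saved alongside.

library(drugproteo)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 7)
cohort <- simulate_cohort(cfg)
psm <- simulate_psm_counts(cohort$protein, seed = 23)
drugs <- simulate_drug_response(cohort$protein, cohort$truth,
                                drug_config(seed = 11))

write_matrix_tsv(cohort$protein, file.path(out, "protein.tsv"))
write_matrix_tsv(cohort$mrna, file.path(out, "mrna.tsv"))
write_matrix_tsv(psm, file.path(out, "psm.tsv"))
write_matrix_tsv(drugs$sdss, file.path(out, "sdss.tsv"), id_col = "drug")
write.table(as.data.frame(cohort$metadata), file.path(out, "metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
cc <- cohort$truth$complexes
write.table(data.frame(complex_id = cc$complex_id, name = cc$name,
                       members = vapply(cc$members, paste,
                                        collapse = ";", "")),
            file.path(out, "complexes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
ann <- drugs$annotations
write.table(data.frame(drug_id = ann$drug_id, class = ann$class,
                       targets = vapply(ann$targets, paste,
                                        collapse = ";", "")),
            file.path(out, "drug_annotations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
truth <- cohort$truth
saveRDS <- NULL  # truth goes to JSON, not binary
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(
    list(group = as.list(truth$group), lineage = as.list(truth$lineage),
         hv_genes = truth$hv_genes, decoupling = truth$decoupling,
         drug_truth = drugs$drug_truth, drug_lines = drugs$lines),
    file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
}

cat(sprintf("cohort: %d genes x %d protein samples (%.1f%% missing), %d HV genes, %d complexes\n",
            nrow(cohort$protein), ncol(cohort$protein),
            100 * mean(is.na(cohort$protein)), length(truth$hv_genes),
            nrow(truth$complexes)))
cat(sprintf("drug screen: %d drugs x %d lines; planted decoupling: %d genes in %s\n",
            nrow(drugs$sdss), ncol(drugs$sdss), nrow(truth$decoupling),
            truth$decoupling$sample[1]))
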