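#!/usr/bin/env Rscript
# PSM-moderated differential abundance between two planted sample groups
# (remaining samples as a combined "other" stratum) and preranked weighted-KS
# GSEA of the mRNA-protein correlation ranking against complex-derived sets.

library(drugproteo)

protein <- read_matrix_tsv("results/cohort/protein.tsv")
psm <- read_matrix_tsv("results/cohort/psm.tsv", kind = NULL)
complexes <- read_complex_catalog("results/cohort/complexes.tsv")
truth <- jsonlite::fromJSON("results/cohort/truth.json")

grp_raw <- unlist(truth$group)
groups <- setNames(ifelse(grp_raw == 1, "G1",
                          ifelse(grp_raw == 2, "G2", "other")),
                   names(grp_raw))
mp <- min_psm_per_protein(psm)
de <- moderated_ttest(protein, groups, contrast = c("G1", "G2"),
                      psm_min = mp)
write.table(as.data.frame(de), "results/differential_abundance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
hv <- unlist(truth$hv_genes)
cat(sprintf("G1 vs G2: %d/%d proteins significant (q <= 0.01, |log2FC| >= log2(1.5)); %d of them are planted HV genes\n",
            sum(de$significant), nrow(de),
            sum(de$gene[de$significant] %in% hv)))

# rank by correlation and test complex-membership sets plus HV set
ct <- paired_feature_correlation(
  protein, read_matrix_tsv("results/cohort/mrna.tsv", kind = "mrna_log2tpm"))
rk <- rank_genes(ct)
sets <- c(setNames(complexes$members, complexes$complex_id),
          list(HV_GENES = hv))
gs <- preranked_gsea(rk, sets, min_size = 4, max_size = 500, n_perm = 1000,
                     seed = 7)
gs_out <- gs[order(gs$p), setdiff(colnames(gs), "leading_edge")]
write.table(gs_out, "results/gsea_correlation_ranking.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("top enriched sets in the correlation ranking:\n")
print(utils::head(gs_out, 5), row.names = FALSE)
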