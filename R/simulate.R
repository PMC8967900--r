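#' Simulation configuration for the synthetic cohort
#'
#' Defaults emulate the statistical structure of a childhood-ALL cell-line
#' panel: a gene-wise mRNA-protein Spearman correlation distribution with
#' median ~0.55, a bimodal protein cross-sample SD (unmodulated vs highly
#' variable at 3x), within-complex protein co-regulation exceeding transcript
#' co-regulation, lineage/subtype sample blocks, TMT-style random missingness,
#' and a planted per-sample protein-mRNA decoupling event in one complex.
#'
#' @param n_genes,n_samples cohort dimensions (genes x primary samples).
#' @param n_groups number of sample blocks; `group_lineage` assigns each block
#'   a lineage label (recycled).
#' @param n_hv_genes number of highly variable genes; their mRNA gets
#'   group-specific offsets and their protein SD is `hv_sd_multiplier` x base.
#' @param base_protein_sd cross-sample SD of an unmodulated protein (log2);
#'   `protein_sd_jitter` is the lognormal spread of per-gene SDs.
#' @param rho_median,rho_spread target per-gene mRNA-protein Spearman
#'   distribution N(median, spread) truncated to `rho_range`.
#' @param mrna_mu_mean,mrna_mu_sd,mrna_sd log2 TPM gene means and within-group
#'   noise SD; `mrna_group_sd` the SD of HV-gene group offsets.
#' @param n_complexes,complex_size protein complexes (disjoint random gene
#'   sets). `complex_latent_sd` is the SD of the shared protein-level factor
#'   inside each gene's unit-variance noise (so the within-complex noise
#'   correlation is `complex_latent_sd^2`); `transcript_latent_sd` the same on
#'   the mRNA layer (default 0: complexes co-regulate only post-transcription).
#' @param decoupling data.frame(gene, sample, shift) of planted protein-only
#'   shifts; `NULL` uses the default event (4 members of the first complex
#'   shifted -2 log2 units in the first sample); `NA` plants none. Decoupled
#'   genes get Spearman target `decoupling_rho` (default 0.86, i.e. residual
#'   SD ~0.4 so the planted complex's expected mean standardized residual is
#'   about -5, the magnitude reported for the archetypal case): per-sample
#'   decoupling is only resolvable for tightly coupled genes.
#' @param n_replicates protein-layer replicate columns (parent + N(0,
#'   `replicate_sd`^2)).
#' @param missing_rate MCAR missingness on the protein layer.
#' @param seed master seed.
#' @return config list.
#' @export
sim_config <- function(n_genes = 3000, n_samples = 64, n_groups = 4,
                       group_lineage = c("B", "B", "T", "T"),
                       n_hv_genes = 300, hv_sd_multiplier = 3,
                       base_protein_sd = 0.82, protein_sd_jitter = 0.08,
                       rho_median = 0.55, rho_spread = 0.12,
                       rho_range = c(0.05, 0.92),
                       mrna_mu_mean = 4, mrna_mu_sd = 2, mrna_sd = 0.5,
                       mrna_group_sd = 1,
                       n_complexes = 40, complex_size = 5,
                       complex_latent_sd = 0.7, transcript_latent_sd = 0,
                       decoupling = NULL, decoupling_rho = 0.86,
                       n_replicates = 4, replicate_sd = 0.1,
                       missing_rate = 0.05, seed = 7) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_hv_genes <= cfg$n_genes,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  if (abs(cfg$rho_median) >= 1) stop("infeasible correlation target")
  if (cfg$n_complexes * cfg$complex_size > cfg$n_genes)
    stop("complexes exceed gene count")
  cfg
}

#' Simulate a matched protein/mRNA cohort with known ground truth
#'
#' Per gene g with Spearman target rho_g, lambda_g = 2*sin(pi*rho_g/6) (the
#' Gaussian-copula Pearson equivalent) and
#'   protein_g = sigma_g * (lambda_g * std(mRNA_g) + sqrt(1-lambda_g^2) * u_g)
#' with u_g unit-variance noise that, for complex members, contains a shared
#' per-complex latent factor. sigma_g is bimodal (base vs 3x for HV genes), so
#' the realized Pearson is lambda_g in expectation regardless of sigma, and the
#' trimmed-SD distribution used for HVF selection is two-component by
#' construction. HV genes additionally carry group-specific mRNA offsets so
#' sample blocks are recoverable by clustering. Decoupling events are additive
#' protein-only shifts. Missingness is MCAR.
#'
#' @param config from [sim_config()].
#' @return list `protein`, `mrna` ([omics_matrix()]), `metadata`
#'   ([sample_metadata()]), `truth` (groups, HV set, per-gene targets and noise
#'   SDs, complex catalog, decoupling events).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  G <- cfg$n_genes; S <- cfg$n_samples
  genes <- sprintf("G%04d", seq_len(G))
  samples <- sprintf("S%02d", seq_len(S))
  group <- sort(rep_len(seq_len(cfg$n_groups), S))
  lineage <- rep_len(cfg$group_lineage, cfg$n_groups)[group]
  names(group) <- names(lineage) <- samples

  # complexes: disjoint random gene sets
  cx_genes <- base::matrix(sample(genes, cfg$n_complexes * cfg$complex_size),
                           nrow = cfg$n_complexes)
  complexes <- complex_catalog(
    sprintf("CPX%02d", seq_len(cfg$n_complexes)),
    sprintf("complex %d", seq_len(cfg$n_complexes)),
    split(cx_genes, row(cx_genes)))
  complex_of <- rep(NA_integer_, G); names(complex_of) <- genes
  for (i in seq_len(cfg$n_complexes)) complex_of[cx_genes[i, ]] <- i

  # planted decoupling event (GINS-style): 4 members of complex 1, sample 1
  if (is.null(cfg$decoupling)) {
    dec <- data.frame(gene = cx_genes[1, seq_len(min(4, cfg$complex_size))],
                      sample = samples[1], shift = -2,
                      stringsAsFactors = FALSE)
  } else if (length(cfg$decoupling) == 1 && is.na(cfg$decoupling)) {
    dec <- data.frame(gene = character(), sample = character(),
                      shift = numeric())
  } else dec <- cfg$decoupling
  if (nrow(dec) && !all(dec$gene %in% genes)) stop("unknown decoupling gene")
  if (is.null(cfg$decoupling) && nrow(dec)) {
    # the decoupled complex mirrors its 4-member archetype exactly
    dropped <- setdiff(cx_genes[1, ], dec$gene)
    complexes$members[[1]] <- intersect(cx_genes[1, ], dec$gene)
    complex_of[dropped] <- NA_integer_
  }

  # HV genes: keep the decoupled complex out so its noise stays at base scale
  hv_pool <- setdiff(genes, if (nrow(dec)) cx_genes[1, ] else character())
  hv_genes <- sort(sample(hv_pool, cfg$n_hv_genes))
  is_hv <- genes %in% hv_genes

  # per-gene correlation targets; decoupled genes pinned to decoupling_rho
  rho <- stats::rnorm(G, cfg$rho_median, cfg$rho_spread)
  rho <- pmin(pmax(rho, cfg$rho_range[1]), cfg$rho_range[2])
  names(rho) <- genes
  rho[dec$gene] <- cfg$decoupling_rho
  lambda <- 2 * sin(pi * rho / 6)

  # mRNA layer: gene means, HV group offsets, optional transcript latent
  mu <- stats::rnorm(G, cfg$mrna_mu_mean, cfg$mrna_mu_sd)
  mrna <- base::matrix(stats::rnorm(G * S, 0, cfg$mrna_sd), G, S,
                       dimnames = list(genes, samples)) + mu
  offs <- base::matrix(stats::rnorm(sum(is_hv) * cfg$n_groups, 0,
                                    cfg$mrna_group_sd), sum(is_hv))
  mrna[is_hv, ] <- mrna[is_hv, ] + offs[, group]
  if (cfg$transcript_latent_sd > 0) {
    Lm <- base::matrix(stats::rnorm(cfg$n_complexes * S), cfg$n_complexes, S)
    in_cx <- !is.na(complex_of)
    mrna[in_cx, ] <- mrna[in_cx, ] +
      cfg$transcript_latent_sd * Lm[complex_of[in_cx], ]
  }

  # protein layer
  sigma_p <- cfg$base_protein_sd *
    exp(stats::rnorm(G, 0, cfg$protein_sd_jitter)) *
    ifelse(is_hv, cfg$hv_sd_multiplier, 1)
  names(sigma_p) <- genes
  m_std <- t(scale(t(mrna)))  # per-gene standardized mRNA
  L <- base::matrix(stats::rnorm(cfg$n_complexes * S), cfg$n_complexes, S)
  eps <- base::matrix(stats::rnorm(G * S), G, S)
  lat_sd <- min(cfg$complex_latent_sd, 0.99)
  u <- eps
  in_cx <- !is.na(complex_of)
  u[in_cx, ] <- lat_sd * L[complex_of[in_cx], ] +
    sqrt(1 - lat_sd^2) * eps[in_cx, ]
  protein <- sigma_p * (lambda * m_std + sqrt(1 - lambda^2) * u)
  dimnames(protein) <- list(genes, samples)
  for (i in seq_len(nrow(dec)))
    protein[dec$gene[i], dec$sample[i]] <-
      protein[dec$gene[i], dec$sample[i]] + dec$shift[i]

  # protein-layer replicates: one per group up to n_replicates
  rep_parent <- character(0)
  if (cfg$n_replicates > 0) {
    parents <- samples[!duplicated(group)][seq_len(min(cfg$n_replicates,
                                                       cfg$n_groups))]
    extra <- cfg$n_replicates - length(parents)
    if (extra > 0) parents <- c(parents, sample(samples, extra))
    rep_ids <- paste0(parents, "_R", seq_along(parents))
    reps <- protein[, parents, drop = FALSE] +
      base::matrix(stats::rnorm(G * length(parents), 0, cfg$replicate_sd), G)
    colnames(reps) <- rep_ids
    protein <- cbind(protein, reps)
    rep_parent <- stats::setNames(parents, rep_ids)
  }

  if (cfg$missing_rate > 0) {
    protein[stats::runif(length(protein)) < cfg$missing_rate] <- NA_real_
  }

  md <- sample_metadata(
    sample_id = c(samples, names(rep_parent)),
    lineage = c(lineage, lineage[rep_parent]),
    subtype = c(paste0("SUBTYPE", group), paste0("SUBTYPE", group[rep_parent])),
    replicate_of = c(rep(NA_character_, S), unname(rep_parent)))

  truth <- list(group = group, lineage = lineage, hv_genes = hv_genes,
                rho_target = rho, lambda = lambda, sigma_p = sigma_p,
                noise_sd = sigma_p * sqrt(1 - lambda^2),
                complexes = complexes, complex_of = complex_of,
                decoupling = dec, replicate_of = rep_parent,
                config = cfg)
  list(protein = omics_matrix(protein, "protein_log2ratio"),
       mrna = omics_matrix(mrna, "mrna_log2tpm"),
       metadata = md, truth = truth)
}

#' Drug-response archetype configuration
#' @param n_target_drugs,n_lineage_drugs,n_toxic_drugs drug counts per
#'   archetype (target-driven, lineage-driven, broadly toxic).
#' @param target_effect slope `a` of sDSS on target protein level (log2).
#' @param noise_sd sDSS residual SD.
#' @param baseline sDSS intercept.
#' @param lineage_offset mean sDSS difference of the sensitive lineage.
#' @param toxic_mean,toxic_sd broad-toxicity archetype parameters.
#' @param n_drug_samples number of (non-replicate) cell lines screened.
#' @param shared_target_pairs target drugs 1..2k assigned pairwise-shared
#'   targets (k pairs), so drug-drug correlation structure is planted.
#' @param seed RNG seed.
#' @export
drug_config <- function(n_target_drugs = 20, n_lineage_drugs = 10,
                        n_toxic_drugs = 10, target_effect = 6, noise_sd = 2,
                        baseline = 5, lineage_offset = 10, toxic_mean = 15,
                        toxic_sd = 1, n_drug_samples = 43,
                        shared_target_pairs = 1, seed = 11) {
  as.list(environment())
}

#' Simulate drug responses driven by target abundance, lineage, or toxicity
#'
#' Target-driven drugs: sDSS = baseline + a * protein(target) + noise, target
#' sampled among genes fully quantified in the screened lines. Lineage-driven:
#' baseline + offset for one lineage + noise. Broadly toxic: N(toxic_mean,
#' toxic_sd). Effect sizes and the drug-target map are recorded in the
#' returned truth.
#'
#' @param protein protein [omics_matrix()] from [simulate_cohort()].
#' @param truth cohort truth from [simulate_cohort()].
#' @param config from [drug_config()].
#' @return list `sdss` ([drug_response_matrix()]), `annotations` (drug_id,
#'   class, targets list-column), `drug_truth` data.frame.
#' @export
simulate_drug_response <- function(protein, truth, config = drug_config()) {
  cfg <- config
  set.seed(cfg$seed)
  primary <- setdiff(colnames(protein), names(truth$replicate_of))
  lines <- sort(sample(primary, min(cfg$n_drug_samples, length(primary))))
  P <- protein[, lines, drop = FALSE]
  complete <- rownames(P)[rowSums(is.na(P)) == 0]
  if (!length(complete)) stop("no fully quantified genes to use as targets")
  n_t <- cfg$n_target_drugs
  targets <- sample(complete, n_t)
  if (cfg$shared_target_pairs > 0 && n_t >= 2) {
    k <- min(cfg$shared_target_pairs, floor(n_t / 2))
    for (j in seq_len(k)) targets[2 * j] <- targets[2 * j - 1]
  }
  n_all <- n_t + cfg$n_lineage_drugs + cfg$n_toxic_drugs
  drugs <- sprintf("DRUG%03d", seq_len(n_all))
  sdss <- base::matrix(NA_real_, n_all, length(lines),
                       dimnames = list(drugs, lines))
  archetype <- c(rep("target", n_t), rep("lineage", cfg$n_lineage_drugs),
                 rep("toxic", cfg$n_toxic_drugs))
  target_of <- c(targets, rep(NA_character_, n_all - n_t))
  lin <- truth$lineage[lines]
  sens_lineage <- rep(NA_character_, n_all)
  for (i in seq_len(n_all)) {
    noise <- stats::rnorm(length(lines), 0, cfg$noise_sd)
    if (archetype[i] == "target") {
      x <- P[target_of[i], ]
      x[is.na(x)] <- 0
      sdss[i, ] <- cfg$baseline + cfg$target_effect * x + noise
    } else if (archetype[i] == "lineage") {
      sl <- sample(c("B", "T"), 1)
      sens_lineage[i] <- sl
      sdss[i, ] <- cfg$baseline + cfg$lineage_offset * (lin == sl) + noise
    } else {
      sdss[i, ] <- stats::rnorm(length(lines), cfg$toxic_mean, cfg$toxic_sd)
    }
  }
  ann <- data.frame(drug_id = drugs, class = archetype,
                    mechanism = NA_character_, stringsAsFactors = FALSE)
  ann$targets <- lapply(target_of, function(t)
    if (is.na(t)) character(0) else t)
  drug_truth <- data.frame(drug_id = drugs, archetype = archetype,
                           target = target_of, effect = ifelse(
                             archetype == "target", cfg$target_effect, NA),
                           sens_lineage = sens_lineage,
                           stringsAsFactors = FALSE)
  list(sdss = drug_response_matrix(sdss), annotations = ann,
       drug_truth = drug_truth, lines = lines)
}

#' Simulate per-gene, per-TMT-set PSM counts
#'
#' Counts are lognormal (heavy-tailed, rounded) with per-gene location
#' inversely proportional to that gene's cross-sample protein variance, so the
#' protein-layer variance decreases monotonically with the min PSM count —
#' the moderation structure the PSM-trend differential test assumes. Zeros
#' occur naturally for high-variance genes, exercising the zero-ignoring min
#' rule.
#'
#' @param protein protein [omics_matrix()].
#' @param n_sets number of TMT sets (samples partitioned round-robin).
#' @param psm_scale numerator of the location rule lambda_g = scale / var_g.
#' @param psm_sdlog lognormal spread.
#' @param seed RNG seed.
#' @return integer matrix genes x sets with attribute `sets` (named list of
#'   sample ids per set).
#' @export
simulate_psm_counts <- function(protein, n_sets = 8, psm_scale = 3,
                                psm_sdlog = 0.5, seed = 23) {
  set.seed(seed)
  v <- apply(protein, 1L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- stats::median(v, na.rm = TRUE)
  lambda <- psm_scale / v
  counts <- vapply(seq_len(n_sets), function(s)
    as.integer(round(stats::rlnorm(length(lambda), log(lambda), psm_sdlog))),
    integer(length(lambda)))
  dimnames(counts) <- list(rownames(protein), sprintf("SET%02d", seq_len(n_sets)))
  sets <- split(colnames(protein),
                rep_len(sprintf("SET%02d", seq_len(n_sets)), ncol(protein)))
  attr(counts, "sets") <- sets
  counts
}
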