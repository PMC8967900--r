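# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# the default synthetic cohort (study conditions); cached across test files
default_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- simulate_cohort(sim_config())
  .fixture_env$cohort
}

# a fast, reduced cohort for structural tests
small_cohort <- function(seed = 3, ...) {
  simulate_cohort(sim_config(n_genes = 600, n_samples = 40, n_hv_genes = 60,
                             n_complexes = 12, n_replicates = 2, seed = seed,
                             ...))
}

toy_omics <- function(values, kind = "protein_log2ratio") {
  omics_matrix(values, kind)
}

# named matrix builder
nm <- function(data, genes, samples) {
  matrix(data, nrow = length(genes), ncol = length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}

# two-level group labels from cohort truth (named by sample)
truth_groups <- function(truth, a = 1, b = 2) {
  g <- ifelse(truth$group == a, "A", ifelse(truth$group == b, "B", "other"))
  stats::setNames(g, names(truth$group))
}

# brute-force weighted-KS enrichment score straight from the definition
brute_force_es <- function(scores, set, weight = 1) {
  scores <- sort(scores, decreasing = TRUE)
  ids <- names(scores)
  hits <- ids %in% set
  nr <- sum(abs(scores[hits])^weight)
  best <- 0; run <- 0
  for (i in seq_along(ids)) {
    if (hits[i]) run <- run + abs(scores[i])^weight / nr
    else run <- run - 1 / (length(ids) - sum(hits))
    if (abs(run) > abs(best)) best <- unname(run)
  }
  best
}
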