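# drugproteo

Integrative analysis of matched proteome, transcriptome and drug-sensitivity
profiles for leukemia cell-line panels.

## The problem

Panels of childhood acute lymphoblastic leukemia (ALL) cell lines profiled at
three levels — gene-symbol-centric relative protein abundance (log2 ratios
from multiplexed isobaric-label MS), protein-coding mRNA (log2 TPM), and
selective drug sensitivity scores (sDSS; dose-response sensitivity normalized
against healthy bone marrow) — support a family of questions that none of the
layers answers alone: which proteins vary enough across lines to define
molecular subgroups; how tightly protein follows transcript gene by gene, and
where individual samples break that coupling; whether protein complexes are
co-regulated beyond what their transcripts explain; which proteins explain
sensitivity to which drugs, and whether those relationships differ by
lineage (BCP-ALL vs T-ALL).

`drugproteo` implements the statistical layer of that analysis for anyone
working with such matrices:

* **Variable-feature selection** — per-protein trimmed ("quantile") SD,
  two-component Gaussian mixture via EM, and a threshold maximizing
  `sum_{x>t} [P(HV|x) − P(unmodulated|x)]`, run ten times with the mean
  threshold floored to 0.5 for reproducibility.
* **mRNA–protein correlation** — per-gene Spearman ρ over pairwise-complete
  samples, p from `t = r√(n−2)/√(1−r²)`, BH q; Fisher-z group comparisons
  (Welch t / ANOVA); within-complex vs random-pair co-regulation tests.
* **Stability scores** — per-gene loess of protein on mRNA; standardized
  residuals (`z = r / √(RSS/(n−enp))`) with |z| > 3 flagging per-sample
  protein–mRNA decoupling, aggregated to complex level.
* **Consensus clustering** — 2000 × (80% samples, 80% features) subsampled
  hierarchical clustering (1 − Pearson, ward.D2), CDF delta-area selection of
  k, outlier pre-flagging, replicate propagation, bootstrap cluster support.
* **Moderated differential abundance** — two-group contrast plus an "other"
  stratum, residual variance shrunk toward a loess trend on log min-PSM count
  (empirical-Bayes, prior df 3), moderated t on augmented df; cut-offs
  q ≤ 0.01 and |log2FC| ≥ log2(1.5).
* **Preranked GSEA** — weighted-KS enrichment score, gene-label permutations,
  sign-classed NES/q, leading edges.
* **Pharmacoproteomics** — effective-drug filtering (sDSS ≥ 8 in ≥ 2 lines),
  drug–protein and drug–drug Pearson correlation with putative-target
  ranking, protein-vs-mRNA correlation-strength comparison, PCA + UMAP
  embedding of drug correlation profiles (27 PCs; n_neighbors 25, spread 3.5,
  min_dist 0.05), and lineage differential correlation on the Fisher-z scale
  `(z_A − z_B)/√(1/(n_A−3) + 1/(n_B−3))` with analytic and permutation p.

A synthetic cohort generator (`simulate_cohort()`, `simulate_drug_response()`,
`simulate_psm_counts()`) emulates the statistical structure these methods
assume — median gene-wise Spearman ρ ≈ 0.55, bimodal protein variability,
protein-level complex co-regulation, planted decoupling events, lineage
blocks, TMT-style missingness, target-driven drug response — with full ground
truth, so the whole pipeline is testable offline. See
`vignettes/pipeline-methods.Rmd` for the models and design choices.

## Worked example

The numbered scripts under `analysis/` run the full workflow on the synthetic
cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R              # cohort + drugs + PSM + truth
Rscript analysis/02_hvf_clustering.R        # HVF selection + consensus clustering
Rscript analysis/03_correlation_stability.R # correlations, complexes, stability
Rscript analysis/04_differential_gsea.R     # moderated DE + preranked GSEA
Rscript analysis/05_pharmaco.R              # drug-protein layer
```

Selected output of one run (seeds fixed in the scripts):

```
<hvf_result> 3000 features, final threshold 1.0, 321 highly variable
HV recovery vs truth: recall 1.000, precision 0.935
<consensus_result> k in {2,3,4,5,6}, chosen k = 4
chosen k = 4; ARI vs planted groups = 1.000; bootstrap support: 0.99 0.96 0.99 0.95
median gene-wise Spearman rho = 0.550; 99.9% positive, 90.5% significant positive (q <= 0.01)
<complex_coregulation> mean r within 0.300 vs random 0.006 (n = 396/396), t-test p = 1.32e-132
same test on the transcript layer: p = 0.655 (complex co-regulation is protein-level)
planted decoupling (S01, 4 members): mean standardized residual -3.72
putative targets at rank 1 for 20/20 annotated drugs (median rank 1 of 3000 features)
```

Reading: the mixture threshold lands at 1.0 and recovers the 300 planted
highly variable proteins essentially exactly; consensus clustering picks the
planted k = 4 sample groups with perfect agreement; the gene-wise mRNA–protein
correlation median matches the configured 0.55; complex members co-vary at
the protein level (mean pairwise r 0.30 vs 0.01 for random pairs) but not at
the transcript level; the planted 4-member complex decoupling in sample S01
is the only complex/sample combination with mean standardized residual below
−3; and every target-driven drug ranks its true target first among 3000
proteins.

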