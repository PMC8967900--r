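test_that("min PSM ignores zeros and missing, excludes unquantified genes", {
  psm <- nm(c(12, 0, 7,
              0, 0, 0,
              NA, 3, NA), c("GA", "GB", "GC"), c("SET1", "SET2", "SET3"))
  mp <- min_psm_per_protein(psm)
  expect_equal(unname(mp["GA"]), 7)
  expect_false("GB" %in% names(mp))   # no quantified PSM -> excluded
  expect_equal(unname(mp["GC"]), 3)
  mp2 <- min_psm_per_protein(psm, contributing_sets = c("SET1", "SET2"))
  expect_equal(unname(mp2["GA"]), 12)
  expect_error(min_psm_per_protein(psm, character(0)), "empty")
})

test_that("identical groups give zero fold change; dropped genes are counted", {
  set.seed(70)
  x <- nm(stats::rnorm(200), sprintf("G%03d", 1:20), sprintf("S%02d", 1:10))
  x <- cbind(x, x); colnames(x) <- sprintf("S%02d", 1:20)
  grp <- stats::setNames(rep(c("A", "B"), each = 10), colnames(x))
  de <- moderated_ttest(x, grp, contrast = c("A", "B"), include_other = FALSE)
  expect_true(all(abs(de$logFC) < 1e-12))
  x[1, grp == "A"] <- NA  # group A entirely missing for G001
  de2 <- moderated_ttest(x, grp, contrast = c("A", "B"),
                         include_other = FALSE)
  expect_false("G001" %in% de2$gene)
  expect_equal(attr(de2, "n_dropped"), 1)
})

test_that("flat prior with no trend reproduces the ordinary pooled t", {
  set.seed(71)
  x <- nm(stats::rnorm(50 * 12, 0, 0.7), sprintf("G%03d", 1:50),
          sprintf("S%02d", 1:12))
  grp <- stats::setNames(rep(c("A", "B"), each = 6), colnames(x))
  de <- moderated_ttest(x, grp, contrast = c("A", "B"), psm_min = NULL,
                        prior_df = 0, include_other = FALSE)
  tcl <- vapply(seq_len(nrow(x)), function(i) {
    unname(stats::t.test(x[i, 1:6], x[i, 7:12],
                         var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_lt(max(abs(de$t - tcl)), 1e-10)
})

test_that("the variance trend decreases with PSM count and shrinks low-PSM genes", {
  co <- default_cohort()
  psm <- simulate_psm_counts(co$protein)
  mp <- min_psm_per_protein(psm)
  grp <- truth_groups(co$truth)
  de <- moderated_ttest(co$protein, grp, contrast = c("A", "B"), psm_min = mp)
  bins <- cut(log1p(de$min_psm), 4)
  med <- tapply(de$s2_prior, bins, stats::median)
  expect_true(all(diff(med) < 0))
  # shrinkage always pulls the gene variance toward its trend value
  expect_true(all(abs(de$s2_mod - de$s2_prior) <=
                    abs(de$s2 - de$s2_prior) + 1e-12))
  # with few residual df the skew of s^2 means most low-PSM genes are bumped up
  set.seed(75)
  G <- 2000
  mp2 <- stats::setNames(pmax(1, round(stats::rlnorm(G, 1.5, 0.7))),
                         sprintf("G%04d", 1:G))
  sdg <- 0.3 + 1 / sqrt(mp2)
  x <- nm(stats::rnorm(G * 6, 0, sdg), names(mp2), sprintf("S%d", 1:6))
  grp2 <- stats::setNames(rep(c("A", "B"), each = 3), colnames(x))
  de2 <- moderated_ttest(x, grp2, contrast = c("A", "B"), psm_min = mp2,
                         include_other = FALSE)
  low <- de2$min_psm <= stats::quantile(de2$min_psm, 0.25)
  expect_gt(mean(de2$s2_mod[low] > de2$s2[low]), 0.5)
})

test_that("planted 2-fold changes are detected with high sensitivity", {
  # a strong lineage-style contrast: most of the proteome shifts two-fold
  set.seed(72)
  G <- 1000; n <- 6
  x <- nm(stats::rnorm(G * 2 * n, 0, 0.4), sprintf("G%04d", 1:G),
          sprintf("S%02d", 1:(2 * n)))
  planted <- sample(G, 800)
  x[planted, 1:n] <- x[planted, 1:n] + 1  # true log2FC = 1
  grp <- stats::setNames(rep(c("A", "B"), each = n), colnames(x))
  de <- moderated_ttest(x, grp, contrast = c("A", "B"), include_other = FALSE)
  sens <- mean(de$significant[match(rownames(x)[planted], de$gene)])
  expect_gte(sens, 0.8)
  fdr <- sum(de$significant & !(de$gene %in% rownames(x)[planted])) /
    max(sum(de$significant), 1)
  expect_lt(fdr, 0.05)
})

test_that("BH q values are invariant to gene order", {
  set.seed(73)
  x <- nm(stats::rnorm(30 * 8), sprintf("G%03d", 1:30), sprintf("S%d", 1:8))
  grp <- stats::setNames(rep(c("A", "B"), each = 4), colnames(x))
  de1 <- moderated_ttest(x, grp, contrast = c("A", "B"),
                         include_other = FALSE)
  de2 <- moderated_ttest(x[sample(30), ], grp, contrast = c("A", "B"),
                         include_other = FALSE)
  expect_equal(de1$q[match(de2$gene, de1$gene)], de2$q)
})

test_that("moderated statistics track an independent empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  set.seed(74)
  G <- 500; n <- 5
  sdg <- sqrt(1 / stats::rgamma(G, 4, 4)) * 0.5  # inverse-chi-like spread
  x <- nm(stats::rnorm(G * 2 * n, 0, sdg), sprintf("G%03d", 1:G),
          sprintf("S%02d", 1:(2 * n)))
  grp <- stats::setNames(rep(c("A", "B"), each = n), colnames(x))
  de <- moderated_ttest(x, grp, contrast = c("A", "B"), psm_min = NULL,
                        prior_df = 4, include_other = FALSE)
  design <- stats::model.matrix(~ 0 + factor(grp))
  colnames(design) <- c("A", "B")
  fit <- limma::lmFit(x, design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(A - B,
                                                        levels = design))
  fit <- limma::eBayes(fit)
  # same shrinkage principle, close agreement in the moderated t ordering
  expect_gt(stats::cor(de$t, fit$t[de$gene, 1], method = "spearman"), 0.98)
})
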