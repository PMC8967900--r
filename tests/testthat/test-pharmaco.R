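test_that("effective-drug filtering applies the threshold rule and is monotone", {
  x <- nm(c(9, 7, 8,
            7, 7, 7,
            9, NA, 9), c("D1", "D2", "D3"), c("S1", "S2", "S3"))
  sd_ <- drug_response_matrix(x)
  expect_setequal(suppressMessages(filter_effective_drugs(sd_, 8, 2)),
                  c("D1", "D3"))
  expect_length(suppressMessages(filter_effective_drugs(sd_, 10, 1)), 0)
  # monotone: raising threshold or min_lines never grows the set
  k1 <- suppressMessages(filter_effective_drugs(sd_, 8, 1))
  k2 <- suppressMessages(filter_effective_drugs(sd_, 8, 2))
  k3 <- suppressMessages(filter_effective_drugs(sd_, 9, 2))
  expect_true(all(k2 %in% k1))
  expect_true(all(k3 %in% k2))
})

test_that("a drug tracking one feature exactly ranks that feature first", {
  set.seed(90)
  f <- nm(stats::rnorm(20 * 15), sprintf("G%03d", 1:20), sprintf("S%02d", 1:15))
  sd_ <- drug_response_matrix(nm(3 * f["G007", ] + 2, "D1", colnames(f)))
  ann <- data.frame(drug_id = "D1", stringsAsFactors = FALSE)
  ann$targets <- list("G007")
  dfc <- suppressMessages(drug_feature_correlations(
    sd_, omics_matrix(f, "protein_log2ratio"), min_n = 5, annotations = ann))
  expect_equal(dfc$target_ranks$rank, 1L)
  expect_equal(unname(dfc$r["D1", "G007"]), 1, tolerance = 1e-12)
  # a feature with too few overlapping samples is excluded from the ranking
  f2 <- f; f2["G001", 1:12] <- NA
  dfc2 <- suppressMessages(drug_feature_correlations(
    sd_, omics_matrix(f2, "protein_log2ratio"), min_n = 5, annotations = ann))
  expect_true(is.na(dfc2$r["D1", "G001"]))
  expect_equal(dfc2$target_ranks$n_features, 19)
})

test_that("drug-drug correlations flag duplicates and planted shared targets", {
  co <- small_cohort(seed = 4)
  dr <- simulate_drug_response(co$protein, co$truth,
                               drug_config(shared_target_pairs = 1, seed = 9))
  dd <- drug_drug_correlations(dr$sdss)
  pair <- dd[dd$id_a == "DRUG001" & dd$id_b == "DRUG002", ]
  expect_gt(pair$r, 0.6)  # same generating target
  dup <- rbind(dr$sdss[, ], DRUGDUP = dr$sdss[1, ])
  dd2 <- drug_drug_correlations(drug_response_matrix(dup))
  expect_equal(dd2$r[dd2$id_a == "DRUG001" & dd2$id_b == "DRUGDUP"], 1,
               tolerance = 1e-12)
  expect_error(drug_drug_correlations(dr$sdss[1, , drop = FALSE]), ">= 2")
})

test_that("protein-vs-mRNA comparison: identity is null, swap reverses sign", {
  # drugs respond to a latent program expressed at the protein level; the
  # transcript layer sees the same program through extra noise
  set.seed(91)
  n <- 40; G <- 80; D <- 15
  u <- stats::rnorm(n)
  p <- nm(stats::rnorm(G * n, 0, 0.6), sprintf("G%03d", 1:G),
          sprintf("S%02d", 1:n)) + outer(stats::rnorm(G, 0.8, 0.1), u)
  sdss <- drug_response_matrix(
    nm(stats::rnorm(D * n, 0, 0.5), sprintf("D%02d", 1:D), colnames(p)) +
      outer(rep(1, D), u) + 10)
  same <- suppressMessages(compare_protein_vs_rna_correlation(
    sdss, omics_matrix(p, "protein_log2ratio"),
    omics_matrix(p[, ], "mrna_log2tpm"), min_n = 8))
  expect_equal(same$mean_diff, 0)
  expect_gt(same$p, 0.99)
  noisy <- p + nm(stats::rnorm(length(p), 0, 1.0), rownames(p), colnames(p))
  res <- suppressMessages(compare_protein_vs_rna_correlation(
    sdss, omics_matrix(p, "protein_log2ratio"),
    omics_matrix(noisy, "mrna_log2tpm"), min_n = 8))
  expect_equal(res$direction, "protein_higher")
  expect_lt(res$p, 1e-6)
  swap <- suppressMessages(compare_protein_vs_rna_correlation(
    sdss, omics_matrix(noisy, "protein_log2ratio"),
    omics_matrix(p[, ], "mrna_log2tpm"), min_n = 8))
  expect_equal(swap$direction, "mrna_higher")
  expect_equal(abs(swap$statistic), abs(res$statistic), tolerance = 1e-10)
})

test_that("embedding returns one deterministic row per drug", {
  set.seed(92)
  r <- matrix(stats::rnorm(40 * 60), 40,
              dimnames = list(sprintf("D%02d", 1:40), sprintf("G%03d", 1:60)))
  r[sample(length(r), 50)] <- NA
  e1 <- suppressMessages(embed_drug_profiles(r, n_pcs = 10, n_neighbors = 8,
                                             seed = 42))
  e2 <- suppressMessages(embed_drug_profiles(r, n_pcs = 10, n_neighbors = 8,
                                             seed = 42))
  expect_equal(nrow(e1), 40)
  expect_true(all(is.finite(e1$dim1)))
  expect_identical(e1, e2)
  expect_warning(suppressMessages(embed_drug_profiles(
    r, n_pcs = 100, n_neighbors = 8, seed = 1)), "clamped")
})

test_that("two orthogonal drug classes separate in the embedding", {
  set.seed(93)
  prog_a <- stats::rnorm(120); prog_b <- stats::rnorm(120)
  mk <- function(prog) t(vapply(1:20, function(i)
    prog + stats::rnorm(120, 0, 0.4), numeric(120)))
  r <- rbind(mk(prog_a), mk(prog_b))
  dimnames(r) <- list(sprintf("D%02d", 1:40), sprintf("G%03d", 1:120))
  emb <- suppressMessages(embed_drug_profiles(r, n_pcs = 10, n_neighbors = 8,
                                              seed = 7))
  d <- as.matrix(stats::dist(emb[, c("dim1", "dim2")]))
  cls <- rep(1:2, each = 20)
  within <- mean(d[outer(cls, cls, "==") & upper.tri(d)])
  between <- mean(d[outer(cls, cls, "!=")])
  expect_lt(within, between)
  # near-duplicate drug lands near its twin
  r2 <- rbind(r, DUP = r[1, ] + stats::rnorm(120, 0, 1e-3))
  emb2 <- suppressMessages(embed_drug_profiles(r2, n_pcs = 10,
                                               n_neighbors = 8, seed = 7))
  d2 <- as.matrix(stats::dist(emb2[, c("dim1", "dim2")]))
  expect_lt(d2["41", "1"], stats::quantile(d2[upper.tri(d2)], 0.01))
})

test_that("differential correlation reproduces the closed-form z difference", {
  # construction with known group correlations via common-factor mixing
  gen_pair <- function(n, r, seed) {
    set.seed(seed)
    z <- stats::rnorm(n)
    x <- sqrt(abs(r)) * z + sqrt(1 - abs(r)) * stats::rnorm(n)
    y <- sign(r) * sqrt(abs(r)) * z + sqrt(1 - abs(r)) * stats::rnorm(n)
    cbind(x, y)
  }
  # frozen oracle: r_a = 0.7, r_b = 0, n = 30 each
  zd <- (atanh(0.7) - atanh(0)) / sqrt(1 / 27 + 1 / 27)
  expect_equal(zd, 3.1867, tolerance = 1e-4)
  expect_equal(2 * stats::pnorm(-zd), 0.00144, tolerance = 1e-2)
  set.seed(94)
  a <- gen_pair(30, 0.9, 1); b <- gen_pair(30, 0.9, 2)
  sam <- sprintf("S%02d", 1:60)
  sd_ <- drug_response_matrix(nm(c(a[, 1], b[, 1]) + 10, "D1", sam))
  fe <- omics_matrix(nm(c(a[, 2], -b[, 2]) + 5, "G1", sam),
                     "protein_log2ratio")
  grp <- stats::setNames(rep(c("A", "B"), each = 30), sam)
  dct <- suppressMessages(differential_correlation(sd_, fe, grp,
                                                   n_perm = 200, seed = 3))
  ra <- stats::cor(a[, 1], a[, 2]); rb <- stats::cor(b[, 1], -b[, 2])
  expect_equal(dct$r_a, ra, tolerance = 1e-10)
  expect_equal(dct$r_b, rb, tolerance = 1e-10)
  expect_equal(dct$z_diff,
               (atanh(ra) - atanh(rb)) / sqrt(1 / 27 + 1 / 27),
               tolerance = 1e-10)
  expect_identical(dct$class, "+/-")
  expect_lt(dct$p_analytic, 0.01)
  expect_lt(dct$p_perm, 0.05)
})

test_that("identical correlation structure in both groups is a null", {
  set.seed(95)
  n <- 60
  z <- stats::rnorm(2 * n)
  x <- z + stats::rnorm(2 * n); y <- z + stats::rnorm(2 * n)
  sam <- sprintf("S%02d", 1:(2 * n))
  sd_ <- drug_response_matrix(nm(x + 10, "D1", sam))
  fe <- omics_matrix(nm(y + 5, "G1", sam), "protein_log2ratio")
  grp <- stats::setNames(rep(c("A", "B"), each = n), sam)
  dct <- suppressMessages(differential_correlation(sd_, fe, grp,
                                                   n_perm = 100, seed = 4))
  expect_gt(dct$p_analytic, 0.05)
  expect_match(dct$class, "\\+/\\+")
  # zeros are excluded from the correlation when exclude_zero is on
  fe0 <- fe; fe0[1, 1:5] <- 0
  dct0 <- suppressMessages(differential_correlation(sd_, fe0, grp,
                                                    n_perm = 10, seed = 5))
  expect_equal(dct0$n_a, sum(grp == "A") - 5)
})
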