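# three well-separated Gaussian sample groups (separation in units of the
# within-group SD), used across the clustering tests
three_group_matrix <- function(n_genes = 200, per_group = 8, sep = 5,
                               seed = 60) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(n_genes * 3, 0, sep), n_genes, 3)
  x <- centers[, rep(1:3, each = per_group)] +
    matrix(stats::rnorm(n_genes * 3 * per_group), n_genes)
  dimnames(x) <- list(sprintf("G%03d", 1:n_genes),
                      sprintf("S%02d", seq_len(3 * per_group)))
  omics_matrix(x, "protein_log2ratio")
}

test_that("outlier flagging spares correlated samples, catches noise", {
  x <- three_group_matrix()
  dup <- cbind(x[, ], x[, 1, drop = FALSE])
  colnames(dup)[ncol(dup)] <- "DUP"
  fl <- flag_outlier_samples(omics_matrix(dup, "protein_log2ratio"))
  expect_false(fl["S01"]); expect_false(fl["DUP"])  # r = 1 pair
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    y <- x[, ]
    y <- rbind(y, matrix(stats::rnorm(1800 * ncol(y)), 1800,
                         dimnames = list(sprintf("N%04d", 1:1800),
                                         colnames(y))))
    y[, "S01"] <- stats::rnorm(nrow(y))  # pure-noise sample
    hits <- hits + flag_outlier_samples(
      omics_matrix(y, "protein_log2ratio"))["S01"]
  }
  expect_gte(hits / 20, 0.95)
  # two samples only: evaluated against each other
  two <- x[, 1:2]
  expect_length(flag_outlier_samples(omics_matrix(two, "protein_log2ratio")), 2)
})

test_that("duplicate sample blocks give an exact 0/1 consensus at k = 2", {
  set.seed(61)
  a <- matrix(stats::rnorm(100), 50, 2)
  x <- cbind(a[, c(1, 1, 1)], a[, c(2, 2, 2)]) +
    matrix(stats::rnorm(300, 0, 1e-3), 50)
  dimnames(x) <- list(sprintf("G%02d", 1:50), sprintf("S%d", 1:6))
  cr <- consensus_cluster(omics_matrix(x, "protein_log2ratio"),
                          k_range = 2:3, reps = 50, r_min = 0, seed = 1)
  cm <- cr$consensus[["2"]]
  blocks <- outer(rep(1:2, each = 3), rep(1:2, each = 3), "==")
  expect_true(all(abs(cm[blocks] - 1) < 1e-12 | cm[blocks] == 0))
  co_sampled <- cm[blocks & upper.tri(cm)]
  expect_true(all(co_sampled[co_sampled > 0] == 1))
  expect_true(all(cm[!blocks] == 0))
  expect_true(isSymmetric(unname(cm)))
})

test_that("three separated groups: chosen k = 3 with perfect assignments", {
  x <- three_group_matrix()
  cr <- consensus_cluster(x, k_range = 2:6, reps = 200, r_min = 0, seed = 2)
  expect_equal(cr$chosen_k, 3)
  asn <- cr$assignments[["3"]]
  truth <- rep(1:3, each = 8)
  expect_equal(adjusted_rand_index(asn, truth), 1)
  # determinism under the seed
  cr2 <- consensus_cluster(x, k_range = 2:6, reps = 200, r_min = 0, seed = 2)
  expect_identical(cr$consensus, cr2$consensus)
  # consensus entries live in [0, 1] and delta areas are reported per k
  expect_true(all(vapply(cr$consensus, function(m) all(m >= 0 & m <= 1),
                         logical(1))))
  expect_length(cr$delta_area, 5)
})

test_that("assignments are invariant to sample order (up to renaming)", {
  x <- three_group_matrix(seed = 62)
  perm <- sample(ncol(x))
  cr1 <- consensus_cluster(x, k_range = 2:4, reps = 100, r_min = 0, seed = 3)
  cr2 <- consensus_cluster(x[, perm], k_range = 2:4, reps = 100, r_min = 0,
                           seed = 4)
  a1 <- cr1$assignments[["3"]]
  a2 <- cr2$assignments[["3"]][names(a1)]
  expect_equal(adjusted_rand_index(a1, a2), 1)
})

test_that("full sampling with one rep degenerates to plain hclust", {
  x <- three_group_matrix(seed = 63)
  cr <- consensus_cluster(x, k_range = 2:4, reps = 1, pItem = 1, pFeature = 1,
                          r_min = 0, seed = 5)
  hc <- stats::hclust(stats::as.dist(1 - stats::cor(x[, ])),
                      method = "ward.D2")
  for (k in 2:4) {
    plain <- stats::cutree(hc, k = k)
    expect_equal(adjusted_rand_index(cr$assignments[[as.character(k)]],
                                     plain), 1)
  }
})

test_that("structureless data shows no dominant delta-area step after k = 2", {
  set.seed(64)
  noise <- matrix(stats::rnorm(200 * 24), 200,
                  dimnames = list(sprintf("G%03d", 1:200),
                                  sprintf("S%02d", 1:24)))
  cr_noise <- consensus_cluster(omics_matrix(noise, "protein_log2ratio"),
                                k_range = 2:6, reps = 150, r_min = 0, seed = 6)
  cr_struct <- consensus_cluster(three_group_matrix(seed = 65), k_range = 2:6,
                                 reps = 150, r_min = 0, seed = 6)
  expect_lt(max(cr_noise$delta_area[-1]), max(cr_struct$delta_area[-1]))
})

test_that("final clustering propagates replicates and supports clusters", {
  x <- three_group_matrix()
  md <- sample_metadata(c(colnames(x), "S01_R1"),
                        lineage = rep("B", ncol(x) + 1),
                        replicate_of = c(rep(NA, ncol(x)), "S01"))
  xr <- cbind(x[, ], "S01_R1" = x[, "S01"] + stats::rnorm(nrow(x), 0, 0.05))
  fin <- finalize_clusters(omics_matrix(xr, "protein_log2ratio"), 3, md,
                           B = 100, seed = 7)
  expect_equal(unname(fin$cluster["S01_R1"]), unname(fin$cluster["S01"]))
  expect_true(all(fin$support >= 0.95))
  # k = n samples: singletons, support defined, no crash
  fin_n <- finalize_clusters(x, ncol(x), B = 10, seed = 8)
  expect_length(unique(fin_n$cluster), ncol(x))
  expect_true(all(is.finite(fin_n$support)))
})
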