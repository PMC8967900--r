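test_that("matrix TSV round-trips values including missing cells", {
  x <- nm(c(1.5, NA, -0.25, 0, 2.125, 3), c("GA", "GB"), c("S1", "S2", "S3"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(x, f)
  y <- read_matrix_tsv(f)
  expect_identical(unclass(y)[, ], x[, ])
  # and a second round trip is value-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(y, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("loading validates identifiers and numeric cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "ga\t1\t2", "GA\t3\t4"), f)
  expect_error(read_matrix_tsv(f), "GA")          # duplicate after uppercasing
  writeLines(c("gene\tS1\tS2", "GA\t1\tx2", "GB\t3\t4"), f)
  err <- tryCatch(read_matrix_tsv(f), error = function(e) conditionMessage(e))
  expect_match(err, "GA")                          # names the row
  expect_match(err, "S2")                          # and the column
  writeLines(c("gene\tS1\tS2", " ga \t1\t2", "GB\t3\t4"), f)
  expect_identical(rownames(read_matrix_tsv(f)), c("GA", "GB"))
})

test_that("cohort loader reports shapes and complete-case counts", {
  co <- small_cohort()
  d <- withr::local_tempdir()
  write_matrix_tsv(co$protein, file.path(d, "p.tsv"))
  write_matrix_tsv(co$mrna, file.path(d, "r.tsv"))
  utils::write.table(as.data.frame(co$metadata), file.path(d, "m.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  loaded <- suppressMessages(
    load_cohort(file.path(d, "p.tsv"), file.path(d, "r.tsv"),
                file.path(d, "m.tsv")))
  expect_equal(dim(loaded$protein), dim(co$protein))
  expect_equal(loaded$summary$n_complete_protein,
               sum(stats::complete.cases(co$protein)))
  expect_equal(loaded$summary$n_shared_features, nrow(co$mrna))
})

test_that("replicate collapse takes the protein-wise median, ignoring missing", {
  md <- sample_metadata(c("P", "R1", "R2", "Q"), lineage = rep("B", 4),
                        replicate_of = c(NA, "P", "P", NA))
  x <- nm(c(1, 3, NA, 9,
            1, 2, 10, 9,
            1, NA, NA, 9), c("GA", "GB", "GC"), c("P", "R1", "R2", "Q"))
  out <- suppressWarnings(collapse_replicates(toy_omics(x), md))
  expect_identical(colnames(out), c("P", "Q"))
  expect_equal(unname(out["GA", "P"]), 2)    # median of {1, 3}, NA ignored
  expect_equal(unname(out["GB", "P"]), 2)    # median of {1, 2, 10}
  expect_equal(unname(out["GC", "P"]), 1)    # median of {1}
  expect_equal(unname(out[, "Q"]), c(9, 9, 9))  # untouched passthrough
})

test_that("replicate collapse is idempotent and replicate-order invariant", {
  co <- small_cohort()
  c1 <- suppressWarnings(collapse_replicates(co$protein, co$metadata))
  c2 <- suppressWarnings(collapse_replicates(c1, co$metadata))
  expect_identical(c1[, ], c2[, ])
  perm <- sample(colnames(co$protein))
  c3 <- suppressWarnings(collapse_replicates(co$protein[, perm], co$metadata))
  expect_identical(c1[, colnames(c1)], c3[, colnames(c1)])
  # empty replicate group -> missing value with warning
  md <- sample_metadata(c("P", "R"), c("B", "B"), replicate_of = c(NA, "P"))
  x <- nm(c(NA_real_, NA_real_), "GA", c("P", "R"))
  expect_warning(out <- collapse_replicates(toy_omics(x), md), "missing")
  expect_true(is.na(out["GA", "P"]))
})

test_that("sample alignment intersects, sorts, and is symmetric", {
  a <- nm(1:6, c("GA", "GB"), c("A", "B", "C"))
  b <- nm(1:6, c("GA", "GB"), c("D", "C", "B"))
  al <- suppressMessages(align_samples(a, b))
  expect_identical(al$shared, c("B", "C"))
  expect_identical(colnames(al$a), colnames(al$b))
  al2 <- suppressMessages(align_samples(b, a))
  expect_identical(al2$shared, al$shared)
  expect_error(suppressMessages(
    align_samples(a, nm(1:2, "GA", c("X", "Y")))), "no shared")
  # cohort fixtures share exactly the primary samples
  co <- default_cohort()
  al3 <- suppressMessages(align_samples(co$protein, co$mrna))
  expect_length(al3$shared, 64)
})

test_that("metadata invariants reject unknown parents and chains", {
  expect_error(sample_metadata("A", "B", replicate_of = "Z"), "unknown")
  expect_error(sample_metadata(c("A", "B", "C"), rep("B", 3),
                               replicate_of = c(NA, "A", "B")), "chain")
  expect_error(sample_metadata(c("A", "A"), c("B", "B")), "duplicate")
})

test_that("annotation formats parse with symbol normalization", {
  d <- withr::local_tempdir()
  gmt <- file.path(d, "sets.gmt")
  writeLines(c("SET1\tdesc\ta\tB", "SET2\tdesc\tC\tD\tE"), gmt)
  gs <- read_gmt(gmt)
  expect_identical(as.character(gs$SET1), c("A", "B"))
  writeLines(c("SET1\tdesc"), gmt)
  expect_error(read_gmt(gmt), "line 1")

  cpx <- file.path(d, "cpx.tsv")
  writeLines(c("complex_id\tname\tmembers", "C1\tGINS\tGINS1;GINS2;GINS3;GINS4"),
             cpx)
  cat_ <- read_complex_catalog(cpx)
  expect_length(cat_$members[[1]], 4)

  da <- file.path(d, "drugs.tsv")
  writeLines(c("drug_id\tclass\ttargets", "D1\tGC\tNR3C1", "D2\tother\t"), da)
  ann <- read_drug_annotations(da)
  expect_identical(ann$targets[[1]], "NR3C1")
  expect_length(ann$targets[[2]], 0)
})
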