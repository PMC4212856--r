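test_that("TSV round trip reproduces the dataset exactly", {
  tmp <- withr::local_tempdir()
  paths <- write_tiny_tsvs(tmp)
  ds <- read_dataset(paths$genotype, paths$samples)
  expect_identical(unname(dim_dataset(ds)), c(3L, 2L))
  expect_identical(unclass(ds$phenotypes)["B01", "L2"], NA_integer_)

  g2 <- file.path(tmp, "geno2.tsv"); s2 <- file.path(tmp, "samples2.tsv")
  write_dataset(ds, g2, s2)
  ds2 <- read_dataset(g2, s2)
  expect_identical(unclass(ds$phenotypes), unclass(ds2$phenotypes))
  expect_equal(as.data.frame(ds$samples), as.data.frame(ds2$samples))
})

test_that("malformed inputs raise typed errors", {
  tmp <- withr::local_tempdir()
  paths <- write_tiny_tsvs(tmp)

  gdup <- file.path(tmp, "dup.tsv")
  writeLines(c("individual_id\tL1\tL2", "B01\t1\t0", "B01\t0\t1"), gdup)
  expect_error(read_dataset(gdup, paths$samples), class = "aflpsgs_consistency_error")

  gbad <- file.path(tmp, "bad.tsv")
  writeLines(c("individual_id\tL1", "A01\t2"), gbad)
  expect_error(read_dataset(gbad, paths$samples), class = "aflpsgs_format_error")

  sbad <- file.path(tmp, "sbad.tsv")
  writeLines(c("individual_id\tpatch_id\tlat\tlon",
               "A01\tP1\t95.0\t19.0", "A02\tP1\t95.0\t19.0",
               "B01\tP2\t53.5\t19.4"), sbad)
  expect_error(read_dataset(paths$genotype, sbad), class = "aflpsgs_range_error")

  smiss <- file.path(tmp, "smiss.tsv")
  writeLines(c("individual_id\tpatch_id\tlat\tlon",
               "A01\tP1\t53.1\t19.0", "A02\tP1\t53.1\t19.0"), smiss)
  expect_error(read_dataset(paths$genotype, smiss),
               class = "aflpsgs_consistency_error")

  # individuals of one patch must share coordinates
  ssplit <- file.path(tmp, "ssplit.tsv")
  writeLines(c("individual_id\tpatch_id\tlat\tlon",
               "A01\tP1\t53.1\t19.0", "A02\tP1\t53.2\t19.0",
               "B01\tP2\t53.5\t19.4"), ssplit)
  expect_error(read_dataset(paths$genotype, ssplit),
               class = "aflpsgs_consistency_error")
})

test_that("locus filter keeps the open retention band and is idempotent", {
  n <- 100
  ph <- cbind(L_mid = c(rep(1L, 50), rep(0L, 50)),
              L_rare = c(rep(1L, 2), rep(0L, 98)),
              L_edge = c(rep(1L, 3), rep(0L, 97)),      # f = 0.03 exactly
              L_common = c(rep(1L, 97), rep(0L, 3)))    # f = 0.97 exactly
  rownames(ph) <- sprintf("i%03d", 1:n)
  ds <- aflp_dataset(dominant_matrix(ph),
                     sample_table(make_samples_df(rownames(ph))))
  f <- filter_loci(ds)
  expect_identical(colnames(f$phenotypes), "L_mid")
  expect_setequal(attr(f, "dropped_loci"), c("L_rare", "L_edge", "L_common"))
  f2 <- filter_loci(f)
  expect_identical(unclass(f2$phenotypes), unclass(f$phenotypes))
})

test_that("filtering away all loci warns instead of failing", {
  ph <- matrix(c(rep(1L, 1), rep(0L, 99)), ncol = 1,
               dimnames = list(sprintf("i%03d", 1:100), "L1"))
  ds <- aflp_dataset(dominant_matrix(ph),
                     sample_table(make_samples_df(rownames(ph))))
  expect_warning(out <- filter_loci(ds), "all loci dropped")
  expect_identical(ncol(out$phenotypes), 0L)
})

test_that("geographic distances are haversine km with exact patch zeros", {
  sm <- sample_table(data.frame(
    individual_id = c("a", "b", "c", "d"),
    patch_id = c("P1", "P1", "P2", "P3"),
    lat = c(0, 0, 0, 10), lon = c(0, 0, 1, 5)))
  D <- geo_distance_matrix(sm)
  expect_identical(D["a", "b"], 0)
  expect_equal(D["a", "c"], pi * 6371.0088 / 180, tolerance = 1e-6)
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("random-coordinate distances obey the triangle inequality", {
  set.seed(421)
  for (rep in 1:25) {
    sm <- sample_table(data.frame(
      individual_id = c("a", "b", "c"), patch_id = c("P1", "P2", "P3"),
      lat = runif(3, -80, 80), lon = runif(3, -179, 179)))
    D <- geo_distance_matrix(sm)
    expect_lte(D[1, 3], D[1, 2] + D[2, 3] + 1e-9)
    expect_lte(D[1, 2], D[1, 3] + D[3, 2] + 1e-9)
  }
})
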