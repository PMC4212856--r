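test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_unstructured(30, 10, seed = 1)$dataset$phenotypes,
                   gen_unstructured(30, 10, seed = 1)$dataset$phenotypes)
  expect_identical(gen_island(5, 6, 10, 0.1, seed = 2)$dataset$phenotypes,
                   gen_island(5, 6, 10, 0.1, seed = 2)$dataset$phenotypes)
  expect_identical(gen_related_pairs(20, 10, "full_sib", seed = 3)$dataset$phenotypes,
                   gen_related_pairs(20, 10, "full_sib", seed = 3)$dataset$phenotypes)
  expect_identical(gen_inbred(20, 10, 0.2, seed = 4)$dataset$phenotypes,
                   gen_inbred(20, 10, 0.2, seed = 4)$dataset$phenotypes)
  a <- gen_ibd_landscape(grid = 6, N_deme = 20, m = 0.05, generations = 15,
                         L = 12, n_patches_sampled = 5, n_per_patch = 4, seed = 5)
  b <- gen_ibd_landscape(grid = 6, N_deme = 20, m = 0.05, generations = 15,
                         L = 12, n_patches_sampled = 5, n_per_patch = 4, seed = 5)
  expect_identical(a$dataset$phenotypes, b$dataset$phenotypes)
  expect_identical(a$truth$q_final, b$truth$q_final)
})

test_that("unstructured phenotypes match Hardy-Weinberg band-absence rates", {
  g <- gen_unstructured(10000, 10, seed = 6)
  obs <- colMeans(unclass(g$dataset$phenotypes) == 0L)
  expect_true(all(abs(obs - g$truth$q^2) < 0.02))
})

test_that("pseudo-populations cut from one panmictic pool show near-zero FST", {
  g <- gen_unstructured(150, 200, seed = 7, n_patches = 5)
  fst <- pairwise_fst(locus_freqs(g$dataset, per_population = TRUE))$global
  expect_lt(abs(fst), 0.01)
})

test_that("island generator honours the Balding-Nichols variance identity", {
  g <- gen_island(20, 2, 2000, 0.1, seed = 8)
  v <- apply(g$truth$q_deme, 2, stats::var)
  expected <- 0.1 * g$truth$q_ancestral * (1 - g$truth$q_ancestral)
  expect_lt(abs(mean(v) / mean(expected) - 1), 0.1)
})

test_that("the vanishing-FST limit collapses to the ancestral frequencies", {
  g <- gen_island(10, 2, 50, 1e-6, seed = 9)
  dev <- abs(sweep(g$truth$q_deme, 2, g$truth$q_ancestral))
  expect_lt(max(dev), 0.01)
})

test_that("related-pair truth records the expected kinship per class", {
  for (rel in c("unrelated", "parent_offspring", "full_sib", "self")) {
    g <- gen_related_pairs(5, 8, rel, seed = 10)
    want <- c(unrelated = 0, parent_offspring = 0.25, full_sib = 0.25,
              self = 0.5)[[rel]]
    expect_identical(unique(g$truth$pairs$kinship), want)
    expect_identical(nrow(g$dataset$phenotypes), 10L)
  }
  gs <- gen_related_pairs(10, 15, "self", seed = 11)
  ph <- unclass(gs$dataset$phenotypes)
  expect_identical(ph[gs$truth$pairs$i, ], ph[gs$truth$pairs$j, ],
                   ignore_attr = TRUE)
})

test_that("inbred generator reproduces the band-absence excess over HW", {
  g0 <- gen_inbred(4000, 10, 0, seed = 12)
  obs0 <- colMeans(unclass(g0$dataset$phenotypes) == 0L)
  expect_true(all(abs(obs0 - g0$truth$q^2) < 0.03))

  g <- gen_inbred(10000, 50, 0.3, f_shape = 5, seed = 13)
  obs <- colMeans(unclass(g$dataset$phenotypes) == 0L)
  excess <- sum(obs - g$truth$q^2)
  expected <- mean(g$truth$Fi) * sum(g$truth$q * (1 - g$truth$q))
  expect_lt(abs(excess / expected - 1), 0.05)
  expect_true(all(g$truth$Fi >= 0 & g$truth$Fi <= 1))
  expect_length(g$truth$Fi, 10000)
})

test_that("landscape generator keeps dataset invariants and layout promises", {
  g <- gen_ibd_landscape(grid = 8, N_deme = 25, m = 0.05, generations = 20,
                         L = 15, n_patches_sampled = 6, n_per_patch = 5, seed = 14)
  ds <- g$dataset
  expect_identical(unname(dim_dataset(ds)), c(30L, 15L))
  expect_identical(length(unique(ds$samples$patch_id)), 6L)
  # multiscale layout includes patch pairs at adjacent-deme distances
  D <- geo_distance_matrix(ds$samples)
  pos <- D[upper.tri(D)]
  step <- g$truth$extent_km / g$truth$grid
  expect_lte(min(pos[pos > 0]), 2.1 * step)
  # round-trip safety
  tmp <- withr::local_tempdir()
  write_dataset(ds, file.path(tmp, "g.tsv"), file.path(tmp, "s.tsv"))
  ds2 <- read_dataset(file.path(tmp, "g.tsv"), file.path(tmp, "s.tsv"))
  expect_identical(unclass(ds$phenotypes), unclass(ds2$phenotypes))
})

test_that("truth records serialize to JSON", {
  g <- gen_unstructured(10, 5, seed = 15)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_truth(g$truth, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_identical(back$generator, "gen_unstructured")
  expect_equal(back$q, g$truth$q, tolerance = 1e-12)
})
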