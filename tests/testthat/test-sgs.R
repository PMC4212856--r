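test_that("doubling distance classes reproduce the 0/10/20/40/80/160/open scheme", {
  cl <- build_distance_classes()
  expect_equal(cl$upper, c(0, 10, 20, 40, 80, 160, Inf))
  expect_identical(assign_distance_class(0, cl), 1L)     # within patch
  expect_identical(assign_distance_class(15, cl), 3L)    # (10, 20]
  expect_identical(assign_distance_class(10, cl), 2L)    # right-closed
  expect_identical(assign_distance_class(500, cl), 7L)   # open-ended
})

test_that("class means, pair counts and jackknife behave as defined", {
  g <- gen_unstructured(40, 30, seed = 101, n_patches = 8)
  K <- kinship_matrix(g$dataset)
  D <- geo_distance_matrix(g$dataset)
  ac <- suppressWarnings(autocorrelogram(K, D, n_perm = 49, seed = 5))
  n <- length(K$ids)
  expect_identical(sum(ac$n_pairs), as.integer(n * (n - 1) / 2))
  # class mean equals the arithmetic mean of its pairs' theta (direct loop)
  cls <- assign_distance_class(D[cbind(K$i, K$j)], build_distance_classes())
  for (k in which(ac$n_pairs > 0)) {
    expect_equal(ac$mean_kinship[k], mean(K$theta[cls == k]), tolerance = 1e-12)
  }
  ok <- ac$n_pairs > 0
  expect_true(all(ac$env_lo[ok] <= ac$env_hi[ok]))
})

test_that("identical per-locus components give a zero jackknife SE", {
  # two loci with equal q and identical phenotype columns: deleting either
  # locus leaves every pairwise estimate unchanged
  ph <- matrix(c(1L, 1L,
                 0L, 0L,
                 1L, 1L,
                 0L, 0L), nrow = 4, byrow = TRUE,
               dimnames = list(letters[1:4], c("L1", "L2")))
  sm <- data.frame(individual_id = letters[1:4],
                   patch_id = c("P1", "P1", "P2", "P2"),
                   lat = c(53, 53, 54, 54), lon = c(19, 19, 20, 20))
  ds <- aflp_dataset(dominant_matrix(ph), sample_table(sm))
  K <- kinship_matrix(ds, freqs = c(L1 = 0.5, L2 = 0.5), min_loci = 1)
  D <- geo_distance_matrix(ds$samples)
  ac <- suppressWarnings(autocorrelogram(K, D, n_perm = 19, seed = 1))
  expect_true(all(abs(ac$jackknife_se[ac$n_pairs > 0]) < 1e-12))
})

test_that("Sp follows its defining identity and guards the f1 = 1 pole", {
  expect_equal(sp_index(-0.0015, 0.0386), 0.0015 / 0.9614, tolerance = 1e-12)
  expect_identical(sp_index(0, 0.2), 0)
  expect_error(sp_index(-0.001, 1), class = "aflpsgs_range_error")
})

test_that("slope regression recovers an exact linear kinship-distance relation", {
  # construct kinship matrix whose theta happen to be linear in ln(d)
  g <- gen_unstructured(30, 40, seed = 7, n_patches = 10)
  K <- kinship_matrix(g$dataset)
  D <- geo_distance_matrix(g$dataset)
  d <- D[cbind(K$i, K$j)]
  K$theta <- ifelse(d > 0, 0.05 - 0.01 * log(d), 0.2)
  sp <- regression_slope_sp(K, D)
  expect_equal(sp$b1, -0.01, tolerance = 1e-9)
  expect_equal(sp$f1, 0.2, tolerance = 1e-9)
  expect_equal(sp$sp, 0.01 / 0.8, tolerance = 1e-9)
})

test_that("Mantel r is exact for proportional matrices and p is seeded", {
  set.seed(17)
  pts <- matrix(runif(20), 10, 2)
  X <- as.matrix(dist(pts)) * 100
  G <- 3 * X
  mt <- mantel_test(G, X, n_perm = 199, seed = 4, log_geo = FALSE)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_lte(mt$p, 0.01)
  mt2 <- mantel_test(G, X, n_perm = 199, seed = 4, log_geo = FALSE)
  expect_identical(mt$p, mt2$p)
  expect_true(mt$r >= -1 && mt$r <= 1)
  expect_error(mantel_test(matrix(1, 5, 5), X[1:5, 1:5], log_geo = FALSE),
               class = "aflpsgs_insufficient_data")
})

test_that("Mantel statistic agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(23)
  pts <- matrix(runif(24), 12, 2)
  X <- as.matrix(dist(pts)) + 0.1
  G <- X + matrix(rnorm(144, sd = 0.3), 12, 12)
  G <- (G + t(G)) / 2; diag(G) <- 0
  ours <- mantel_test(G, X, n_perm = 999, seed = 9, log_geo = FALSE)
  ref <- vegan::mantel(G, X, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
  expect_lt(abs(ours$p - ref$signif), 0.05)
})

test_that("structure detection combines envelope and slope significance", {
  acorr <- data.frame(mean_kinship = c(0.3, 0), env_hi = c(0.01, 0.01))
  spres <- list(b1 = -0.02, se_b1 = 0.004)
  expect_true(sgs_detected(acorr, spres))
  expect_false(sgs_detected(acorr, list(b1 = -0.002, se_b1 = 0.004)))
  expect_false(sgs_detected(acorr, list(b1 = 0.02, se_b1 = 0.004)))
  acorr$env_hi[1] <- 0.5
  expect_false(sgs_detected(acorr, spres))
})
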