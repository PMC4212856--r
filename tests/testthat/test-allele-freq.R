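test_that("moment-matched prior inverts the beta mean/variance equations", {
  # m = 0.5, v = 0.05 has the hand solution a = b = 2
  pr <- aflpsgs:::.moment_prior(0.5 + sqrt(0.025) * c(-1, 1))
  expect_equal(pr$a, 2, tolerance = 1e-10)
  expect_equal(pr$b, 2, tolerance = 1e-10)

  set.seed(11)
  for (rep in 1:20) {
    x <- runif(30, 0.05, 0.95)
    pr <- aflpsgs:::.moment_prior(x)
    if (pr$source == "moment_matched") {
      m <- pr$a / (pr$a + pr$b)
      v <- pr$a * pr$b / ((pr$a + pr$b)^2 * (pr$a + pr$b + 1))
      expect_equal(m, mean(x), tolerance = 1e-10)
      expect_equal(v, var(x), tolerance = 1e-10)
    }
  }
})

test_that("degenerate across-locus variance falls back to the uniform prior", {
  pr <- aflpsgs:::.moment_prior(rep(0.4, 10))
  expect_identical(c(pr$a, pr$b), c(1, 1))
  expect_identical(pr$source, "uniform")
  # incompatible variance (v >= m(1-m)) also falls back
  pr2 <- aflpsgs:::.moment_prior(c(0.001, 0.999, 0.001, 0.999))
  expect_identical(pr2$source, "uniform")
})

test_that("prior fitting needs at least two loci", {
  ph <- matrix(c(1L, 0L, 1L), ncol = 1, dimnames = list(c("a", "b", "c"), "L1"))
  ds <- aflp_dataset(dominant_matrix(ph),
                     sample_table(make_samples_df(c("a", "b", "c"))))
  expect_error(fit_phenotype_prior(ds), class = "aflpsgs_insufficient_data")
})

test_that("posterior-mean-sqrt estimator matches its closed forms", {
  expect_equal(estimate_allele_freq(1, 1, prior_spec(1, 1)), 0.8,
               tolerance = 1e-12)
  expect_equal(estimate_allele_freq(100, 100, prior_spec(1, 1)), 101 / 101.5,
               tolerance = 1e-12)
  # quadrature agreement on a handful of random parameter sets
  set.seed(31)
  for (rep in 1:10) {
    a <- runif(1, 0.2, 6); b <- runif(1, 0.2, 6)
    n <- sample(2:300, 1); n0 <- sample(0:n, 1)
    expect_equal(estimate_allele_freq(n, n0, prior_spec(a, b)),
                 quad_mean_sqrt_beta(a + n0, b + n - n0), tolerance = 1e-8)
  }
})

test_that("estimator is monotone in the band-absent count and guards n = 0", {
  q <- estimate_allele_freq(rep(50, 51), 0:50, prior_spec(2, 3))
  expect_true(all(diff(q) > 0))
  expect_true(all(q > 0 & q < 1))
  expect_error(estimate_allele_freq(0, 0, prior_spec(1, 1)),
               class = "aflpsgs_insufficient_data")
  expect_error(estimate_allele_freq(5, 6, prior_spec(1, 1)),
               class = "aflpsgs_range_error")
})

test_that("diversity reports PLP by the minor-allele criterion and bounded Hj", {
  # the counting rule itself: q in {0.5, 0.04, 0.06} at the 5% criterion
  maf <- pmin(c(0.5, 0.04, 0.06), 1 - c(0.5, 0.04, 0.06))
  expect_equal(mean(maf >= 0.05), 2 / 3)

  set.seed(5)
  n <- 200
  qs <- c(0.5, 0.04, 0.96)
  ph <- sapply(qs, function(q) rbinom(n, 1, 1 - q^2))
  colnames(ph) <- c("La", "Lb", "Lc"); rownames(ph) <- sprintf("i%03d", 1:n)
  ds <- aflp_dataset(dominant_matrix(ph),
                     sample_table(make_samples_df(rownames(ph))))
  div <- diversity(ds, prior = prior_spec(1, 1), maf_threshold = 0.05)
  # PLP applied to the estimated frequencies matches the counting rule
  fr <- locus_freqs(ds, prior = prior_spec(1, 1), per_population = TRUE)
  expect_equal(div$PLP, mean(pmin(fr$q, 1 - fr$q) >= 0.05), tolerance = 1e-12)
  # the near-fixed band-presence locus (q ~ 0.96) is not polymorphic
  expect_lt(pmin(fr$q, 1 - fr$q)[3], 0.05)
  expect_true(div$Hj > 0 && div$Hj < 0.5 * 2 * n / (2 * n - 1))
  expect_true(div$Hj_se > 0)
  # q -> 0 sends per-locus gene diversity to 0; q = 0.5 maximizes it
  hj <- 2 * fr$q * (1 - fr$q)
  expect_true(hj[1] > hj[2] && hj[1] > hj[3])
})

test_that("Hj is invariant to locus relabeling", {
  g <- gen_unstructured(60, 30, seed = 77)
  ds <- g$dataset
  perm <- sample(ncol(ds$phenotypes))
  ds2 <- aflp_dataset(dominant_matrix(unclass(ds$phenotypes)[, perm]), ds$samples)
  expect_equal(diversity(ds)$Hj, diversity(ds2)$Hj, tolerance = 1e-12)
})

test_that("FST is zero for identical populations and near one for fixed differences", {
  loci <- sprintf("L%d", 1:20)
  q <- runif(20, 0.2, 0.8)
  same <- rbind(
    data.frame(locus_id = loci, population_id = "A", q = q, n = 50, n_absent = 0),
    data.frame(locus_id = loci, population_id = "B", q = q, n = 50, n_absent = 0))
  fs <- pairwise_fst(same)
  expect_equal(fs$fst["A", "B"], 0)   # negative moment estimate truncated at 0
  expect_equal(fs$linearized["A", "B"], 0)

  fixed <- rbind(
    data.frame(locus_id = loci, population_id = "A", q = 0.001, n = 1e6, n_absent = 0),
    data.frame(locus_id = loci, population_id = "B", q = 0.999, n = 1e6, n_absent = 0))
  ff <- pairwise_fst(fixed)
  expect_gt(ff$fst["A", "B"], 0.95)
})

test_that("monomorphic population pairs give a missing FST with a warning", {
  loci <- sprintf("L%d", 1:5)
  mono <- rbind(
    data.frame(locus_id = loci, population_id = "A", q = 0, n = 10, n_absent = 0),
    data.frame(locus_id = loci, population_id = "B", q = 0, n = 10, n_absent = 0))
  expect_warning(fm <- pairwise_fst(mono), "undefined")
  expect_true(is.na(fm$fst["A", "B"]))
})

test_that("linearization is the identity at 0 and strictly increasing", {
  fst <- seq(0, 0.9, by = 0.1)
  lin <- fst / (1 - fst)
  expect_identical(lin[1], 0)
  expect_true(all(diff(lin) > 0))
})
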