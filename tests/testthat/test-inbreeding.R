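test_that("band-absence probability follows q^2 + Fi q(1-q)", {
  expect_equal(phenotype_prob(0.5, 0), 0.25)
  expect_equal(phenotype_prob(0.5, 1), 0.5)
  set.seed(2)
  q <- runif(20); Fi <- runif(20)
  p0 <- phenotype_prob(q, Fi)
  expect_true(all(p0 >= 0 & p0 <= 1))
  expect_equal(p0 + (1 - p0), rep(1, 20))
  expect_error(phenotype_prob(1.2, 0), class = "aflpsgs_range_error")
})

test_that("model specification validates its invariants", {
  expect_error(inbreeding_model(alpha = 0), class = "aflpsgs_range_error")
  expect_error(inbreeding_model(n_steps = 100, burn_in = 100),
               class = "aflpsgs_range_error")
  expect_error(inbreeding_model(n_steps = 109, burn_in = 100, thin = 10),
               class = "aflpsgs_range_error")
})

test_that("identical seed and spec give a bit-identical chain", {
  g <- gen_inbred(25, 15, 0.2, seed = 8)
  spec <- inbreeding_model(n_steps = 2000, burn_in = 200, thin = 5, seed = 99)
  f1 <- run_chain(g$dataset, spec)
  f2 <- run_chain(g$dataset, spec)
  expect_identical(f1$F_draws, f2$F_draws)
  expect_identical(f1$logL_draws, f2$logL_draws)
})

test_that("constant likelihood recovers the beta prior exactly", {
  # 0 loci: the Fi marginal must be Beta(alpha, beta); single individual so
  # the recorded F trace is that marginal
  ds1 <- make_empty_locus_dataset(1)
  fit <- run_chain(ds1, inbreeding_model(alpha = 2, beta = 5, n_steps = 310000,
                                         burn_in = 10000, thin = 30, seed = 9))
  expect_length(fit$F_draws, 10000)
  ks <- stats::ks.test(fit$F_draws, "pbeta", 2, 5)
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("summaries are finite, bounded and internally consistent", {
  g <- gen_inbred(30, 20, 0.2, seed = 12)
  fit <- run_chain(g$dataset, inbreeding_model(n_steps = 4000, burn_in = 500,
                                               thin = 5, seed = 13))
  expect_true(all(is.finite(c(fit$F_mean, fit$F_ci, fit$logL_mean, fit$logL_sd))))
  expect_true(fit$F_mean >= 0 && fit$F_mean <= 1)
  expect_true(all(fit$Fi$Fi_mean >= 0 & fit$Fi$Fi_mean <= 1))
  expect_true(fit$F_ci[1] <= fit$F_median && fit$F_median <= fit$F_ci[2])
  acc <- fit$acceptance[c("q", "Fi", "ridge")]
  expect_true(all(acc > 0 & acc < 1))
})

test_that("posterior mean F rises with the band-absent fraction", {
  # single-locus gradients, everything else fixed
  n <- 60
  fmean <- sapply(c(5, 30, 55), function(n0) {
    ph <- matrix(c(rep(0L, n0), rep(1L, n - n0)), ncol = 1,
                 dimnames = list(sprintf("i%02d", 1:n), "L1"))
    ds <- aflp_dataset(dominant_matrix(ph),
                       sample_table(make_samples_df(rownames(ph))))
    run_chain(ds, inbreeding_model(n_steps = 20000, burn_in = 2000, thin = 10,
                                   seed = 41))$F_mean
  })
  expect_true(all(diff(fmean) > 0))
})

test_that("hierarchical mode updates the shapes and keeps F honest", {
  g <- gen_inbred(40, 30, 0.2, seed = 14)
  fit <- run_chain(g$dataset,
                   inbreeding_model(n_steps = 5000, burn_in = 1000, thin = 5,
                                    estimate_shapes = TRUE, seed = 15))
  expect_gt(stats::sd(fit$a_draws), 0)
  expect_gt(stats::sd(fit$b_draws), 0)
  expect_true(fit$acceptance["shapes"] > 0 && fit$acceptance["shapes"] < 1)
  expect_true(all(fit$F_draws >= 0 & fit$F_draws <= 1))
})

test_that("prior sensitivity tabulates the three default priors", {
  g <- gen_inbred(25, 15, 0.2, seed = 16)
  ps <- prior_sensitivity(g$dataset, n_steps = 2000, burn_in = 300, thin = 5,
                          seed = 17)
  expect_identical(nrow(ps), 3L)
  expect_equal(ps$alpha, c(0.1, 1, 5))
  expect_equal(ps$beta, c(0.1, 1, 5))
  expect_true(all(is.finite(ps$F)) && all(is.finite(ps$logL_mean)))
  expect_type(attr(ps, "disagreement"), "logical")
})

test_that("prior-mean pull dominates a fixed-prior fit on informative data", {
  # fixed a = b priors share the prior mean 0.5; with the mean-F direction
  # unidentified the three posterior means agree closely
  g <- gen_inbred(60, 40, 0.15, seed = 18)
  ps <- prior_sensitivity(g$dataset, n_steps = 8000, burn_in = 1000, thin = 5,
                          seed = 19)
  d <- outer(ps$F, ps$F, "-")
  expect_lt(max(abs(d)), 0.03)
})
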