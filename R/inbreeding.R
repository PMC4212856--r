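#' Probability of band absence under partial inbreeding
#'
#' For a dominant biallelic locus with null-allele frequency q and an
#' individual inbreeding coefficient Fi (the probability that the two
#' alleles are identical by descent), the probability of the band-absent
#' (null homozygote) phenotype is P(Y = 0) = q^2 + Fi q(1 - q).
#'
#' @param q null-allele frequency in \[0, 1\] (vectorized).
#' @param Fi individual inbreeding coefficient in \[0, 1\].
#' @return numeric probability of band absence.
#' @export
phenotype_prob <- function(q, Fi) {
  .assert(all(q >= 0 & q <= 1) && all(Fi >= 0 & Fi <= 1),
          "q and Fi must lie in [0, 1]", "aflpsgs_range_error")
  q^2 + Fi * q * (1 - q)
}

#' Specify the inbreeding MCMC model and run settings
#'
#' Individual inbreeding coefficients Fi follow an iid Beta(alpha, beta)
#' prior (prior mean F = alpha/(alpha + beta)); locus null-allele
#' frequencies carry flat priors.  Sampling is Metropolis-within-Gibbs
#' with random-walk proposals on the logit scale, adaptively tuned to a
#' 20-45% acceptance rate during burn-in and frozen afterwards.
#'
#' With `estimate_shapes = TRUE` the shapes become parameters of a
#' hierarchical model — updated by Metropolis on the log scale under weak
#' lognormal hyperpriors — and `alpha`, `beta` act as chain
#' initializations.  This is the mode to use for estimating the average
#' inbreeding coefficient itself: with dominant data from a single
#' population the likelihood is nearly flat along a ridge trading mean
#' inbreeding against the allele frequencies, so under a *fixed* iid beta
#' prior the posterior of F stays at the prior mean a/(a+b) regardless of
#' the data.  The sampler also performs a joint "ridge" move (a common
#' logit shift of all Fi with compensating per-locus frequency
#' adjustments) so that chains traverse this ridge.
#'
#' @param alpha,beta positive prior shapes (initial values when
#'   `estimate_shapes`).
#' @param n_steps chain length in sweeps (default 100000).
#' @param burn_in discarded initial sweeps (default 10000).
#' @param thin record every `thin`-th post-burn-in sweep.
#' @param prop_q,prop_f,prop_ridge,prop_shape initial proposal s.d. on the
#'   logit/log scales.
#' @param estimate_shapes treat (alpha, beta) as estimated hyperparameters.
#' @param hyper_mu,hyper_sd lognormal hyperprior on each shape (log-scale
#'   mean and s.d.), used only when `estimate_shapes`.
#' @param seed optional integer seed.
#' @return list of class `inbreeding_model_spec`.
#' @export
inbreeding_model <- function(alpha = 1, beta = 1, n_steps = 100000,
                             burn_in = 10000, thin = 10,
                             prop_q = 0.5, prop_f = 1, prop_ridge = 0.2,
                             prop_shape = 0.4, estimate_shapes = FALSE,
                             hyper_mu = 0, hyper_sd = 2, seed = NULL) {
  .assert(alpha > 0 && beta > 0, "alpha and beta must be positive",
          "aflpsgs_range_error")
  .assert(.is_count(n_steps) && .is_count(burn_in) && burn_in < n_steps,
          "need burn_in < n_steps", "aflpsgs_range_error")
  .assert(.is_count(thin) && thin >= 1, "thin must be a positive integer",
          "aflpsgs_range_error")
  .assert(n_steps - burn_in >= thin,
          "chain too short: no post-burn-in record would be kept",
          "aflpsgs_range_error")
  structure(list(alpha = alpha, beta = beta, n_steps = as.integer(n_steps),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 prop_q = prop_q, prop_f = prop_f, prop_ridge = prop_ridge,
                 prop_shape = prop_shape,
                 estimate_shapes = isTRUE(estimate_shapes),
                 hyper_mu = hyper_mu, hyper_sd = hyper_sd, seed = seed),
            class = "inbreeding_model_spec")
}

#' Run the inbreeding MCMC chain
#'
#' Jointly samples locus null-allele frequencies and individual inbreeding
#' coefficients from dominant phenotype data.  Missing phenotypes are
#' skipped in the likelihood.  The average inbreeding coefficient F is
#' recorded per kept sweep as the mean of the current Fi; posterior
#' summaries come from the post-burn-in, thinned records.
#'
#' @param ds an `aflp_dataset` (a zero-locus dataset recovers the prior).
#' @param spec an [inbreeding_model()] specification.
#' @return object of class `inbreeding_fit` with posterior mean of F, 95%
#'   credible interval, per-individual Fi summaries, chain draws of F and
#'   log-likelihood, and acceptance rates.
#' @export
run_chain <- function(ds, spec = inbreeding_model()) {
  .assert(inherits(spec, "inbreeding_model_spec"),
          "spec must come from inbreeding_model()", "aflpsgs_format_error")
  Y <- unclass(ds$phenotypes)
  n <- nrow(Y); L <- ncol(Y)
  .assert(n >= 1, "need at least 1 individual", "aflpsgs_insufficient_data")
  storage.mode(Y) <- "integer"

  res <- .with_seed(spec$seed, {
    n_scored <- colSums(!is.na(Y))
    n_absent <- colSums(Y == 0L, na.rm = TRUE)
    attempt <- 0
    repeat {
      attempt <- attempt + 1
      q0 <- sqrt((n_absent + 0.5) / (n_scored + 1))
      q0 <- pmin(pmax(q0, 0.02), 0.98)
      if (attempt > 1) q0 <- pmin(pmax(stats::runif(L, 0.05, 0.95), 0.02), 0.98)
      f0 <- pmin(pmax(stats::rbeta(n, spec$alpha, spec$beta), 0.01), 0.99)
      ll0 <- sum(ifelse(is.na(Y), 0,
                        ifelse(Y == 0L,
                               log(outer(f0, q0, function(f, q) q^2 + f * q * (1 - q))),
                               log1p(-outer(f0, q0, function(f, q) q^2 + f * q * (1 - q))))))
      if (is.finite(ll0)) break
      if (attempt >= 10) .err("non-finite likelihood at initialization",
                              "aflpsgs_numeric_error")
    }
    inbreeding_chain_cpp(Y, spec$alpha, spec$beta, spec$n_steps, spec$burn_in,
                         spec$thin, spec$prop_q, spec$prop_f, spec$prop_ridge,
                         spec$prop_shape, q0, f0, spec$estimate_shapes,
                         spec$hyper_mu, spec$hyper_sd)
  })

  nr <- res$n_records
  Fd <- res$F_draws[seq_len(nr)]
  ll <- res$logL_draws[seq_len(nr)]
  ci <- stats::quantile(Fd, c(0.025, 0.975), names = FALSE)
  fi_mean <- res$fi_sum / nr
  fi_sd <- sqrt(pmax(res$fi_sumsq / nr - fi_mean^2, 0))
  structure(list(
    F_mean = mean(Fd), F_median = stats::median(Fd),
    F_ci = c(lower = ci[1], upper = ci[2]),
    Fi = data.frame(individual_id = rownames(Y), Fi_mean = fi_mean,
                    Fi_sd = fi_sd, stringsAsFactors = FALSE),
    q_mean = if (L > 0) stats::setNames(res$q_sum / nr, colnames(Y)) else numeric(0),
    logL_mean = mean(ll), logL_sd = stats::sd(ll),
    F_draws = Fd, logL_draws = ll,
    a_draws = res$a_draws[seq_len(nr)], b_draws = res$b_draws[seq_len(nr)],
    acceptance = c(q = res$acc_rate_q, Fi = res$acc_rate_f,
                   ridge = res$acc_rate_ridge, shapes = res$acc_rate_shapes),
    proposal_widths = c(q = res$w_q, Fi = res$w_f, ridge = res$w_r,
                        shapes = res$w_s),
    spec = spec, n_individuals = n, n_loci = L),
    class = "inbreeding_fit")
}

#' @export
print.inbreeding_fit <- function(x, ...) {
  cat(sprintf("Inbreeding MCMC (Beta(%.3g, %.3g) prior on Fi): %d individuals, %d loci\n",
              x$spec$alpha, x$spec$beta, x$n_individuals, x$n_loci))
  cat(sprintf("  F = %.4f, 95%% CrI [%.4f, %.4f]\n",
              x$F_mean, x$F_ci[1], x$F_ci[2]))
  cat(sprintf("  mean logL = %.2f (sd %.2f); acceptance q %.2f, Fi %.2f\n",
              x$logL_mean, x$logL_sd, x$acceptance["q"], x$acceptance["Fi"]))
  invisible(x)
}

#' @export
summary.inbreeding_fit <- function(object, ...) {
  out <- list(F_mean = object$F_mean, F_median = object$F_median,
              F_ci = object$F_ci,
              Fi = object$Fi, logL_mean = object$logL_mean,
              logL_sd = object$logL_sd, acceptance = object$acceptance,
              n_records = length(object$F_draws))
  class(out) <- "summary.inbreeding_fit"
  out
}

#' @export
print.summary.inbreeding_fit <- function(x, ...) {
  cat(sprintf("F = %.4f (median %.4f), 95%% CrI [%.4f, %.4f], %d records\n",
              x$F_mean, x$F_median, x$F_ci[1], x$F_ci[2], x$n_records))
  cat(sprintf("Fi range: [%.3f, %.3f]\n", min(x$Fi$Fi_mean), max(x$Fi$Fi_mean)))
  invisible(x)
}

#' Prior-sensitivity harness for the inbreeding estimate
#'
#' Re-runs the chain under several beta prior shapes (default a = b in
#' {0.1, 1, 5}: the same prior mean F = 0.5 with very different variances)
#' and tabulates F, its credible interval and the mean log-likelihood per
#' prior.  Disjoint credible intervals between any two priors are flagged
#' as disagreement.
#'
#' @param ds an `aflp_dataset`.
#' @param shapes list of `c(alpha, beta)` pairs.
#' @param ... further arguments to [inbreeding_model()] (`n_steps`,
#'   `seed`, ...).
#' @return data frame of class `prior_sensitivity` with one row per prior;
#'   `attr(, "disagreement")` is `TRUE` when any two CrIs are disjoint;
#'   the fits are kept in `attr(, "fits")`.
#' @export
prior_sensitivity <- function(ds, shapes = list(c(0.1, 0.1), c(1, 1), c(5, 5)),
                              ...) {
  .assert(length(shapes) >= 2, "need at least 2 prior sets",
          "aflpsgs_insufficient_data")
  fits <- lapply(shapes, function(s) {
    run_chain(ds, inbreeding_model(alpha = s[1], beta = s[2], ...))
  })
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(alpha = f$spec$alpha, beta = f$spec$beta,
               F = f$F_mean, ci_lower = f$F_ci[1], ci_upper = f$F_ci[2],
               logL_mean = f$logL_mean, logL_sd = f$logL_sd)
  }))
  rownames(out) <- NULL
  disjoint <- FALSE
  for (a in seq_len(nrow(out) - 1)) for (b in (a + 1):nrow(out)) {
    if (out$ci_lower[a] > out$ci_upper[b] || out$ci_lower[b] > out$ci_upper[a])
      disjoint <- TRUE
  }
  attr(out, "disagreement") <- disjoint
  attr(out, "fits") <- fits
  class(out) <- c("prior_sensitivity", "data.frame")
  out
}
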