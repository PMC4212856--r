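#' Simulate a neutral (He, FST) null cloud under an island model
#'
#' FDist-style neutrality scan for dominant markers: each iteration
#' simulates one neutral biallelic locus.  The ancestral band-absence
#' phenotype frequency is drawn from the fitted beta prior and converted
#' to the allele scale (q = sqrt(x)); per-deme null-allele frequencies are
#' drawn from the Balding-Nichols beta law
#' Beta(q(1-FST)/FST, (1-q)(1-FST)/FST); dominant phenotypes are sampled
#' per deme at the observed sample sizes; allele frequencies are then
#' re-estimated with [estimate_allele_freq()] and summarized with the same
#' (He, FST) estimators applied to the observed data.  Since dominant data
#' are intrinsically biallelic, this biallelic draw stands in for the
#' infinite-alleles simulator of codominant scans.
#'
#' @param target_fst calibration FST in (0, 1) (typically the trimmed mean
#'   of the observed per-locus FST values).
#' @param sample_sizes per-sampled-deme counts of individuals.
#' @param n_demes nominal island-model deme number (the Balding-Nichols
#'   draw is its large-deme-number limit; kept for reporting).
#' @param iterations number of simulated loci (default 50000).
#' @param prior a [prior_spec()] for the ancestral frequency draw and the
#'   re-estimation step.
#' @param seed optional integer seed.
#' @return data frame of class `null_cloud` with columns `He`, `fst`.
#' @export
simulate_null_cloud <- function(target_fst, sample_sizes, n_demes = 100,
                                iterations = 50000, prior = prior_spec(),
                                seed = NULL) {
  .assert(is.numeric(target_fst) && length(target_fst) == 1 &&
          target_fst > 0 && target_fst < 1,
          "target_fst must lie in (0, 1)", "aflpsgs_range_error")
  .assert(length(sample_sizes) >= 2 && all(sample_sizes >= 1),
          "need sample sizes for at least 2 demes", "aflpsgs_insufficient_data")
  d <- length(sample_sizes)
  it <- as.integer(iterations)
  draw <- function(fst_param, niter) {
    x_anc <- stats::rbeta(niter, prior$a, prior$b)
    q_anc <- pmin(pmax(sqrt(x_anc), 1e-4), 1 - 1e-4)
    sh1 <- q_anc * (1 - fst_param) / fst_param
    sh2 <- (1 - q_anc) * (1 - fst_param) / fst_param
    qd <- matrix(stats::rbeta(niter * d, rep(sh1, d), rep(sh2, d)), niter, d)
    nmat <- matrix(sample_sizes, niter, d, byrow = TRUE)
    n0 <- matrix(stats::rbinom(niter * d, size = as.vector(nmat),
                               prob = as.vector(qd)^2), niter, d)
    .dominant_locus_stats(nmat, n0, prior)
  }
  out <- .with_seed(seed, {
    # at small per-deme sizes the estimated per-locus FST is biased toward
    # zero; a pilot draw measures the multiplicative bias of the
    # true-FST -> estimate map and the final cloud is simulated at the
    # inverted parameter, centring the cloud's trimmed-mean FST on the
    # requested target (which is how the scan calibrates to the data)
    pilot <- draw(target_fst, min(3000L, it))
    bias <- mean(pilot$fst[is.finite(pilot$fst)], trim = 0.15) / target_fst
    bias <- min(max(bias, 0.1), 2)
    t_star <- min(max(target_fst / bias, 1e-4), 0.99)
    res <- draw(t_star, it)
    attr(res, "internal_fst") <- t_star
    res
  })
  t_star <- attr(out, "internal_fst")
  out <- out[is.finite(out$fst), ]
  rownames(out) <- NULL
  attr(out, "target_fst") <- target_fst
  attr(out, "internal_fst") <- t_star
  attr(out, "n_demes") <- n_demes
  attr(out, "sample_sizes") <- sample_sizes
  class(out) <- c("null_cloud", "data.frame")
  out
}

#' @export
print.null_cloud <- function(x, ...) {
  cat(sprintf("Neutral null cloud: %d simulated loci, target FST %.4f, %d sampled demes\n",
              nrow(x), attr(x, "target_fst"), length(attr(x, "sample_sizes"))))
  cat(sprintf("  trimmed-mean simulated FST = %.4f\n", mean(x$fst, trim = 0.15)))
  invisible(x)
}

#' Classify loci against a neutral null cloud
#'
#' Each observed locus' FST is ranked among the `k_neighbors` simulated
#' loci nearest in He (a bin-free empirical quantile conditional on He).
#' Loci above the `upper` quantile are flagged as candidates for
#' directional selection, below `lower` for stabilizing/balancing
#' selection.  Monomorphic observed loci (He ~ 0) are excluded before
#' classification.
#'
#' @param observed data frame with columns `locus_id`, `He`, `fst` (see
#'   [scan_outliers()] for the end-to-end wrapper).
#' @param cloud a [simulate_null_cloud()] result.
#' @param upper,lower quantile cutoffs (defaults 0.99 and 0.01).
#' @param k_neighbors neighborhood size for the conditional quantile.
#' @return data frame of class `neutrality_result`: `locus_id`, `He`,
#'   `fst`, `quantile`, `class`; removed (non-neutral) locus ids in
#'   `attr(, "removed_loci")`.
#' @export
classify_loci <- function(observed, cloud, upper = 0.99, lower = 0.01,
                          k_neighbors = 2000) {
  .assert(nrow(cloud) > 0, "empty null cloud", "aflpsgs_insufficient_data")
  .assert(all(c("locus_id", "He", "fst") %in% names(observed)),
          "observed table needs locus_id, He, fst", "aflpsgs_format_error")
  k <- min(as.integer(k_neighbors), nrow(cloud))
  mono <- !is.finite(observed$fst) | !is.finite(observed$He) | observed$He < 1e-8
  qt <- rep(NA_real_, nrow(observed))
  cl <- rep(NA_character_, nrow(observed))
  for (idx in which(!mono)) {
    nb <- order(abs(cloud$He - observed$He[idx]))[seq_len(k)]
    f <- cloud$fst[nb]
    qt[idx] <- (sum(f < observed$fst[idx]) + 0.5 * sum(f == observed$fst[idx]) + 0.5) /
      (k + 1)
    cl[idx] <- if (qt[idx] > upper) "directional"
               else if (qt[idx] < lower) "stabilizing"
               else "neutral"
  }
  out <- data.frame(locus_id = observed$locus_id, He = observed$He,
                    fst = observed$fst, quantile = qt, class = cl,
                    stringsAsFactors = FALSE)
  attr(out, "removed_loci") <- out$locus_id[!is.na(cl) & cl != "neutral"]
  attr(out, "cutoffs") <- c(lower = lower, upper = upper)
  class(out) <- c("neutrality_result", "data.frame")
  out
}

#' @export
print.neutrality_result <- function(x, ...) {
  tab <- table(factor(x$class, levels = c("neutral", "directional", "stabilizing")))
  cat(sprintf("FST-outlier scan over %d loci: %d neutral, %d directional, %d stabilizing, %d excluded\n",
              nrow(x), tab["neutral"], tab["directional"], tab["stabilizing"],
              sum(is.na(x$class))))
  invisible(x)
}

#' End-to-end FST-outlier neutrality scan of a dataset
#'
#' Computes per-locus observed (He, FST) across patches, calibrates the
#' null cloud to the trimmed mean (central 70%) of the observed per-locus
#' FST in a single pass, simulates the cloud and classifies every locus.
#'
#' @param ds an `aflp_dataset` (patches are the demes).
#' @param prior optional [prior_spec()]; default moment-matched on the
#'   pooled sample.
#' @param iterations,upper,lower,k_neighbors,n_demes,seed passed to
#'   [simulate_null_cloud()] / [classify_loci()].
#' @return a `neutrality_result` with the cloud in `attr(, "cloud")`.
#' @export
scan_outliers <- function(ds, prior = NULL, iterations = 50000, upper = 0.99,
                          lower = 0.01, k_neighbors = 2000, n_demes = 100,
                          seed = NULL) {
  if (is.null(prior)) {
    prior <- tryCatch(fit_phenotype_prior(ds),
                      aflpsgs_insufficient_data = function(e) prior_spec(1, 1))
  }
  # per-patch counts; the SAME prior is used for the observed loci and for
  # the simulated cloud so both sides share the estimator's shrinkage
  Y <- unclass(ds$phenotypes)
  pops <- unique(ds$samples$patch_id)
  nmat <- sapply(pops, function(p) colSums(!is.na(Y[ds$samples$patch_id == p, ,
                                                    drop = FALSE])))
  n0mat <- sapply(pops, function(p) colSums(Y[ds$samples$patch_id == p, ,
                                              drop = FALSE] == 0L, na.rm = TRUE))
  st <- .dominant_locus_stats(pmax(nmat, 1), n0mat, prior)
  st$fst[apply(nmat == 0, 1, any)] <- NA_real_
  obs <- data.frame(locus_id = colnames(Y), He = st$He, fst = st$fst,
                    stringsAsFactors = FALSE)
  sizes <- as.integer(table(ds$samples$patch_id))
  tf <- mean(obs$fst[is.finite(obs$fst)], trim = 0.15)
  tf <- min(max(tf, 1e-3), 0.999)
  cloud <- simulate_null_cloud(tf, sizes, n_demes = n_demes,
                               iterations = iterations, prior = prior,
                               seed = seed)
  res <- classify_loci(obs, cloud, upper = upper, lower = lower,
                       k_neighbors = k_neighbors)
  attr(res, "cloud") <- cloud
  attr(res, "target_fst") <- tf
  res
}
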