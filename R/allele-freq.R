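#' Moment-matched beta prior for band-absence phenotype frequencies
#'
#' Dominant markers hide heterozygotes, so allele frequencies must be
#' inferred from the band-absence phenotype frequency x = q^2 (with q the
#' null-allele frequency).  Rather than a flat prior, a beta prior on x is
#' fitted across loci by the method of moments: with across-locus mean m
#' and variance v of the observed band-absence proportions,
#' a = m(m(1-m)/v - 1), b = (1-m)(m(1-m)/v - 1).  When the variance is
#' degenerate (v ~ 0) or incompatible with a beta law (v >= m(1-m)) the
#' prior falls back to uniform.
#'
#' @param ds an `aflp_dataset` (typically one population).
#' @return list of class `prior_spec` with fields `a`, `b`, `source`.
#' @export
fit_phenotype_prior <- function(ds) {
  Y <- ds$phenotypes
  .assert(ncol(Y) >= 2, "need at least 2 loci to fit a prior",
          "aflpsgs_insufficient_data")
  .moment_prior(colMeans(Y == 0L, na.rm = TRUE))
}

.moment_prior <- function(x) {
  x <- x[is.finite(x)]
  .assert(length(x) >= 2, "need at least 2 scored loci to fit a prior",
          "aflpsgs_insufficient_data")
  m <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v) || v < 1e-10 || m <= 0 || m >= 1 || v >= m * (1 - m)) {
    return(prior_spec(1, 1, source = "uniform"))
  }
  k <- m * (1 - m) / v - 1
  prior_spec(m * k, (1 - m) * k, source = "moment_matched")
}

#' Build a prior specification
#' @param a,b positive beta shape parameters.
#' @param source how the prior was obtained (`"uniform"` or
#'   `"moment_matched"`).
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(a = 1, b = 1, source = "uniform") {
  .assert(is.numeric(a) && is.numeric(b) && length(a) == 1 && length(b) == 1 &&
          is.finite(a) && is.finite(b) && a > 0 && b > 0,
          "prior shapes must be finite and positive", "aflpsgs_range_error")
  structure(list(a = a, b = b, source = source), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Beta(%.4g, %.4g) prior on the band-absence phenotype frequency (%s)\n",
              x$a, x$b, x$source))
  invisible(x)
}

#' Bayesian null-allele frequency estimate from dominant phenotypes
#'
#' With a Beta(a, b) prior on the band-absence phenotype frequency x and
#' `n_absent` band-absent individuals out of `n`, the posterior of x is
#' Beta(a + n_absent, b + n - n_absent).  Under Hardy-Weinberg x = q^2, so
#' the null-allele frequency is estimated as the posterior mean of sqrt(x):
#' q = B(a + n_absent + 1/2, b + n - n_absent) / B(a + n_absent, b + n - n_absent).
#'
#' Vectorized over `n` and `n_absent`.
#'
#' @param n non-missing sample sizes (individuals), `n >= 1`.
#' @param n_absent counts of band-absent phenotypes, `0 <= n_absent <= n`.
#' @param prior a [prior_spec()].
#' @return numeric vector of estimated null-allele frequencies in (0, 1).
#' @export
estimate_allele_freq <- function(n, n_absent, prior = prior_spec()) {
  .assert(inherits(prior, "prior_spec"), "prior must be a prior_spec",
          "aflpsgs_format_error")
  .assert(length(n) == length(n_absent) || length(n) == 1 || length(n_absent) == 1,
          "n and n_absent lengths incompatible", "aflpsgs_format_error")
  nn <- pmax(length(n), length(n_absent))
  n <- rep_len(n, nn); n_absent <- rep_len(n_absent, nn)
  .assert(all(n >= 1), "n = 0: no data to estimate from", "aflpsgs_insufficient_data")
  .assert(all(n_absent >= 0 & n_absent <= n), "need 0 <= n_absent <= n",
          "aflpsgs_range_error")
  a1 <- prior$a + n_absent
  b1 <- prior$b + n - n_absent
  exp(lbeta(a1 + 0.5, b1) - lbeta(a1, b1))
}

#' Per-locus, per-population null-allele frequency estimates
#'
#' Applies [estimate_allele_freq()] locus-by-locus, either within each
#' patch/population or on the pooled sample.  Unless supplied, the beta
#' prior is moment-matched per population ([fit_phenotype_prior()]).
#'
#' @param ds an `aflp_dataset`.
#' @param prior optional [prior_spec()] used for all populations.
#' @param per_population estimate within patches (`TRUE`, default) or on
#'   the pooled sample (`FALSE`).
#' @return data frame of class `locus_freqs`: `locus_id`, `population_id`,
#'   `q`, `n`, `n_absent`.
#' @export
locus_freqs <- function(ds, prior = NULL, per_population = TRUE) {
  Y <- ds$phenotypes
  pops <- if (per_population) unique(ds$samples$patch_id) else "pooled"
  out <- vector("list", length(pops))
  for (k in seq_along(pops)) {
    rows <- if (per_population) ds$samples$patch_id == pops[k] else TRUE
    Yk <- Y[rows, , drop = FALSE]
    n <- colSums(!is.na(Yk))
    n0 <- colSums(Yk == 0L, na.rm = TRUE)
    pr <- prior
    if (is.null(pr)) {
      pr <- tryCatch(.moment_prior(n0[n > 0] / n[n > 0]),
                     aflpsgs_insufficient_data = function(e) prior_spec(1, 1))
    }
    q <- rep(NA_real_, ncol(Yk))
    est <- n >= 1
    q[est] <- estimate_allele_freq(n[est], n0[est], pr)
    out[[k]] <- data.frame(locus_id = colnames(Y), population_id = pops[k],
                           q = q, n = n, n_absent = n0,
                           prior_a = pr$a, prior_b = pr$b,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("locus_freqs", "data.frame")
  res
}

#' Per-population diversity statistics for dominant markers
#'
#' PLP is the proportion of loci whose minor allele frequency is at least
#' `maf_threshold` (5% criterion by default).  Nei's gene diversity per
#' locus is Hj = 2q(1-q) * 2n/(2n-1) (small-sample correction with n the
#' locus' non-missing sample size); the population Hj is the across-locus
#' mean with its across-locus standard error.
#'
#' @param ds an `aflp_dataset`.
#' @param prior optional [prior_spec()]; default: moment-matched per
#'   population.
#' @param maf_threshold minor-allele-frequency criterion for PLP.
#' @return data frame of class `pop_diversity`: `population_id`, `n_ind`,
#'   `n_loci`, `PLP`, `Hj`, `Hj_se`.
#' @export
diversity <- function(ds, prior = NULL, maf_threshold = 0.05) {
  fr <- locus_freqs(ds, prior = prior, per_population = TRUE)
  pops <- unique(fr$population_id)
  rows <- lapply(pops, function(p) {
    sub <- fr[fr$population_id == p & is.finite(fr$q), ]
    n_ind <- sum(ds$samples$patch_id == p)
    if (n_ind < 2) warning(sprintf("population %s has fewer than 2 individuals", p))
    maf <- pmin(sub$q, 1 - sub$q)
    hj <- 2 * sub$q * (1 - sub$q) * ifelse(sub$n > 0, 2 * sub$n / (2 * sub$n - 1), NA)
    data.frame(population_id = p, n_ind = n_ind, n_loci = nrow(sub),
               PLP = mean(maf >= maf_threshold),
               Hj = mean(hj),
               Hj_se = stats::sd(hj) / sqrt(length(hj)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pop_diversity", "data.frame")
  out
}

# Per-locus numerator/denominator of the moment FST estimator across the
# populations in columns of qmat; nmat holds per-population sample sizes
# (individuals), amat/bmat the beta-prior shapes behind each estimate.
# The numerator is the across-population variance of the estimated
# frequencies (population divisor r, so complete fixation of two demes
# gives FST = 1) minus the matching share of the estimator's own sampling
# variance.  For dominant markers that variance is larger than the
# binomial-allele q(1-q)/(2n): the delta method on the posterior-mean-sqrt
# estimator gives w^2 (1-q^2)/(4n) with shrink factor w = n/(n + a + b).
# The same shrink deflates the across-population spread, so the
# denominator q̄(1-q̄) is multiplied by w̄^2, keeping the estimator's
# expectation close to the island-model FST.
.fst_components <- function(qmat, nmat, amat = 1, bmat = 1) {
  r <- ncol(qmat)
  w <- nmat / (nmat + amat + bmat)
  qbar <- rowMeans(qmat)
  s2 <- rowSums((qmat - qbar)^2) / r
  varhat <- w^2 * (1 - qmat^2) / (4 * nmat)
  corr <- (r - 1) / r * rowMeans(varhat)
  wbar <- rowMeans(w)
  list(num = s2 - corr, den = wbar^2 * qbar * (1 - qbar))
}

.fst_ratio <- function(qmat, nmat, amat = 1, bmat = 1) {
  ok <- apply(is.finite(qmat), 1, all) & apply(nmat > 0, 1, all)
  if (!any(ok)) return(NA_real_)
  if (is.matrix(amat)) amat <- amat[ok, , drop = FALSE]
  if (is.matrix(bmat)) bmat <- bmat[ok, , drop = FALSE]
  cmp <- .fst_components(qmat[ok, , drop = FALSE], nmat[ok, , drop = FALSE],
                         amat, bmat)
  usable <- cmp$den > 1e-12
  if (!any(usable)) return(NA_real_)
  sum(cmp$num[usable]) / sum(cmp$den[usable])
}

#' Pairwise and global FST from per-population allele frequencies
#'
#' Ratio-of-sums moment estimator: per locus the across-population variance
#' of the null-allele frequency, minus a binomial allele-sampling
#' correction, is divided by qbar(1-qbar), with numerators and denominators
#' each summed over loci before taking the ratio.  Negative estimates are
#' truncated at 0.  The linearized form FST/(1-FST) used for
#' isolation-by-distance regressions is also returned.
#'
#' @param freqs a [locus_freqs()] table with at least 2 populations.
#' @return list of class `fst_result`: `populations`, matrices `fst` and
#'   `linearized`, `global`, `global_linearized`, `n_loci`.
#' @export
pairwise_fst <- function(freqs) {
  pops <- unique(freqs$population_id)
  .assert(length(pops) >= 2, "need at least 2 populations",
          "aflpsgs_insufficient_data")
  loci <- unique(freqs$locus_id)
  qmat <- matrix(NA_real_, length(loci), length(pops),
                 dimnames = list(loci, pops))
  nmat <- matrix(0, length(loci), length(pops), dimnames = list(loci, pops))
  amat <- matrix(1, length(loci), length(pops))
  bmat <- matrix(1, length(loci), length(pops))
  idx <- cbind(match(freqs$locus_id, loci), match(freqs$population_id, pops))
  qmat[idx] <- freqs$q
  nmat[idx] <- freqs$n
  if (!is.null(freqs$prior_a)) amat[idx] <- freqs$prior_a
  if (!is.null(freqs$prior_b)) bmat[idx] <- freqs$prior_b
  r <- length(pops)
  fst <- matrix(NA_real_, r, r, dimnames = list(pops, pops))
  diag(fst) <- 0
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    v <- .fst_ratio(qmat[, c(i, j), drop = FALSE], nmat[, c(i, j), drop = FALSE],
                    amat[, c(i, j), drop = FALSE], bmat[, c(i, j), drop = FALSE])
    if (is.na(v)) {
      warning(sprintf("FST undefined for pair %s-%s (no polymorphic shared loci)",
                      pops[i], pops[j]))
    } else {
      v <- max(0, v)
    }
    fst[i, j] <- fst[j, i] <- v
  }
  g <- .fst_ratio(qmat, nmat, amat, bmat)
  g <- if (is.na(g)) NA_real_ else max(0, g)
  lin <- ifelse(is.na(fst) | fst >= 1, NA_real_, fst / (1 - fst))
  diag(lin) <- 0
  structure(list(populations = pops, fst = fst, linearized = lin,
                 global = g,
                 global_linearized = if (is.na(g) || g >= 1) NA_real_ else g / (1 - g),
                 n_loci = length(loci)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Moment FST over %d loci, %d populations\n", x$n_loci,
              length(x$populations)))
  cat(sprintf("  global FST = %.4f (linearized %.4f)\n", x$global,
              x$global_linearized))
  up <- x$fst[upper.tri(x$fst)]
  cat(sprintf("  pairwise FST: mean %.4f, range [%.4f, %.4f]\n",
              mean(up, na.rm = TRUE), min(up, na.rm = TRUE), max(up, na.rm = TRUE)))
  invisible(x)
}

# Per-locus (He, FST) for the outlier scan, from per-deme counts and a
# single shared prior.  The posterior-mean-sqrt frequency estimate shrinks
# deviations toward the prior by w = n/(n + a + b) per deme, so the raw
# across-deme variance understates the true one by ~wbar^2 and the
# estimator's own sampling variance is ~w^2 (1 - q^2)/(4n) (delta method
# on sqrt of a binomial phenotype proportion).  Subtracting the latter and
# dividing by wbar^2 * qbar(1-qbar) makes the true-FST -> estimate map
# close to the identity, which the single-pass cloud calibration needs.
# Untruncated ratios are returned (the null cloud is two-sided).
.dominant_locus_stats <- function(nmat, n0mat, prior) {
  r <- ncol(nmat)
  qhat <- matrix(estimate_allele_freq(as.vector(nmat), as.vector(n0mat), prior),
                 nrow(nmat), r)
  w <- nmat / (nmat + prior$a + prior$b)
  qbar <- rowMeans(qhat)
  s2 <- rowSums((qhat - qbar)^2) / (r - 1)
  varhat <- w^2 * (1 - qhat^2) / (4 * nmat)
  corr <- rowMeans(varhat)
  wbar <- rowMeans(w)
  den <- wbar^2 * qbar * (1 - qbar)
  data.frame(He = 2 * qbar * (1 - qbar),
             fst = ifelse(den > 1e-12, (s2 - corr) / den, NA_real_))
}
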