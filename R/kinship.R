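#' Single-locus kinship components for a pair of dominant phenotypes
#'
#' For a biallelic dominant locus with null-allele frequency q, the
#' band-presence phenotype frequency is p = 1 - q^2 (Hardy-Weinberg; with
#' an optional population inbreeding adjustment, p = 1 - q^2 - F q(1-q)).
#' To first order in the kinship coefficient theta of a non-inbred pair,
#' corr(Y_i, Y_j) = 4 theta q / (1 + q), which yields the per-locus
#' estimator components
#'   numerator c = (Y_i - p)(Y_j - p),   weight w = 4 q p (1 - p)/(1 + q),
#' and the per-locus kinship estimate c/w.  The expectation of c/w equals
#' theta exactly for relationship classes without a double-IBD mode
#' (unrelated, parent-offspring); for classes with double IBD (full sibs,
#' clones) the estimator is biased upward (e.g. (1+3q)/(16q) per locus for
#' full sibs).
#'
#' Monomorphic loci (q = 0 or 1) carry no information and are signalled by
#' `NA` components rather than an error.
#'
#' @param y_i,y_j band-presence phenotypes in `{0, 1}` (vectorized).
#' @param q null-allele frequency/frequencies in (0, 1).
#' @param f_adjust assumed population inbreeding coefficient entering p
#'   (default 0).
#' @return list with vectors `numerator` and `weight` (`NA` for excluded
#'   loci).
#' @export
locus_kinship <- function(y_i, y_j, q, f_adjust = 0) {
  nn <- max(length(y_i), length(y_j), length(q))
  y_i <- rep_len(y_i, nn); y_j <- rep_len(y_j, nn); q <- rep_len(q, nn)
  .assert(all(y_i %in% c(0, 1), na.rm = TRUE) && all(y_j %in% c(0, 1), na.rm = TRUE),
          "phenotypes must be 0 or 1", "aflpsgs_format_error")
  ok <- is.finite(q) & q > 0 & q < 1
  p <- ifelse(ok, 1 - q^2 - f_adjust * q * (1 - q), NA_real_)
  num <- (y_i - p) * (y_j - p)
  w <- 4 * q * p * (1 - p) / (1 + q)
  num[!ok] <- NA_real_
  w[!ok] <- NA_real_
  list(numerator = num, weight = w)
}

# shared pair-kinship engine: Y individuals x loci (NA allowed), q per
# locus, i/j parallel index vectors of pair members.  Returns per-pair
# sums and, optionally, the per-locus component matrices needed for
# jackknifing over loci.
.kinship_core <- function(Y, q, i, j, f_adjust = 0, keep_components = TRUE) {
  usable <- is.finite(q) & q > 0 & q < 1
  Y <- Y[, usable, drop = FALSE]
  q <- q[usable]
  p <- 1 - q^2 - f_adjust * q * (1 - q)
  w <- 4 * q * p * (1 - p) / (1 + q)
  A <- sweep(Y, 2, p)                     # NA propagates through products
  num <- A[i, , drop = FALSE] * A[j, , drop = FALSE]
  used <- !is.na(num)
  W <- matrix(w, nrow = length(i), ncol = length(q), byrow = TRUE)
  W[!used] <- 0
  num[!used] <- 0
  sum_num <- rowSums(num)
  sum_den <- rowSums(W)
  theta <- ifelse(sum_den > 0, sum_num / sum_den, NA_real_)
  out <- list(theta = theta, sum_num = sum_num, sum_den = sum_den,
              n_loci = rowSums(used), loci = colnames(Y), q = q, w = w)
  if (keep_components) {
    out$num <- num
    out$W <- W
  }
  out
}

# resolve a freqs argument into a per-locus numeric q vector aligned with
# the dataset's loci; default: pooled Bayesian estimates
.resolve_freqs <- function(ds, freqs) {
  loci <- colnames(ds$phenotypes)
  if (is.null(freqs)) {
    fr <- locus_freqs(ds, per_population = FALSE)
    q <- fr$q[match(loci, fr$locus_id)]
  } else if (inherits(freqs, "data.frame")) {
    pops <- unique(freqs$population_id)
    .assert(length(pops) == 1,
            "freqs must contain a single (reference) population", "aflpsgs_format_error")
    q <- freqs$q[match(loci, freqs$locus_id)]
  } else {
    q <- as.numeric(freqs)
    if (!is.null(names(q))) q <- q[match(loci, names(q))]
    .assert(length(q) == length(loci),
            "freqs must supply one frequency per locus", "aflpsgs_format_error")
  }
  q
}

#' Pairwise multilocus kinship matrix from dominant phenotypes
#'
#' Multilocus kinship for each pair is the ratio of per-locus numerator
#' sums to weight sums over the loci scored in both individuals
#' ([locus_kinship()]).  Reference allele frequencies default to Bayesian
#' estimates on the pooled sample.  Per-locus components are retained so
#' that downstream summaries (correlogram class means, regression slopes)
#' can be jackknifed over loci.
#'
#' @param ds an `aflp_dataset`.
#' @param freqs reference null-allele frequencies: a single-population
#'   [locus_freqs()] table, a numeric vector (one per locus), or `NULL`
#'   (pooled estimate).
#' @param f_adjust population inbreeding coefficient assumed in the
#'   phenotype frequency (default 0).
#' @param min_loci pairs with fewer usable loci are flagged (`flagged`
#'   field), not dropped.
#' @param keep_components retain per-pair per-locus component matrices
#'   (needed for jackknife errors; set `FALSE` to save memory).
#' @return object of class `kinship_matrix`.
#' @export
kinship_matrix <- function(ds, freqs = NULL, f_adjust = 0, min_loci = 10L,
                           keep_components = TRUE) {
  Y <- unclass(ds$phenotypes)
  all_missing <- rowSums(!is.na(Y)) == 0 & ncol(Y) > 0
  if (any(all_missing)) {
    warning(sprintf("excluding %d individual(s) with all-missing genotypes",
                    sum(all_missing)))
    Y <- Y[!all_missing, , drop = FALSE]
  }
  n <- nrow(Y)
  .assert(n >= 2, "need at least 2 individuals", "aflpsgs_insufficient_data")
  q <- .resolve_freqs(ds, freqs)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  core <- .kinship_core(Y, q, i, j, f_adjust = f_adjust,
                        keep_components = keep_components)
  structure(list(ids = rownames(Y), i = i, j = j,
                 theta = core$theta, sum_num = core$sum_num,
                 sum_den = core$sum_den, n_loci = core$n_loci,
                 flagged = core$n_loci < min_loci,
                 loci = core$loci, num = core$num, W = core$W,
                 f_adjust = f_adjust),
            class = "kinship_matrix")
}

#' Kinship estimates for designated pairs only
#'
#' Same estimator as [kinship_matrix()] but restricted to given pairs;
#' useful for large simulated pair collections where the full matrix is
#' not needed.
#'
#' @param ds an `aflp_dataset`.
#' @param i,j individual ids (character) or row indices defining the pairs.
#' @param freqs,f_adjust as in [kinship_matrix()].
#' @return data frame: `i`, `j`, `theta`, `n_loci`.
#' @export
kinship_pairs <- function(ds, i, j, freqs = NULL, f_adjust = 0) {
  Y <- unclass(ds$phenotypes)
  if (is.character(i)) i <- match(i, rownames(Y))
  if (is.character(j)) j <- match(j, rownames(Y))
  .assert(!anyNA(i) && !anyNA(j) && all(i >= 1 & i <= nrow(Y)) &&
          all(j >= 1 & j <= nrow(Y)),
          "unknown individuals in pair list", "aflpsgs_consistency_error")
  q <- .resolve_freqs(ds, freqs)
  core <- .kinship_core(Y, q, i, j, f_adjust = f_adjust, keep_components = FALSE)
  data.frame(i = rownames(Y)[i], j = rownames(Y)[j],
             theta = core$theta, n_loci = core$n_loci,
             stringsAsFactors = FALSE)
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("Pairwise multilocus kinship: %d individuals, %d pairs, %d loci\n",
              length(x$ids), length(x$theta), length(x$loci)))
  cat(sprintf("  mean theta = %.4f (sd %.4f); %d pair(s) flagged (< %s usable loci)\n",
              mean(x$theta, na.rm = TRUE), stats::sd(x$theta, na.rm = TRUE),
              sum(x$flagged), "min_loci"))
  invisible(x)
}

#' @export
as.matrix.kinship_matrix <- function(x, ...) {
  n <- length(x$ids)
  M <- matrix(NA_real_, n, n, dimnames = list(x$ids, x$ids))
  M[cbind(x$i, x$j)] <- x$theta
  M[cbind(x$j, x$i)] <- x$theta
  M
}

#' @export
as.data.frame.kinship_matrix <- function(x, ...) {
  data.frame(i = x$ids[x$i], j = x$ids[x$j], theta = x$theta,
             n_loci = x$n_loci, stringsAsFactors = FALSE)
}
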