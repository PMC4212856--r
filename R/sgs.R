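#' Doubling distance classes for kinship autocorrelograms
#'
#' Class 0 is reserved for within-patch pairs (distance exactly 0); the
#' following classes have upper edges w, 2w, 4w, ... (each interval twice
#' as wide as the previous), and the final class is open-ended.  The
#' defaults reproduce the {0, 10, 20, 40, 80, 160, >160} km scheme.
#'
#' @param first_width_km width of the first positive class, > 0.
#' @param n_classes number of finite class edges including the zero class.
#' @return list of class `distance_classes` with `upper` edges (km, last
#'   `Inf`) and printable `labels`.
#' @export
build_distance_classes <- function(first_width_km = 10, n_classes = 6) {
  .assert(is.numeric(first_width_km) && first_width_km > 0,
          "first_width_km must be positive", "aflpsgs_range_error")
  .assert(.is_count(n_classes) && n_classes >= 2, "n_classes must be >= 2",
          "aflpsgs_range_error")
  upper <- c(0, first_width_km * 2^(0:(n_classes - 2)), Inf)
  lower <- c(0, utils::head(upper, -1))
  labels <- c("0 (within patch)",
              sprintf("(%g, %g]", lower[-c(1, length(upper))], upper[-c(1, length(upper))]),
              sprintf("> %g", lower[length(upper)]))
  structure(list(upper = upper, lower = lower, labels = labels),
            class = "distance_classes")
}

#' Assign pair distances to distance classes
#' @param d distances in km (vectorized).
#' @param classes a [build_distance_classes()] spec.
#' @return integer class indices (1 = within patch).
#' @export
assign_distance_class <- function(d, classes = build_distance_classes()) {
  up <- classes$upper
  breaks <- c(-Inf, up[-length(up)], Inf)
  as.integer(cut(d, breaks = breaks, right = TRUE))
}

# class means of theta given integer class labels; absent classes give NA
.class_means <- function(theta, cls, n_classes) {
  s <- rep(0, n_classes); cnt <- tabulate(cls, n_classes)
  rs <- rowsum(theta, cls)
  s[as.integer(rownames(rs))] <- rs
  ifelse(cnt > 0, s / cnt, NA_real_)
}

# leave-one-locus-out theta matrix (pairs x loci) from stored components
.theta_jackknife <- function(K) {
  .assert(!is.null(K$num), "kinship matrix lacks per-locus components (keep_components = FALSE)",
          "aflpsgs_insufficient_data")
  den <- K$sum_den - K$W
  th <- (K$sum_num - K$num) / den
  th[den <= 0] <- NA_real_
  th
}

.jack_se <- function(est_minus) {
  est_minus <- est_minus[is.finite(est_minus)]
  L <- length(est_minus)
  if (L < 2) return(NA_real_)
  sqrt((L - 1) / L * sum((est_minus - mean(est_minus))^2))
}

#' Kinship autocorrelogram over distance classes
#'
#' Mean pairwise kinship per geographic distance class, with (i) a null
#' envelope from random permutations of individual spatial locations
#' (joint permutation of the rows/columns of the distance matrix against
#' the fixed kinship matrix) and (ii) standard errors from jackknifing over
#' loci.
#'
#' @param K a [kinship_matrix()] with components retained.
#' @param D distance matrix in km, indexed like `K` (see
#'   [geo_distance_matrix()]).
#' @param classes a [build_distance_classes()] spec.
#' @param n_perm number of location permutations (default 9999).
#' @param seed optional integer seed for the permutations.
#' @param envelope quantiles of the permutation envelope.
#' @return data frame of class `autocorrelogram`: per class `lower_km`,
#'   `upper_km`, `n_pairs`, `mean_kinship`, `jackknife_se`, `env_lo`,
#'   `env_hi`.
#' @export
autocorrelogram <- function(K, D, classes = build_distance_classes(),
                            n_perm = 9999, seed = NULL,
                            envelope = c(0.025, 0.975)) {
  n <- length(K$ids)
  .assert(nrow(D) == n && ncol(D) == n, "K and D must index the same individuals",
          "aflpsgs_consistency_error")
  if (!is.null(rownames(D))) {
    .assert(identical(rownames(D), K$ids), "K and D row order differs",
            "aflpsgs_consistency_error")
  }
  i <- K$i; j <- K$j; theta <- K$theta
  d <- D[cbind(i, j)]
  nc <- length(classes$upper)
  cls <- assign_distance_class(d, classes)
  n_pairs <- tabulate(cls, nc)
  if (any(n_pairs == 0)) {
    warning(sprintf("empty distance class(es): %s",
                    paste(classes$labels[n_pairs == 0], collapse = "; ")))
  }
  obs <- .class_means(theta, cls, nc)

  # jackknife over loci
  th_minus <- .theta_jackknife(K)
  jse <- rep(NA_real_, nc)
  for (k in which(n_pairs > 0)) {
    fbar_minus <- colMeans(th_minus[cls == k, , drop = FALSE], na.rm = TRUE)
    jse[k] <- .jack_se(fbar_minus)
  }

  # permutation envelope: permute individual locations
  clsmat <- matrix(0L, n, n)
  clsmat[cbind(i, j)] <- cls
  clsmat[cbind(j, i)] <- cls
  perm_means <- matrix(NA_real_, n_perm, nc)
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      pcls <- clsmat[cbind(pm[i], pm[j])]
      perm_means[b, ] <- .class_means(theta, pcls, nc)
    }
  })
  env <- apply(perm_means, 2, stats::quantile, probs = envelope, na.rm = TRUE,
               names = FALSE)
  out <- data.frame(class = seq_len(nc), label = classes$labels,
                    lower_km = classes$lower, upper_km = classes$upper,
                    n_pairs = n_pairs, mean_kinship = obs,
                    jackknife_se = jse,
                    env_lo = env[1, ], env_hi = env[2, ],
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "envelope") <- envelope
  class(out) <- c("autocorrelogram", "data.frame")
  out
}

#' @export
plot.autocorrelogram <- function(x, ...) {
  mid <- ifelse(is.finite(x$upper_km), (x$lower_km + x$upper_km) / 2,
                x$lower_km * 1.5)
  mid[1] <- max(x$upper_km[2] / 20, 0.1)
  ylim <- range(c(x$mean_kinship + x$jackknife_se,
                  x$mean_kinship - x$jackknife_se,
                  x$env_lo, x$env_hi, 0), na.rm = TRUE)
  graphics::plot(mid, x$mean_kinship, log = "x", type = "b", pch = 19,
                 ylim = ylim, xlab = "distance class midpoint (km)",
                 ylab = "mean pairwise kinship", ...)
  graphics::arrows(mid, x$mean_kinship - x$jackknife_se,
                   mid, x$mean_kinship + x$jackknife_se,
                   angle = 90, code = 3, length = 0.03)
  graphics::lines(mid, x$env_lo, lty = 2)
  graphics::lines(mid, x$env_hi, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' The Sp index from a slope and first-class kinship
#'
#' Sp = -b1 / (1 - f1), where b1 is the slope of pairwise kinship on
#' ln(distance) and f1 the mean kinship of the first distance class.  Sp
#' quantifies the intensity of fine-scale spatial genetic structure and is
#' comparable across studies.
#'
#' @param b1 regression slope of kinship on ln(km).
#' @param f1 mean kinship of the first distance class, < 1.
#' @return numeric Sp value.
#' @export
sp_index <- function(b1, f1) {
  .assert(all(is.finite(b1)) && all(is.finite(f1)), "b1 and f1 must be finite",
          "aflpsgs_range_error")
  .assert(all(f1 < 1), "Sp undefined for f1 >= 1", "aflpsgs_range_error")
  -b1 / (1 - f1)
}

#' Log-distance regression of kinship and the Sp statistic
#'
#' Ordinary least squares of pairwise kinship on ln(distance) over all
#' pairs at positive distance (within-patch pairs, at distance 0, enter
#' f1 but not the regression).  Standard errors of the slope and of Sp are
#' obtained by jackknifing over loci: the slope, first-class mean and Sp
#' are recomputed with each locus deleted in turn.
#'
#' @param K a [kinship_matrix()] with components retained.
#' @param D distance matrix in km indexed like `K`.
#' @param classes distance-class spec used to define the first class.
#' @param f1 optionally override the first-class mean kinship.
#' @return list of class `sp_result`: `b1`, `se_b1`, `f1`, `sp`, `se_sp`,
#'   `n_pairs_regression`.
#' @export
regression_slope_sp <- function(K, D, classes = build_distance_classes(),
                                f1 = NULL) {
  n <- length(K$ids)
  .assert(nrow(D) == n && ncol(D) == n, "K and D must index the same individuals",
          "aflpsgs_consistency_error")
  i <- K$i; j <- K$j
  d <- D[cbind(i, j)]
  pos <- d > 0 & is.finite(K$theta)
  .assert(length(unique(d[pos])) >= 2,
          "need at least 2 distinct positive distances", "aflpsgs_insufficient_data")
  x <- log(d[pos])
  y <- K$theta[pos]
  b1 <- stats::cov(x, y) / stats::var(x)

  cls <- assign_distance_class(d, classes)
  first <- cls == 1L
  if (is.null(f1)) {
    if (!any(first)) {
      warning("no within-patch pairs; using first non-empty distance class for f1")
      first <- cls == min(cls)
    }
    f1 <- mean(K$theta[first], na.rm = TRUE)
  }
  .assert(f1 < 1, "Sp undefined for f1 >= 1", "aflpsgs_range_error")
  sp <- sp_index(b1, f1)

  th_minus <- .theta_jackknife(K)
  vx <- stats::var(x)
  xc <- x - mean(x)
  Ym <- th_minus[pos, , drop = FALSE]
  b1_minus <- colSums(xc * sweep(Ym, 2, colMeans(Ym, na.rm = TRUE)), na.rm = TRUE) /
    ((sum(pos) - 1) * vx)
  f1_minus <- colMeans(th_minus[first, , drop = FALSE], na.rm = TRUE)
  sp_minus <- -b1_minus / (1 - f1_minus)
  structure(list(b1 = b1, se_b1 = .jack_se(b1_minus),
                 f1 = f1, se_f1 = .jack_se(f1_minus),
                 sp = sp, se_sp = .jack_se(sp_minus),
                 n_pairs_regression = sum(pos)),
            class = "sp_result")
}

#' @export
print.sp_result <- function(x, ...) {
  cat("Isolation-by-distance regression of kinship on ln(distance)\n")
  cat(sprintf("  b1 = %.5f (jackknife SE %.5f), %d pairs\n",
              x$b1, x$se_b1, x$n_pairs_regression))
  cat(sprintf("  f(1) = %.4f (jackknife SE %.4f)\n", x$f1, x$se_f1))
  cat(sprintf("  Sp = %.5f (jackknife SE %.5f)\n", x$sp, x$se_sp))
  invisible(x)
}

#' Mantel matrix-correlation test
#'
#' Pearson correlation between the off-diagonal upper triangles of two
#' square symmetric matrices (e.g. linearized FST/(1-FST) against
#' log geographic distance), with a permutation p-value obtained by
#' jointly permuting rows and columns of the second matrix:
#' p = (1 + #\{permuted r >= observed r\}) / (1 + n_perm) for the
#' one-sided test of positive association.
#'
#' @param G genetic distance matrix.
#' @param X geographic distance matrix.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed.
#' @param log_geo log-transform the off-diagonal entries of `X` (requires
#'   positive distances).
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @return list of class `mantel_result`: `r`, `p`, `n_permutations`,
#'   `alternative`.
#' @export
mantel_test <- function(G, X, n_perm = 9999, seed = NULL, log_geo = TRUE,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  .assert(is.matrix(G) && is.matrix(X) && nrow(G) == ncol(G) &&
          nrow(X) == ncol(X) && nrow(G) == nrow(X) && nrow(G) >= 3,
          "G and X must be square matrices of equal dimension >= 3",
          "aflpsgs_format_error")
  .assert(max(abs(G - t(G)), na.rm = TRUE) < 1e-8 &&
          max(abs(X - t(X)), na.rm = TRUE) < 1e-8,
          "G and X must be symmetric", "aflpsgs_format_error")
  n <- nrow(G)
  ut <- upper.tri(G)
  if (log_geo) {
    .assert(all(X[ut] > 0), "log_geo requires positive off-diagonal distances",
            "aflpsgs_range_error")
    X[ut] <- log(X[ut])
    X[lower.tri(X)] <- t(X)[lower.tri(X)]
  }
  g <- G[ut]; x <- X[ut]
  .assert(stats::sd(g) > 0 && stats::sd(x) > 0,
          "correlation undefined for a constant matrix", "aflpsgs_insufficient_data")
  r <- stats::cor(g, x)
  rp <- numeric(n_perm)
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      rp[b] <- stats::cor(g, X[pm, pm][ut])
    }
  })
  p <- if (alternative == "greater") {
    (1 + sum(rp >= r)) / (1 + n_perm)
  } else {
    (1 + sum(abs(rp) >= abs(r))) / (1 + n_perm)
  }
  structure(list(r = r, p = p, n_permutations = n_perm,
                 alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$alternative, x$n_permutations))
  invisible(x)
}

#' Joint detection rule for fine-scale spatial genetic structure
#'
#' Declares structure present when the first-class mean kinship exceeds
#' the upper permutation envelope AND the log-distance slope is negative
#' with |b1| > 2 x jackknife SE.
#'
#' @param acorr an [autocorrelogram()] result.
#' @param spres a [regression_slope_sp()] result.
#' @return logical.
#' @export
sgs_detected <- function(acorr, spres) {
  isTRUE(acorr$mean_kinship[1] > acorr$env_hi[1]) &&
    isTRUE(spres$b1 < 0) &&
    isTRUE(abs(spres$b1) > 2 * spres$se_b1)
}
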