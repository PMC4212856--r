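// Metropolis-within-Gibbs sampler for the dominant-marker inbreeding model:
//   P(Y_il = 0) = q_l^2 + Fi_i * q_l * (1 - q_l)
// with flat priors on the q_l and iid Beta(alpha, beta) priors on the Fi.
//
// Sweep structure:
//   1. random-walk update of each q_l on the logit scale;
//   2. random-walk update of each Fi on the logit scale;
//   3. one joint "ridge" move: all logit(Fi) shifted by a common delta with
//      each q_l deterministically adjusted to keep the population-mean
//      band-absence probability of its locus unchanged (the near-flat
//      likelihood direction for mean F), accepted with the exact Jacobian;
//   4. optionally (estimate_shapes) random-walk updates of log(alpha) and
//      log(beta) under lognormal hyperpriors, making the Fi prior
//      hierarchical with (alpha, beta) estimated.
//
// Proposal widths adapt toward 20-45% acceptance during burn-in only and
// are frozen afterwards.  Uses R's RNG: chains reproduce from set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clamp01(double x) {
  if (x < 1e-12) return 1e-12;
  if (x > 1.0 - 1e-12) return 1.0 - 1e-12;
  return x;
}

// grouped-product log accumulator: one log() per 16 factors
struct LLAcc {
  double s, prod; int k;
  LLAcc() : s(0.0), prod(1.0), k(0) {}
  inline void mul(double v) {
    prod *= v;
    if (++k == 16) { s += std::log(prod); prod = 1.0; k = 0; }
  }
  inline double total() { s += std::log(prod); prod = 1.0; k = 0; return s; }
};

static inline double p_absent(double q, double f) {
  return clamp01(q * q + f * q * (1.0 - q));
}

// [[Rcpp::export]]
List inbreeding_chain_cpp(IntegerMatrix Y, double alpha, double beta,
                          int n_steps, int burn_in, int thin,
                          double w_q_init, double w_f_init, double w_r_init,
                          double w_s_init,
                          NumericVector q_init, NumericVector fi_init,
                          bool estimate_shapes, double hyper_mu,
                          double hyper_sd) {
  const int n = Y.nrow(), L = Y.ncol();
  std::vector<double> q(q_init.begin(), q_init.end());
  std::vector<double> fi(fi_init.begin(), fi_init.end());
  // row-major copy for cache-friendly per-individual scans
  std::vector<int> Yr((size_t)n * L);
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < n; ++i)
      Yr[(size_t)i * L + l] = Y(i, l);
  double w_q = w_q_init, w_f = w_f_init, w_r = w_r_init, w_s = w_s_init;
  double a = alpha, b = beta;

  const int n_rec = (thin > 0) ? (n_steps - burn_in) / thin : 0;
  NumericVector F_draws(n_rec), logL_draws(n_rec), a_draws(n_rec), b_draws(n_rec);
  NumericVector fi_sum(n), fi_sumsq(n), q_sum(L);
  long long acc_q = 0, prop_q = 0, acc_f = 0, prop_f = 0;
  long long acc_r = 0, prop_r = 0, acc_s = 0, prop_s = 0;
  long long wa_q = 0, wp_q = 0, wa_f = 0, wp_f = 0, wa_r = 0, wp_r = 0,
            wa_s = 0, wp_s = 0;
  int rec = 0;

  std::vector<double> q_prop(L);

  for (int s = 1; s <= n_steps; ++s) {
    const bool in_burn = (s <= burn_in);

    // --- per-locus frequency updates ---------------------------------
    for (int l = 0; l < L; ++l) {
      double qc = q[l];
      double z = std::log(qc / (1.0 - qc)) + w_q * norm_rand();
      double qp = clamp01(1.0 / (1.0 + std::exp(-z)));
      LLAcc llc, llp;
      for (int i = 0; i < n; ++i) {
        int y = Y(i, l);
        if (y == NA_INTEGER) continue;
        double pc = p_absent(qc, fi[i]);
        double pp = p_absent(qp, fi[i]);
        llc.mul(y == 0 ? pc : 1.0 - pc);
        llp.mul(y == 0 ? pp : 1.0 - pp);
      }
      // flat prior on q plus logit-transform Jacobian log(q(1-q))
      double lacc = (llp.total() + std::log(qp * (1.0 - qp))) -
                    (llc.total() + std::log(qc * (1.0 - qc)));
      if (in_burn) ++wp_q; else ++prop_q;
      if (std::log(unif_rand()) < lacc) {
        q[l] = qp;
        if (in_burn) ++wa_q; else ++acc_q;
      }
    }

    // --- per-individual inbreeding updates ---------------------------
    for (int i = 0; i < n; ++i) {
      double fc = fi[i];
      double z = std::log(fc / (1.0 - fc)) + w_f * norm_rand();
      double fp = clamp01(1.0 / (1.0 + std::exp(-z)));
      LLAcc llc, llp;
      const int *yrow = &Yr[(size_t)i * L];
      for (int l = 0; l < L; ++l) {
        int y = yrow[l];
        if (y == NA_INTEGER) continue;
        double pc = p_absent(q[l], fc);
        double pp = p_absent(q[l], fp);
        llc.mul(y == 0 ? pc : 1.0 - pc);
        llp.mul(y == 0 ? pp : 1.0 - pp);
      }
      // Beta(a,b) prior with logit Jacobian folds to a*log f + b*log(1-f)
      double lacc = (llp.total() + a * std::log(fp) + b * std::log1p(-fp)) -
                    (llc.total() + a * std::log(fc) + b * std::log1p(-fc));
      if (in_burn) ++wp_f; else ++prop_f;
      if (std::log(unif_rand()) < lacc) {
        fi[i] = fp;
        if (in_burn) ++wa_f; else ++acc_f;
      }
    }

    // --- joint ridge move --------------------------------------------
    if (n > 0) {
      double delta = w_r * norm_rand();
      double fbar_c = 0.0, fbar_p = 0.0;
      double lprior = 0.0;
      // shifted inbreeding coefficients and their prior contribution
      // (stored implicitly; recomputed on acceptance)
      for (int i = 0; i < n; ++i) {
        double z = std::log(fi[i] / (1.0 - fi[i])) + delta;
        double fp = clamp01(1.0 / (1.0 + std::exp(-z)));
        fbar_c += fi[i];
        fbar_p += fp;
        lprior += a * (std::log(fp) - std::log(fi[i])) +
                  b * (std::log1p(-fp) - std::log1p(-fi[i]));
      }
      fbar_c /= n; fbar_p /= n;
      // per-locus compensation: keep qbar-level absence prob fixed at the
      // population mean inbreeding; exact Jacobian term per locus
      double ljac = 0.0;
      bool ok = true;
      for (int l = 0; l < L; ++l) {
        double p0 = q[l] * q[l] + fbar_c * q[l] * (1.0 - q[l]);
        double A = 1.0 - fbar_p;
        double qp;
        if (A < 1e-10) qp = p0;
        else qp = (-fbar_p + std::sqrt(fbar_p * fbar_p + 4.0 * A * p0)) / (2.0 * A);
        qp = clamp01(qp);
        q_prop[l] = qp;
        double dc = fbar_c + 2.0 * q[l] * (1.0 - fbar_c);   // d p0 / d q at current
        double dp = fbar_p + 2.0 * qp * (1.0 - fbar_p);     // at proposal
        if (dp <= 0 || dc <= 0) { ok = false; break; }
        ljac += std::log(dc) - std::log(dp);
      }
      if (ok) {
        LLAcc llc, llp;
        for (int l = 0; l < L; ++l) {
          for (int i = 0; i < n; ++i) {
            int y = Y(i, l);
            if (y == NA_INTEGER) continue;
            double zfi = std::log(fi[i] / (1.0 - fi[i])) + delta;
            double fp = clamp01(1.0 / (1.0 + std::exp(-zfi)));
            double pc = p_absent(q[l], fi[i]);
            double pp = p_absent(q_prop[l], fp);
            llc.mul(y == 0 ? pc : 1.0 - pc);
            llp.mul(y == 0 ? pp : 1.0 - pp);
          }
        }
        double lacc = llp.total() - llc.total() + lprior + ljac;
        if (in_burn) ++wp_r; else ++prop_r;
        if (std::log(unif_rand()) < lacc) {
          for (int i = 0; i < n; ++i) {
            double z = std::log(fi[i] / (1.0 - fi[i])) + delta;
            fi[i] = clamp01(1.0 / (1.0 + std::exp(-z)));
          }
          for (int l = 0; l < L; ++l) q[l] = q_prop[l];
          if (in_burn) ++wa_r; else ++acc_r;
        }
      }
    }

    // --- hyperparameter updates (hierarchical mode) -------------------
    if (estimate_shapes && n > 0) {
      double slf = 0.0, sl1f = 0.0;
      for (int i = 0; i < n; ++i) {
        slf += std::log(fi[i]);
        sl1f += std::log1p(-fi[i]);
      }
      for (int which = 0; which < 2; ++which) {
        double cur = (which == 0) ? a : b;
        double lp = std::log(cur) + w_s * norm_rand();
        double prop = std::exp(lp);
        if (prop < 1e-3 || prop > 1e3) continue;
        double ap = (which == 0) ? prop : a;
        double bp = (which == 0) ? b : prop;
        double lacc =
          (ap - 1.0) * slf + (bp - 1.0) * sl1f - n * ::Rf_lbeta(ap, bp) -
          ((a - 1.0) * slf + (b - 1.0) * sl1f - n * ::Rf_lbeta(a, b));
        // lognormal hyperprior on the shape (flat-in-log location hyper_mu)
        double zc = (std::log(cur) - hyper_mu) / hyper_sd;
        double zp = (lp - hyper_mu) / hyper_sd;
        lacc += 0.5 * (zc * zc - zp * zp);
        if (in_burn) ++wp_s; else ++prop_s;
        if (std::log(unif_rand()) < lacc) {
          if (which == 0) a = prop; else b = prop;
          if (in_burn) ++wa_s; else ++acc_s;
        }
      }
    }

    // --- adapt proposal widths during burn-in only --------------------
    if (in_burn && s % 100 == 0) {
      if (wp_q > 0) {
        double r = (double)wa_q / (double)wp_q;
        if (r < 0.20) w_q *= 0.8; else if (r > 0.45) w_q *= 1.25;
        if (w_q < 1e-3) w_q = 1e-3; if (w_q > 20.0) w_q = 20.0;
      }
      if (wp_f > 0) {
        double r = (double)wa_f / (double)wp_f;
        if (r < 0.20) w_f *= 0.8; else if (r > 0.45) w_f *= 1.25;
        if (w_f < 1e-3) w_f = 1e-3; if (w_f > 20.0) w_f = 20.0;
      }
      if (wp_r > 0) {
        double r = (double)wa_r / (double)wp_r;
        if (r < 0.20) w_r *= 0.8; else if (r > 0.45) w_r *= 1.25;
        if (w_r < 1e-4) w_r = 1e-4; if (w_r > 20.0) w_r = 20.0;
      }
      if (wp_s > 0) {
        double r = (double)wa_s / (double)wp_s;
        if (r < 0.20) w_s *= 0.8; else if (r > 0.45) w_s *= 1.25;
        if (w_s < 1e-3) w_s = 1e-3; if (w_s > 20.0) w_s = 20.0;
      }
      wa_q = wp_q = wa_f = wp_f = wa_r = wp_r = wa_s = wp_s = 0;
    }

    // --- record -------------------------------------------------------
    if (s > burn_in && thin > 0 && (s - burn_in) % thin == 0 && rec < n_rec) {
      double Fbar = 0.0;
      for (int i = 0; i < n; ++i) Fbar += fi[i];
      Fbar = (n > 0) ? Fbar / n : NA_REAL;
      LLAcc ll;
      for (int l = 0; l < L; ++l)
        for (int i = 0; i < n; ++i) {
          int y = Y(i, l);
          if (y == NA_INTEGER) continue;
          double p0 = p_absent(q[l], fi[i]);
          ll.mul(y == 0 ? p0 : 1.0 - p0);
        }
      F_draws[rec] = Fbar;
      logL_draws[rec] = ll.total();
      a_draws[rec] = a;
      b_draws[rec] = b;
      for (int i = 0; i < n; ++i) { fi_sum[i] += fi[i]; fi_sumsq[i] += fi[i] * fi[i]; }
      for (int l = 0; l < L; ++l) q_sum[l] += q[l];
      ++rec;
    }
  }

  return List::create(
    _["F_draws"] = F_draws,
    _["logL_draws"] = logL_draws,
    _["a_draws"] = a_draws,
    _["b_draws"] = b_draws,
    _["fi_sum"] = fi_sum,
    _["fi_sumsq"] = fi_sumsq,
    _["q_sum"] = q_sum,
    _["n_records"] = rec,
    _["acc_rate_q"] = (prop_q > 0) ? (double)acc_q / (double)prop_q : NA_REAL,
    _["acc_rate_f"] = (prop_f > 0) ? (double)acc_f / (double)prop_f : NA_REAL,
    _["acc_rate_ridge"] = (prop_r > 0) ? (double)acc_r / (double)prop_r : NA_REAL,
    _["acc_rate_shapes"] = (prop_s > 0) ? (double)acc_s / (double)prop_s : NA_REAL,
    _["w_q"] = w_q, _["w_f"] = w_f, _["w_r"] = w_r, _["w_s"] = w_s);
}
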