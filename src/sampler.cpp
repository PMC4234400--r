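// Adaptive random-walk Metropolis-within-Gibbs sampler for the joint
// toxicity/efficacy dose-response models.
//
// Parameter vector on the sampling scale:
//   th[0] = beta0_T, th[1] = log beta1_T, th[2] = beta0_E,
//   th[3] = log beta1_E, th[4] = beta2_E, th[5] = transformed association
// (th[5] only for the copula families). Blocks: toxicity {0,1},
// efficacy {2,3,4}, association {5}. Proposal scales adapt toward the
// target acceptance rate during burn-in only; the retained chain is a
// fixed-kernel Markov chain. Uses R's RNG so set.seed() governs
// reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

const double PCLAMP = 1e-12;  // marginal-probability clamp inside the
                              // log-likelihood only

inline double expit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// family: 0 = independence, 1 = braun, 2 = gumbel
double log_post(const std::vector<double>& th, int family,
                const IntegerMatrix& counts, const NumericVector& pr,
                bool prior_only) {
  const double b0T = th[0], b1T = std::exp(th[1]);
  const double b0E = th[2], b1E = std::exp(th[3]), b2E = th[4];

  // priors: normals on intercepts/quadratic; Gamma on slopes with the
  // log-scale Jacobian (+ th); flat association prior with the Jacobian of
  // the logit-type transform
  double lp = R::dnorm(b0T, pr[0], pr[1], 1) + R::dnorm(b0E, pr[2], pr[3], 1) +
              R::dnorm(b2E, pr[4], pr[5], 1) +
              R::dgamma(b1T, pr[6], 1.0 / pr[7], 1) + th[1] +
              R::dgamma(b1E, pr[6], 1.0 / pr[7], 1) + th[3];

  double psi = 0.0;
  if (family != 0) {
    double p = expit(th[5]);
    lp += std::log(p) + std::log(1.0 - p);  // d psi / d th up to a constant
    psi = (family == 1) ? p : 2.0 * p - 1.0;
  }

  if (!prior_only) {
    const int K = counts.nrow();
    for (int z = 0; z < K; ++z) {
      const int n11 = counts(z, 0), n10 = counts(z, 1), n01 = counts(z, 2),
                n00 = counts(z, 3);
      if (n11 + n10 + n01 + n00 == 0) continue;
      const double x = static_cast<double>(z);
      double piT = expit(b0T + b1T * x);
      double piE = expit(b0E + b1E * x + b2E * x * x);
      piT = std::min(std::max(piT, PCLAMP), 1.0 - PCLAMP);
      piE = std::min(std::max(piE, PCLAMP), 1.0 - PCLAMP);
      double c11, c10, c01, c00;
      if (family == 1) {
        const double k =
            1.0 / ((1.0 - psi) * (1.0 - piT * piE) + psi * piT * piE);
        c11 = k * piT * piE * psi;
        c10 = k * piT * (1.0 - piE) * (1.0 - psi);
        c01 = k * (1.0 - piT) * piE * (1.0 - psi);
        c00 = k * (1.0 - piT) * (1.0 - piE) * (1.0 - psi);
      } else if (family == 2) {
        const double d = piE * (1.0 - piE) * piT * (1.0 - piT) * psi;
        c11 = piT * piE + d;
        c10 = piT * (1.0 - piE) - d;
        c01 = (1.0 - piT) * piE - d;
        c00 = (1.0 - piT) * (1.0 - piE) + d;
      } else {
        c11 = piT * piE;
        c10 = piT * (1.0 - piE);
        c01 = (1.0 - piT) * piE;
        c00 = (1.0 - piT) * (1.0 - piE);
      }
      if ((n11 > 0 && c11 <= 0.0) || (n10 > 0 && c10 <= 0.0) ||
          (n01 > 0 && c01 <= 0.0) || (n00 > 0 && c00 <= 0.0))
        return R_NegInf;
      if (n11 > 0) lp += n11 * std::log(c11);
      if (n10 > 0) lp += n10 * std::log(c10);
      if (n01 > 0) lp += n01 * std::log(c01);
      if (n00 > 0) lp += n00 * std::log(c00);
    }
  }
  return lp;
}

// Cholesky factor (lower) of a small SPD matrix, dimension <= 3
void chol_small(const double* a, int m, double* L) {
  for (int i = 0; i < m * m; ++i) L[i] = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = a[i * m + j];
      for (int k = 0; k < j; ++k) s -= L[i * m + k] * L[j * m + k];
      if (i == j) {
        L[i * m + i] = std::sqrt(std::max(s, 1e-12));
      } else {
        L[i * m + j] = s / L[j * m + j];
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List mcmc_sampler_cpp(IntegerMatrix counts, int family, NumericVector prior,
                      int burn_in, int retained, int thin, int adapt_interval,
                      double target_acceptance, bool prior_only) {
  const int npar = (family == 0) ? 5 : 6;
  const int nblock = (family == 0) ? 2 : 3;
  const int block_lo[3] = {0, 2, 5};
  const int block_hi[3] = {1, 4, 5};  // inclusive

  // init: prior means for intercepts/quadratic, slope 1 (log 0),
  // independence value for the association transform
  std::vector<double> th(npar, 0.0);
  th[0] = prior[0];
  th[2] = prior[2];
  th[4] = prior[4];

  std::vector<double> scale(nblock, 0.5);
  double lp = log_post(th, family, counts, prior, prior_only);
  if (!std::isfinite(lp)) stop("non-finite log-posterior at initial values");

  const int total = burn_in + retained * thin;
  NumericMatrix draws(retained, npar);
  std::vector<int> acc(nblock, 0), tries(nblock, 0);   // within adapt window
  std::vector<double> post_acc(nblock, 0.0), post_n(nblock, 0.0);
  std::vector<double> prop(npar);

  // running first/second moments per block for Haario-style covariance
  // adaptation of the proposal (burn-in only)
  std::vector<std::vector<double>> bmean(nblock), bM2(nblock), bL(nblock);
  std::vector<bool> useL(nblock, false);
  std::vector<double> bn(nblock, 0.0);
  for (int b = 0; b < nblock; ++b) {
    const int m = block_hi[b] - block_lo[b] + 1;
    bmean[b].assign(m, 0.0);
    bM2[b].assign(m * m, 0.0);
    bL[b].assign(m * m, 0.0);
  }
  const int cov_warmup = 10 * adapt_interval;  // samples before using cov

  RNGScope rng;
  int kept = 0;
  for (int it = 0; it < total; ++it) {
    const bool adapting = it < burn_in;
    for (int b = 0; b < nblock; ++b) {
      const int m = block_hi[b] - block_lo[b] + 1;
      prop = th;
      if (useL[b]) {
        double z[3];
        for (int j = 0; j < m; ++j) z[j] = norm_rand();
        for (int j = 0; j < m; ++j) {
          double dx = 0.0;
          for (int k = 0; k <= j; ++k) dx += bL[b][j * m + k] * z[k];
          prop[block_lo[b] + j] = th[block_lo[b] + j] + scale[b] * dx;
        }
      } else {
        for (int j = block_lo[b]; j <= block_hi[b]; ++j)
          prop[j] = th[j] + scale[b] * norm_rand();
      }
      const double lp_new = log_post(prop, family, counts, prior, prior_only);
      bool accept = false;
      if (std::isfinite(lp_new) &&
          std::log(unif_rand()) < lp_new - lp) {
        th = prop;
        lp = lp_new;
        accept = true;
      }
      if (adapting) {
        ++tries[b];
        if (accept) ++acc[b];
        // accumulate block moments for the covariance proposal
        bn[b] += 1.0;
        for (int j = 0; j < m; ++j) {
          const double x = th[block_lo[b] + j];
          const double d = x - bmean[b][j];
          bmean[b][j] += d / bn[b];
          for (int k = 0; k <= j; ++k) {
            const double e = th[block_lo[b] + k] - bmean[b][k];
            bM2[b][j * m + k] += d * e;
            if (k != j) bM2[b][k * m + j] = bM2[b][j * m + k];
          }
        }
        if (tries[b] == adapt_interval) {
          const double rate = static_cast<double>(acc[b]) / tries[b];
          scale[b] *= std::exp(rate - target_acceptance);
          scale[b] = std::min(std::max(scale[b], 1e-3), 10.0);
          acc[b] = 0;
          tries[b] = 0;
          if (bn[b] > cov_warmup) {
            std::vector<double> cov(m * m);
            for (int j = 0; j < m * m; ++j)
              cov[j] = bM2[b][j] / (bn[b] - 1.0);
            for (int j = 0; j < m; ++j) cov[j * m + j] += 1e-8;
            chol_small(cov.data(), m, bL[b].data());
            if (!useL[b]) {
              useL[b] = true;
              scale[b] = 2.38 / std::sqrt(static_cast<double>(m));
            }
          }
        }
      } else {
        post_n[b] += 1.0;
        if (accept) post_acc[b] += 1.0;
      }
    }
    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < retained) {
      draws(kept, 0) = th[0];
      draws(kept, 1) = std::exp(th[1]);
      draws(kept, 2) = th[2];
      draws(kept, 3) = std::exp(th[3]);
      draws(kept, 4) = th[4];
      if (family != 0) {
        const double p = expit(th[5]);
        draws(kept, 5) = (family == 1) ? p : 2.0 * p - 1.0;
      }
      ++kept;
    }
  }

  NumericVector acc_rate(nblock), scales(nblock);
  for (int b = 0; b < nblock; ++b) {
    acc_rate[b] = post_n[b] > 0 ? post_acc[b] / post_n[b] : NA_REAL;
    scales[b] = scale[b];
  }
  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate,
                      _["scales"] = scales);
}
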