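#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Half-normal SECR likelihood pieces for a Poisson point process of activity
// centers over a discretized habitat mask.
//
// Classes index the cross of known classes (sex, or solitary/group) and
// latent mixture classes; all mixture bookkeeping (intensities psi_c =
// D_c * pi_c and the individual weight matrix W) is done on the R side.
//
// encounter: 0 = Bernoulli per occasion (proximity detector, effort enters
//            as exponent: p_ks = 1 - (1 - g)^e), 1 = Poisson counts (effort
//            scales the rate: lambda_ks = lambda0 * h * e).
//
// Detections are passed in sparse form: for individual i the entries
// start[i] .. start[i+1]-1 of (dk, dy, de) give detector index (0-based),
// count (binary for Bernoulli) and the effort fraction of that
// detector-occasion. effortTotal[k] is the sum of effort over all
// occasions (it carries the all-zero part of each history).
//
// Returns Lambda (expected number of detected individuals) and the vector
// of per-individual log-integrals log I_i = log( a * sum_m sum_c W_ic
// psi_c Pr(omega_i | m, theta_c) ).

static inline double clamp_prob(double p) {
  if (p < 1e-12) return 1e-12;
  if (p > 1.0 - 1e-12) return 1.0 - 1e-12;
  return p;
}

// [[Rcpp::export]]
List secr_nll_parts_cpp(NumericMatrix mask, NumericMatrix dets,
                        double cellArea, NumericVector effortTotal,
                        int encounter,
                        NumericVector psi, NumericVector g0,
                        NumericVector sigma, NumericVector detOffset,
                        IntegerMatrix W,
                        IntegerVector start, IntegerVector dk,
                        NumericVector dy, NumericVector de) {
  const int M = mask.nrow();
  const int K = dets.nrow();
  const int C = psi.size();
  const int n = W.nrow();

  double Lambda = 0.0;
  NumericVector logI(n);
  std::vector<double> acc(n, R_NegInf);

  // T caches per cell x detector: log(1 - g) (Bernoulli) or log(g) and g
  // (Poisson); logS is log Pr(no detection anywhere | m, c).
  std::vector<double> T((size_t)M * K);
  std::vector<double> logS(M);
  std::vector<double> logPr(M);

  for (int c = 0; c < C; ++c) {
    const double sig2 = 2.0 * sigma[c] * sigma[c];
    std::vector<double> b0(K);
    for (int k = 0; k < K; ++k) {
      if (encounter == 0) {
        double lg = std::log(g0[c] / (1.0 - g0[c])) + detOffset[k];
        b0[k] = 1.0 / (1.0 + std::exp(-lg));
      } else {
        b0[k] = g0[c] * std::exp(detOffset[k]);
      }
    }
    for (int m = 0; m < M; ++m) {
      const double mx = mask(m, 0), my = mask(m, 1);
      double ls = 0.0;
      double *Tm = &T[(size_t)m * K];
      for (int k = 0; k < K; ++k) {
        const double dx = dets(k, 0) - mx, dyy = dets(k, 1) - my;
        const double h = std::exp(-(dx * dx + dyy * dyy) / sig2);
        const double g = b0[k] * h;
        if (encounter == 0) {
          const double l1mg = std::log1p(-clamp_prob(g));
          Tm[k] = l1mg;
          ls += effortTotal[k] * l1mg;
        } else {
          Tm[k] = std::log(g > 1e-300 ? g : 1e-300);
          ls += -g * effortTotal[k];
        }
      }
      logS[m] = ls;
      Lambda += psi[c] * (1.0 - std::exp(ls));
    }
    for (int i = 0; i < n; ++i) {
      if (W(i, c) == 0) continue;
      const int j0 = start[i], j1 = start[i + 1];
      // per-individual terms constant across cells (Poisson count model)
      double ci = 0.0;
      if (encounter == 1) {
        for (int j = j0; j < j1; ++j) {
          ci += dy[j] * std::log(de[j]) - std::lgamma(dy[j] + 1.0);
        }
      }
      double best = R_NegInf;
      for (int m = 0; m < M; ++m) {
        double lp = logS[m];
        const double *Tm = &T[(size_t)m * K];
        if (encounter == 0) {
          for (int j = j0; j < j1; ++j) {
            const double l1mg = Tm[dk[j]];
            const double p = clamp_prob(1.0 - std::exp(de[j] * l1mg));
            lp += std::log(p) - de[j] * l1mg;
          }
        } else {
          for (int j = j0; j < j1; ++j) lp += dy[j] * Tm[dk[j]];
        }
        logPr[m] = lp;
        if (lp > best) best = lp;
      }
      if (!std::isfinite(best)) continue;
      double s = 0.0;
      for (int m = 0; m < M; ++m) s += std::exp(logPr[m] - best);
      const double chunk = std::log(psi[c]) + best + std::log(s) + ci;
      if (acc[i] == R_NegInf) {
        acc[i] = chunk;
      } else {
        const double hi = std::max(acc[i], chunk);
        acc[i] = hi + std::log(std::exp(acc[i] - hi) + std::exp(chunk - hi));
      }
    }
  }
  Lambda *= cellArea;
  for (int i = 0; i < n; ++i) logI[i] = std::log(cellArea) + acc[i];
  return List::create(_["Lambda"] = Lambda, _["logI"] = logI);
}
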