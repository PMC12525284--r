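#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Diploid Li-Stephens forward-backward over a haplotype panel.
//
// Hidden state at each site: an ordered pair (k, l) of panel haplotypes.
// Per-haplotype transition between adjacent markers: stay with 1 - r,
// otherwise jump to a uniformly chosen haplotype (including itself),
// i.e. T = (1 - r) I + (r / K) J. The pair transition is the product of
// the two per-haplotype transitions, so one update step is the rank-one
// transform  T' A T = c^2 A + c d (JA + AJ) + d^2 * sum(A)  with
// c = 1 - r, d = r / K, computable in O(K^2) per site.
//
// Emission: the implied genotype hap(k,s) + hap(l,s) is read through a
// per-allele error channel with error e; missing observations emit a
// constant. Messages are renormalized per site (scaled forward-backward).
//
// hap: K x S matrix of 0/1 alleles; obs: length-S genotype vector with
// values 0/1/2 or NA; returns a 3 x S matrix of per-site genotype
// posteriors.
// [[Rcpp::export]]
NumericMatrix hmm_genotype_posterior_cpp(IntegerMatrix hap, IntegerVector obs,
                                         double switch_rate, double emit_error) {
  const int K = hap.nrow();
  const int S = hap.ncol();
  if (K < 1 || S < 1) stop("empty panel or map");
  const double c = 1.0 - switch_rate;
  const double d = switch_rate / K;
  const double e = emit_error;

  // emit[o][g] = P(observe o | true genotype g), per-allele error model
  double emit[3][3];
  emit[0][0] = (1 - e) * (1 - e); emit[1][0] = 2 * e * (1 - e); emit[2][0] = e * e;
  emit[0][1] = e * (1 - e); emit[1][1] = (1 - e) * (1 - e) + e * e; emit[2][1] = e * (1 - e);
  emit[0][2] = e * e; emit[1][2] = 2 * e * (1 - e); emit[2][2] = (1 - e) * (1 - e);

  const int KK = K * K;
  std::vector<double> fwd((size_t)KK * S);
  std::vector<double> cur(KK), nxt(KK), rowsum(K), colsum(K);

  auto emission = [&](int s, std::vector<double>& out) {
    int o = obs[s];
    if (o == NA_INTEGER) {
      std::fill(out.begin(), out.end(), 1.0);
      return;
    }
    for (int l = 0; l < K; ++l) {
      int hl = hap(l, s);
      for (int k = 0; k < K; ++k) {
        out[(size_t)l * K + k] = emit[o][hap(k, s) + hl];
      }
    }
  };

  auto transform = [&](const std::vector<double>& a, std::vector<double>& out) {
    // out = T' A T with A indexed [l * K + k] (column l, row k)
    double tot = 0.0;
    std::fill(rowsum.begin(), rowsum.end(), 0.0);
    std::fill(colsum.begin(), colsum.end(), 0.0);
    for (int l = 0; l < K; ++l) {
      for (int k = 0; k < K; ++k) {
        double v = a[(size_t)l * K + k];
        rowsum[k] += v;
        colsum[l] += v;
        tot += v;
      }
    }
    for (int l = 0; l < K; ++l) {
      for (int k = 0; k < K; ++k) {
        out[(size_t)l * K + k] = c * c * a[(size_t)l * K + k] +
          c * d * (rowsum[k] + colsum[l]) + d * d * tot;
      }
    }
  };

  auto normalize = [&](std::vector<double>& a) {
    double tot = 0.0;
    for (double v : a) tot += v;
    if (tot <= 0.0) stop("forward-backward underflow: zero message");
    for (double& v : a) v /= tot;
  };

  std::vector<double> em(KK);

  // forward
  emission(0, em);
  for (int i = 0; i < KK; ++i) cur[i] = em[i] / KK;
  normalize(cur);
  std::copy(cur.begin(), cur.end(), fwd.begin());
  for (int s = 1; s < S; ++s) {
    transform(cur, nxt);
    emission(s, em);
    for (int i = 0; i < KK; ++i) nxt[i] *= em[i];
    normalize(nxt);
    std::swap(cur, nxt);
    std::copy(cur.begin(), cur.end(), fwd.begin() + (size_t)KK * s);
  }

  // backward, combining with stored forward messages on the fly
  NumericMatrix post(3, S);
  std::vector<double> bwd(KK, 1.0), comb(KK);
  for (int s = S - 1; s >= 0; --s) {
    for (int i = 0; i < KK; ++i) comb[i] = fwd[(size_t)KK * s + i] * bwd[i];
    normalize(comb);
    double g[3] = {0.0, 0.0, 0.0};
    for (int l = 0; l < K; ++l) {
      int hl = hap(l, s);
      for (int k = 0; k < K; ++k) {
        g[hap(k, s) + hl] += comb[(size_t)l * K + k];
      }
    }
    post(0, s) = g[0]; post(1, s) = g[1]; post(2, s) = g[2];
    if (s > 0) {
      emission(s, em);
      for (int i = 0; i < KK; ++i) nxt[i] = em[i] * bwd[i];
      transform(nxt, bwd);
      normalize(bwd);
    }
  }
  return post;
}
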