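#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Batch evaluation of aggregated isotopic distributions by the power-sum
// recurrences. Inputs are per-element coefficient tables (rows aligned
// with the columns of `counts`):
//   L(e, l-1): series-log coefficients of P_e(x)/a_e0, l = 1..K-1
//   G(e, l):   series coefficients of R_e(x)/P_e(x), l = 0..K-1
//   logA0(e):  log abundance of the lightest isotope
//   mono(e):   lightest-isotope mass
// For each molecule: lambda_l = sum_e n_e L(e,l) and gamma_l likewise are
// linear in the counts; q follows from the series-exponential recurrence
// j*q_j = sum_{l=1..j} l*lambda_l*q_{j-l}, and the mass moments are the
// convolution eta_j = sum_{l=0..j} gamma_l * q_{j-l}, with center masses
// mu_j = eta_j / q_j.

static void brain_one(const int* n, int E, int K,
                      const NumericMatrix& L, const NumericMatrix& G,
                      const NumericVector& logA0, const NumericVector& mono,
                      double* q, double* eta, double* m0) {
  std::vector<double> lam(K, 0.0), gam(K, 0.0);
  double lq0 = 0.0, mm = 0.0;
  for (int e = 0; e < E; ++e) {
    if (n[e] == 0) continue;
    double ne = (double)n[e];
    lq0 += ne * logA0[e];
    mm += ne * mono[e];
    for (int l = 1; l < K; ++l) lam[l] += ne * L(e, l - 1);
    for (int l = 0; l < K; ++l) gam[l] += ne * G(e, l);
  }
  q[0] = std::exp(lq0);
  for (int j = 1; j < K; ++j) {
    double s = 0.0;
    for (int l = 1; l <= j; ++l) s += l * lam[l] * q[j - l];
    q[j] = s / j;
  }
  for (int j = 0; j < K; ++j) {
    double s = 0.0;
    for (int l = 0; l <= j; ++l) s += gam[l] * q[j - l];
    eta[j] = s;
  }
  *m0 = mm;
}

// [[Rcpp::export]]
NumericMatrix brain_summaries_cpp(IntegerMatrix counts, NumericMatrix L,
                                  NumericMatrix G, NumericVector logA0,
                                  NumericVector mono, int K) {
  int N = counts.nrow(), E = counts.ncol();
  NumericMatrix out(N, 6);
  std::vector<double> q(K), eta(K);
  std::vector<int> n(E);
  for (int i = 0; i < N; ++i) {
    for (int e = 0; e < E; ++e) n[e] = counts(i, e);
    double m0;
    brain_one(n.data(), E, K, L, G, logA0, mono, q.data(), eta.data(), &m0);
    int mode = 0;
    double qmax = q[0], sq = 0.0, se = 0.0;
    for (int j = 0; j < K; ++j) {
      if (q[j] > qmax) { qmax = q[j]; mode = j; }  // ties -> lower offset
      sq += q[j];
      se += eta[j];
    }
    out(i, 0) = m0;                       // monoisotopic mass
    out(i, 1) = mode;                     // most-abundant offset
    out(i, 2) = eta[mode] / q[mode];      // most-abundant center mass
    out(i, 3) = se / sq;                  // intensity-weighted average mass
    out(i, 4) = sq;                       // truncation mass conservation
    out(i, 5) = q[0] / qmax;              // mono-to-mode intensity ratio
  }
  return out;
}

// [[Rcpp::export]]
List brain_full_cpp(IntegerMatrix counts, NumericMatrix L, NumericMatrix G,
                    NumericVector logA0, NumericVector mono, int K) {
  int N = counts.nrow(), E = counts.ncol();
  NumericMatrix qm(N, K), mum(N, K);
  std::vector<double> q(K), eta(K);
  std::vector<int> n(E);
  for (int i = 0; i < N; ++i) {
    for (int e = 0; e < E; ++e) n[e] = counts(i, e);
    double m0;
    brain_one(n.data(), E, K, L, G, logA0, mono, q.data(), eta.data(), &m0);
    double qmax = 0.0;
    for (int j = 0; j < K; ++j) if (q[j] > qmax) qmax = q[j];
    double prev = m0 - 1.003;
    for (int j = 0; j < K; ++j) {
      double qj = q[j] > qmax * 1e-13 ? q[j] : 0.0;
      qm(i, j) = qj;
      mum(i, j) = qj > 0.0 ? eta[j] / q[j] : prev + 1.003;
      prev = mum(i, j);
    }
  }
  return List::create(Named("q") = qm, Named("mu") = mum);
}
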