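#include <Rcpp.h>
using namespace Rcpp;

// HMM recursions for a K-state chain with a sticky, exchangeable transition
// kernel: P(j -> j) = rho, P(j -> k != j) = (1 - rho) / (K - 1).  The rank-1
// structure makes each step O(K).  Chains restart (uniform initial
// distribution) at chromosome boundaries given by `chrom` (any change of
// value starts a new chain).

// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logE, double rho, IntegerVector chrom) {
  const int N = logE.nrow(), K = logE.ncol();
  if (N == 0) stop("empty chain");
  const double u = (K > 1) ? (1.0 - rho) / (K - 1) : 1.0;
  const double s = rho - u;  // T = s*I + u*11'

  NumericMatrix alpha(N, K), beta(N, K), gamma(N, K);
  std::vector<double> emax(N);
  double loglik = 0.0;

  // scaled emissions e_t(j) = exp(logE - rowmax)
  NumericMatrix E(N, K);
  for (int t = 0; t < N; ++t) {
    double m = logE(t, 0);
    for (int j = 1; j < K; ++j) if (logE(t, j) > m) m = logE(t, j);
    emax[t] = m;
    for (int j = 0; j < K; ++j) E(t, j) = std::exp(logE(t, j) - m);
  }

  // forward
  for (int t = 0; t < N; ++t) {
    bool newchain = (t == 0) || (chrom[t] != chrom[t - 1]);
    double c = 0.0;
    if (newchain) {
      for (int j = 0; j < K; ++j) { alpha(t, j) = E(t, j) / K; c += alpha(t, j); }
    } else {
      double tot = 0.0;
      for (int j = 0; j < K; ++j) tot += alpha(t - 1, j);
      for (int j = 0; j < K; ++j) {
        alpha(t, j) = E(t, j) * (s * alpha(t - 1, j) + u * tot);
        c += alpha(t, j);
      }
    }
    if (c <= 0 || !R_finite(c)) stop("numerical failure in forward pass");
    for (int j = 0; j < K; ++j) alpha(t, j) /= c;
    loglik += std::log(c) + emax[t];
  }

  // backward
  for (int t = N - 1; t >= 0; --t) {
    bool chainend = (t == N - 1) || (chrom[t + 1] != chrom[t]);
    if (chainend) {
      for (int j = 0; j < K; ++j) beta(t, j) = 1.0;
    } else {
      double tot = 0.0, c = 0.0;
      std::vector<double> eb(K);
      for (int j = 0; j < K; ++j) { eb[j] = E(t + 1, j) * beta(t + 1, j); tot += eb[j]; }
      for (int j = 0; j < K; ++j) { beta(t, j) = s * eb[j] + u * tot; c += beta(t, j); }
      for (int j = 0; j < K; ++j) beta(t, j) /= c;
    }
  }

  for (int t = 0; t < N; ++t) {
    double c = 0.0;
    for (int j = 0; j < K; ++j) { gamma(t, j) = alpha(t, j) * beta(t, j); c += gamma(t, j); }
    for (int j = 0; j < K; ++j) gamma(t, j) /= c;
  }

  return List::create(_["gamma"] = gamma, _["loglik"] = loglik);
}

// Viterbi decoding.  `pref` is a permutation of 0..K-1; on exact ties the
// state earliest in `pref` wins (used to break ties toward NEUT), and on a
// stay-vs-switch tie the path stays (fewest segments).
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logE, double rho, IntegerVector chrom,
                          IntegerVector pref) {
  const int N = logE.nrow(), K = logE.ncol();
  if (N == 0) stop("empty chain");
  if (K == 1) return IntegerVector(N, 1);
  const double lrho = std::log(rho), lu = std::log((1.0 - rho) / (K - 1));
  const double linit = -std::log((double)K);

  NumericMatrix delta(N, K);
  IntegerMatrix bp(N, K);
  IntegerVector path(N);

  for (int t = 0; t < N; ++t) {
    bool newchain = (t == 0) || (chrom[t] != chrom[t - 1]);
    if (newchain) {
      for (int j = 0; j < K; ++j) { delta(t, j) = linit + logE(t, j); bp(t, j) = -1; }
      continue;
    }
    // best and runner-up of delta(t-1, .) in pref order
    int arg1 = -1, arg2 = -1;
    double m1 = R_NegInf, m2 = R_NegInf;
    for (int r = 0; r < K; ++r) {
      int j = pref[r];
      double v = delta(t - 1, j);
      if (v > m1) { m2 = m1; arg2 = arg1; m1 = v; arg1 = j; }
      else if (v > m2) { m2 = v; arg2 = j; }
    }
    for (int j = 0; j < K; ++j) {
      double stay = lrho + delta(t - 1, j);
      double jumpv; int jumpfrom;
      if (j != arg1) { jumpv = lu + m1; jumpfrom = arg1; }
      else           { jumpv = lu + m2; jumpfrom = arg2; }
      if (stay >= jumpv) { delta(t, j) = stay + logE(t, j); bp(t, j) = j; }
      else               { delta(t, j) = jumpv + logE(t, j); bp(t, j) = jumpfrom; }
    }
  }

  // backtrack per chain
  int t = N - 1;
  while (t >= 0) {
    int cstart = t;
    while (cstart > 0 && chrom[cstart - 1] == chrom[t]) --cstart;
    int best = pref[0];
    for (int r = 0; r < K; ++r) {
      int j = pref[r];
      if (delta(t, j) > delta(t, best)) best = j;
    }
    path[t] = best;
    for (int tt = t; tt > cstart; --tt) path[tt - 1] = bp(tt, path[tt]);
    t = cstart - 1;
  }
  for (int i = 0; i < N; ++i) path[i] += 1;  // 1-based for R
  return path;
}
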