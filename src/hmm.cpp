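#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a set of independent two-state chains sharing
// one parameter set. Each chain restarts from the initial distribution.
//
// logB: (total bins) x 2 emission log-probabilities, genes concatenated
// lens: bins per gene (sums to nrow(logB))
// pi2:  initial state distribution (P(z=1), P(z=2))
// A:    2x2 row-stochastic transition matrix
//
// Per-position rescaling: emissions are exponentiated relative to their row
// maximum so at least one state has weight 1; the subtracted maxima are added
// back into the log-likelihood through the scaling constants.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logB, IntegerVector lens,
            NumericVector pi2, NumericMatrix A) {
  const int total = logB.nrow();
  const int G = lens.size();
  NumericMatrix gamma(total, 2);
  // transition posteriors, rows index transitions (total - G of them),
  // columns are the 2x2 cells in column-major order: (1,1),(2,1),(1,2),(2,2)
  NumericMatrix eps(total - G, 4);
  NumericVector loglik(G);

  std::vector<double> a1(total), a2(total), c(total), b1(total), b2(total);
  int off = 0, eoff = 0;
  for (int g = 0; g < G; ++g) {
    const int N = lens[g];
    // forward with scaling
    for (int n = 0; n < N; ++n) {
      const int i = off + n;
      const double bmax = std::max(logB(i, 0), logB(i, 1));
      b1[i] = std::exp(logB(i, 0) - bmax);
      b2[i] = std::exp(logB(i, 1) - bmax);
      double f1, f2;
      if (n == 0) {
        f1 = pi2[0] * b1[i];
        f2 = pi2[1] * b2[i];
      } else {
        f1 = (a1[i - 1] * A(0, 0) + a2[i - 1] * A(1, 0)) * b1[i];
        f2 = (a1[i - 1] * A(0, 1) + a2[i - 1] * A(1, 1)) * b2[i];
      }
      double cn = f1 + f2;
      if (cn <= 0) { cn = 1e-300; }
      a1[i] = f1 / cn;
      a2[i] = f2 / cn;
      c[i] = cn;
      loglik[g] += std::log(cn) + bmax;
    }
    // backward (scaled), gamma and transition posteriors
    double be1 = 1.0, be2 = 1.0;
    gamma(off + N - 1, 0) = a1[off + N - 1];
    gamma(off + N - 1, 1) = a2[off + N - 1];
    for (int n = N - 2; n >= 0; --n) {
      const int i = off + n, ip = i + 1;
      const double u1 = b1[ip] * be1, u2 = b2[ip] * be2;
      // epsilon for transition n -> n+1
      const double inv_c = 1.0 / c[ip];
      eps(eoff + n, 0) = a1[i] * A(0, 0) * u1 * inv_c;  // j=1,k=1
      eps(eoff + n, 1) = a2[i] * A(1, 0) * u1 * inv_c;  // j=2,k=1
      eps(eoff + n, 2) = a1[i] * A(0, 1) * u2 * inv_c;  // j=1,k=2
      eps(eoff + n, 3) = a2[i] * A(1, 1) * u2 * inv_c;  // j=2,k=2
      const double nb1 = (A(0, 0) * u1 + A(0, 1) * u2) * inv_c;
      const double nb2 = (A(1, 0) * u1 + A(1, 1) * u2) * inv_c;
      be1 = nb1;
      be2 = nb2;
      double g1 = a1[i] * be1, g2 = a2[i] * be2;
      const double s = g1 + g2;  // guard tiny drift
      gamma(i, 0) = g1 / s;
      gamma(i, 1) = g2 / s;
    }
    off += N;
    eoff += N - 1;
  }
  return List::create(_["gamma"] = gamma, _["epsilon"] = eps,
                      _["loglik"] = loglik);
}

// Viterbi MAP decoding for concatenated chains; ties broken toward state 1
// (unmethylated) at every comparison.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logB, IntegerVector lens,
                          NumericVector log_pi2, NumericMatrix logA) {
  const int total = logB.nrow();
  const int G = lens.size();
  IntegerVector path(total);
  std::vector<double> d1(total), d2(total);
  std::vector<int> bp1(total), bp2(total);
  int off = 0;
  for (int g = 0; g < G; ++g) {
    const int N = lens[g];
    d1[off] = log_pi2[0] + logB(off, 0);
    d2[off] = log_pi2[1] + logB(off, 1);
    for (int n = 1; n < N; ++n) {
      const int i = off + n;
      const double s11 = d1[i - 1] + logA(0, 0), s21 = d2[i - 1] + logA(1, 0);
      const double s12 = d1[i - 1] + logA(0, 1), s22 = d2[i - 1] + logA(1, 1);
      if (s11 >= s21) { d1[i] = s11 + logB(i, 0); bp1[i] = 1; }
      else            { d1[i] = s21 + logB(i, 0); bp1[i] = 2; }
      if (s12 >= s22) { d2[i] = s12 + logB(i, 1); bp2[i] = 1; }
      else            { d2[i] = s22 + logB(i, 1); bp2[i] = 2; }
    }
    int last = off + N - 1;
    int st = (d1[last] >= d2[last]) ? 1 : 2;
    path[last] = st;
    for (int n = N - 1; n >= 1; --n) {
      const int i = off + n;
      st = (st == 1) ? bp1[i] : bp2[i];
      path[i - 1] = st;
    }
    off += N;
  }
  return path;
}
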