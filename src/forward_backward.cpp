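#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a discrete-time HMM.
//
// logB: T x K matrix of per-time log emission densities (channels already
//       multiplied together).  A: K x K row-stochastic transition matrix.
//       pi0: initial state distribution.
//
// Returns log-likelihood, smoothing posteriors gamma (T x K), and the
// expected transition-count matrix xi (K x K, summed over time), which is
// all the Baum-Welch M-step needs.  Per-time scaling keeps the recursion
// finite for traces of 10^4-10^5 steps.
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix logB, NumericMatrix A,
                          NumericVector pi0) {
  const int T = logB.nrow();
  const int K = logB.ncol();

  NumericMatrix alpha(T, K);   // scaled forward variables
  NumericMatrix beta(T, K);    // scaled backward variables
  NumericVector cvec(T);       // per-time scaling constants
  NumericMatrix B(T, K);       // emission densities, rescaled per time step
  NumericVector bmax(T);

  // Rescale emissions so the largest density each time step is 1; the
  // shift is restored in the log-likelihood accumulation.
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    bmax[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }

  // Forward pass
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = pi0[k] * B(0, k);
    c0 += alpha(0, k);
  }
  if (c0 <= 0.0) stop("zero forward probability at t=1");
  cvec[0] = c0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;

  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * A(j, k);
      double v = s * B(t, k);
      alpha(t, k) = v;
      ct += v;
    }
    if (ct <= 0.0) stop("zero forward probability at t=%d", t + 1);
    cvec[t] = ct;
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(cvec[t]) + bmax[t];

  // Backward pass
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = s / cvec[t + 1];
    }
  }

  // Posteriors and expected transition counts
  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      s += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      if (alpha(t, j) == 0.0) continue;
      for (int k = 0; k < K; ++k) {
        if (A(j, k) == 0.0) continue;
        xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) *
                    beta(t + 1, k) / cvec[t + 1];
      }
    }
  }

  return List::create(_["loglik"] = loglik,
                      _["gamma"] = gamma,
                      _["xi"] = xi);
}

// Log-likelihood only (no posteriors); used by confidence-interval scans
// where only the scalar is needed.
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix logB, NumericMatrix A,
                          NumericVector pi0) {
  const int T = logB.nrow();
  const int K = logB.ncol();
  std::vector<double> a(K), anew(K);

  double loglik = 0.0;
  double m = logB(0, 0);
  for (int k = 1; k < K; ++k) if (logB(0, k) > m) m = logB(0, k);
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) {
    a[k] = pi0[k] * std::exp(logB(0, k) - m);
    c0 += a[k];
  }
  if (c0 <= 0.0) stop("zero forward probability at t=1");
  for (int k = 0; k < K; ++k) a[k] /= c0;
  loglik += std::log(c0) + m;

  for (int t = 1; t < T; ++t) {
    m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += a[j] * A(j, k);
      anew[k] = s * std::exp(logB(t, k) - m);
      ct += anew[k];
    }
    if (ct <= 0.0) stop("zero forward probability at t=%d", t + 1);
    for (int k = 0; k < K; ++k) a[k] = anew[k] / ct;
    loglik += std::log(ct) + m;
  }
  return loglik;
}
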