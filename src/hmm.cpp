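#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a 2-state HMM.
// dens: T x 2 matrix of emission densities per state.
// Returns gamma (T x 2), summed xi (2 x 2) and the log-likelihood.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix dens, NumericVector init,
                          NumericMatrix trans) {
  int T = dens.nrow();
  const int S = 2;
  NumericMatrix alpha(T, S), beta(T, S), gamma(T, S);
  NumericVector scale(T);
  double ll = 0.0;

  for (int s = 0; s < S; ++s) alpha(0, s) = init[s] * dens(0, s);
  scale[0] = alpha(0, 0) + alpha(0, 1);
  if (scale[0] <= 0) scale[0] = 1e-300;
  for (int s = 0; s < S; ++s) alpha(0, s) /= scale[0];
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double a = alpha(t - 1, 0) * trans(0, s) + alpha(t - 1, 1) * trans(1, s);
      alpha(t, s) = a * dens(t, s);
    }
    scale[t] = alpha(t, 0) + alpha(t, 1);
    if (scale[t] <= 0) scale[t] = 1e-300;
    for (int s = 0; s < S; ++s) alpha(t, s) /= scale[t];
  }
  for (int t = 0; t < T; ++t) ll += std::log(scale[t]);

  beta(T - 1, 0) = beta(T - 1, 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int s = 0; s < S; ++s) {
      double b = 0.0;
      for (int r = 0; r < S; ++r)
        b += trans(s, r) * dens(t + 1, r) * beta(t + 1, r);
      beta(t, s) = b / scale[t + 1];
    }
  }

  NumericMatrix xi(S, S);
  for (int t = 0; t < T; ++t) {
    double norm = alpha(t, 0) * beta(t, 0) + alpha(t, 1) * beta(t, 1);
    if (norm <= 0) norm = 1e-300;
    for (int s = 0; s < S; ++s) gamma(t, s) = alpha(t, s) * beta(t, s) / norm;
  }
  for (int t = 0; t < T - 1; ++t) {
    double denom = 0.0;
    double raw[2][2];
    for (int s = 0; s < S; ++s)
      for (int r = 0; r < S; ++r) {
        raw[s][r] = alpha(t, s) * trans(s, r) * dens(t + 1, r) * beta(t + 1, r);
        denom += raw[s][r];
      }
    if (denom <= 0) denom = 1e-300;
    for (int s = 0; s < S; ++s)
      for (int r = 0; r < S; ++r) xi(s, r) += raw[s][r] / denom;
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// Viterbi path (log space) for a 2-state HMM; returns 1-based states.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix dens, NumericVector init,
                          NumericMatrix trans) {
  int T = dens.nrow();
  const int S = 2;
  NumericMatrix delta(T, S);
  IntegerMatrix psi(T, S);
  const double NEG = -1e300;
  auto lg = [](double x) { return x > 0 ? std::log(x) : -1e300; };
  for (int s = 0; s < S; ++s) delta(0, s) = lg(init[s]) + lg(dens(0, s));
  for (int t = 1; t < T; ++t)
    for (int s = 0; s < S; ++s) {
      double best = NEG;
      int arg = 0;
      for (int r = 0; r < S; ++r) {
        double v = delta(t - 1, r) + lg(trans(r, s));
        if (v > best) { best = v; arg = r; }
      }
      delta(t, s) = best + lg(dens(t, s));
      psi(t, s) = arg;
    }
  IntegerVector path(T);
  path[T - 1] = delta(T - 1, 1) > delta(T - 1, 0) ? 1 : 0;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;
}
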