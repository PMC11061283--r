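#include <Rcpp.h>
using namespace Rcpp;

// Baum-Welch for a two-state (Human/Archaic) hidden Markov model with
// Poisson emissions over one window-count sequence. State 2 is oriented to
// the higher rate on return. Scaled forward-backward; log-likelihood
// convergence.
// [[Rcpp::export]]
List baum_welch_poisson(IntegerVector counts, double lam1, double lam2,
                        double a11, double a22, double pi1,
                        int max_iter, double tol) {
  int T = counts.size();
  std::vector<double> al1(T), al2(T), sc(T), e1(T), e2(T), g1(T), g2(T);
  double ll = R_NegInf, ll_old = R_NegInf;
  for (int it = 0; it < max_iter; ++it) {
    for (int t = 0; t < T; ++t) {
      e1[t] = std::max(R::dpois(counts[t], lam1, 0), 1e-300);
      e2[t] = std::max(R::dpois(counts[t], lam2, 0), 1e-300);
    }
    // forward
    double a1 = pi1 * e1[0], a2 = (1.0 - pi1) * e2[0];
    sc[0] = a1 + a2; al1[0] = a1 / sc[0]; al2[0] = a2 / sc[0];
    for (int t = 1; t < T; ++t) {
      a1 = (al1[t - 1] * a11 + al2[t - 1] * (1.0 - a22)) * e1[t];
      a2 = (al1[t - 1] * (1.0 - a11) + al2[t - 1] * a22) * e2[t];
      sc[t] = a1 + a2; al1[t] = a1 / sc[t]; al2[t] = a2 / sc[t];
    }
    // backward + accumulators
    double b1 = 1.0, b2 = 1.0;
    double x11 = 0, x12 = 0, x21 = 0, x22 = 0;
    double gg = al1[T - 1] + al2[T - 1];
    g1[T - 1] = al1[T - 1] / gg; g2[T - 1] = al2[T - 1] / gg;
    for (int t = T - 2; t >= 0; --t) {
      double e1b1 = e1[t + 1] * b1 / sc[t + 1];
      double e2b2 = e2[t + 1] * b2 / sc[t + 1];
      x11 += al1[t] * a11 * e1b1;
      x12 += al1[t] * (1.0 - a11) * e2b2;
      x21 += al2[t] * (1.0 - a22) * e1b1;
      x22 += al2[t] * a22 * e2b2;
      b1 = a11 * e1b1 + (1.0 - a11) * e2b2;
      b2 = (1.0 - a22) * e1b1 + a22 * e2b2;
      double u1 = al1[t] * b1, u2 = al2[t] * b2;
      g1[t] = u1 / (u1 + u2); g2[t] = u2 / (u1 + u2);
    }
    ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(sc[t]);
    double s1 = 0, s2 = 0, c1 = 0, c2 = 0;
    for (int t = 0; t < T; ++t) {
      s1 += g1[t]; s2 += g2[t];
      c1 += g1[t] * counts[t]; c2 += g2[t] * counts[t];
    }
    lam1 = c1 / std::max(s1, 1e-300);
    lam2 = c2 / std::max(s2, 1e-300);
    a11 = x11 / std::max(x11 + x12, 1e-300);
    a22 = x22 / std::max(x21 + x22, 1e-300);
    pi1 = g1[0];
    if (std::fabs(ll - ll_old) < tol) break;
    ll_old = ll;
  }
  NumericVector post(T);
  bool swap = lam2 < lam1;
  for (int t = 0; t < T; ++t) post[t] = swap ? g1[t] : g2[t];
  double lo = swap ? lam2 : lam1, hi = swap ? lam1 : lam2;
  return List::create(_["lambda"] = NumericVector::create(lo, hi),
                      _["posterior"] = post, _["loglik"] = ll,
                      _["degenerate"] = std::fabs(hi - lo) < 1e-6);
}
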