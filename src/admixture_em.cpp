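// EM updates for the admixture likelihood.
//
// Model: called dosage g_il ~ Binomial(2, f_il), f_il = sum_k q_ik p_kl.
// The E-step attributes each ALT (and REF) allele copy to an ancestral
// population; the M-step re-normalises the expected counts. Missing
// genotypes carry zero weight throughout. P is clamped away from {0,1} so
// the log-likelihood stays finite. The update is one fused pass over the
// genotype matrix with an inner loop over populations (O(n L K) per
// iteration); the homozygote branches skip the zero-weight half of the
// E-step, which matters in highly inbred panels where heterozygotes are
// rare.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".admixture_em_cpp")]]
Rcpp::List admixture_em_cpp(const arma::mat& G0, const arma::mat& G2,
                            const arma::vec& ncall2, arma::mat Q,
                            arma::mat P, int max_iter, double tol) {
  const uword n = G0.n_rows, L = G0.n_cols, K = Q.n_cols;
  const double pmin_ = 1e-6, pmax_ = 1.0 - 1e-6;
  const double fmin_ = 1e-9, fmax_ = 1.0 - 1e-9;

  std::vector<double> trace;
  trace.reserve(max_iter + 2);
  mat Qn(n, K), Pnum(K, L), Pden(K, L);
  std::vector<double> pl(K), cpl(K);

  auto eval_ll = [&]() {
    double ll = 0.0;
    for (uword l = 0; l < L; ++l) {
      for (uword k = 0; k < K; ++k) pl[k] = P(k, l);
      for (uword i = 0; i < n; ++i) {
        double g0 = G0(i, l), g2 = G2(i, l);
        if (g0 == 0.0 && g2 == 0.0) continue;  // missing
        double f = 0.0;
        for (uword k = 0; k < K; ++k) f += Q(i, k) * pl[k];
        f = std::min(std::max(f, fmin_), fmax_);
        if (g0 != 0.0) ll += g0 * std::log(f);
        if (g2 != 0.0) ll += g2 * std::log1p(-f);
      }
    }
    return ll;
  };

  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    Qn.zeros();
    Pnum.zeros();
    Pden.zeros();
    // likelihood of the incoming parameters falls out of the same pass
    double ll = 0.0;
    for (uword l = 0; l < L; ++l) {
      for (uword k = 0; k < K; ++k) {
        pl[k] = P(k, l);
        cpl[k] = 1.0 - pl[k];
      }
      for (uword i = 0; i < n; ++i) {
        const double g0 = G0(i, l), g2 = G2(i, l);
        if (g0 == 0.0 && g2 == 0.0) continue;
        double f = 0.0;
        for (uword k = 0; k < K; ++k) f += Q(i, k) * pl[k];
        f = std::min(std::max(f, fmin_), fmax_);
        if (g0 == 0.0) {                    // REF homozygote (usual case)
          ll += g2 * std::log1p(-f);
          const double wb = g2 / (1.0 - f);
          for (uword k = 0; k < K; ++k) {
            const double b = wb * Q(i, k) * cpl[k];
            Qn(i, k) += b;
            Pden(k, l) += b;
          }
        } else if (g2 == 0.0) {             // ALT homozygote
          ll += g0 * std::log(f);
          const double wa = g0 / f;
          for (uword k = 0; k < K; ++k) {
            const double a = wa * Q(i, k) * pl[k];
            Qn(i, k) += a;
            Pnum(k, l) += a;
            Pden(k, l) += a;
          }
        } else {                            // heterozygote
          ll += g0 * std::log(f) + g2 * std::log1p(-f);
          const double wa = g0 / f, wb = g2 / (1.0 - f);
          for (uword k = 0; k < K; ++k) {
            const double q = Q(i, k);
            const double a = wa * q * pl[k];
            const double b = wb * q * cpl[k];
            Qn(i, k) += a + b;
            Pnum(k, l) += a;
            Pden(k, l) += a + b;
          }
        }
      }
    }
    for (uword k = 0; k < K; ++k)
      for (uword i = 0; i < n; ++i) Qn(i, k) /= ncall2(i);
    for (uword i = 0; i < n; ++i) {
      double s = 0.0;
      for (uword k = 0; k < K; ++k) s += Qn(i, k);
      for (uword k = 0; k < K; ++k) Qn(i, k) /= s;
    }
    Q = Qn;
    for (uword l = 0; l < L; ++l)
      for (uword k = 0; k < K; ++k) {
        double d = Pden(k, l);
        double p = d > 1e-12 ? Pnum(k, l) / d : 0.5;
        P(k, l) = std::min(std::max(p, pmin_), pmax_);
      }
    trace.push_back(ll);
    if (it > 1 && ll - trace[it - 2] < tol) {
      converged = true;
      break;
    }
  }
  trace.push_back(eval_ll());  // likelihood of the returned parameters
  return Rcpp::List::create(
    Rcpp::Named("Q") = Q, Rcpp::Named("P") = P,
    Rcpp::Named("trace") = trace, Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = it);
}
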