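#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mean-field variational inference for LDA documents with a fixed
// row-stochastic topic-word matrix.
//
// For each document d with word ids w (0-based into the vocabulary) and
// counts c: initialize responsibilities uniformly (equivalently gamma_k =
// alpha_k + N_d/K), then iterate
//   phi_wk  ∝ exp(digamma(gamma_k)) * beta_kw
//   gamma_k = alpha_k + sum_w c_w phi_wk
// until the mean absolute change in gamma drops below tol (or max_inner).
//
// The returned per-document bound is, at the final gamma with phi set to
// its optimum for that gamma,
//   L_d = lgamma(sum alpha) - sum lgamma(alpha) - lgamma(sum gamma)
//       + sum lgamma(gamma) + sum_k (alpha_k - gamma_k) dg_k
//       + sum_w c_w * logsumexp_k(dg_k + log beta_kw)
// where dg_k = digamma(gamma_k) - digamma(sum gamma). This is a valid
// lower bound on log p(doc | beta, alpha). Sufficient statistics for the
// M-step use the same optimal phi.

// gamma_init: optional D x K warm start (makes the outer EM a true
// coordinate ascent and cuts inner iterations drastically); when absent
// each document starts from uniform responsibilities.
// [[Rcpp::export]]
List lda_estep(List ids_list, List cnt_list, NumericMatrix log_beta,
               NumericVector alpha, int max_inner, double inner_tol,
               bool compute_ss,
               Nullable<NumericMatrix> gamma_init = R_NilValue) {
  const int D = ids_list.size();
  const int K = log_beta.nrow();
  const int V = log_beta.ncol();

  NumericMatrix gamma_out(D, K);
  NumericMatrix ss;
  if (compute_ss) ss = NumericMatrix(K, V);
  double bound = 0.0;

  double alpha_sum = 0.0, lg_alpha = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha_sum += alpha[k];
    lg_alpha += R::lgammafn(alpha[k]);
  }
  const double alpha_const = R::lgammafn(alpha_sum) - lg_alpha;

  NumericMatrix ginit;
  const bool warm = gamma_init.isNotNull();
  if (warm) ginit = NumericMatrix(gamma_init);

  std::vector<double> gam(K), dg(K), lp(K);

  for (int d = 0; d < D; ++d) {
    IntegerVector ids = ids_list[d];
    NumericVector cnt = cnt_list[d];
    const int W = ids.size();
    double Nd = 0.0;
    for (int w = 0; w < W; ++w) Nd += cnt[w];

    if (warm) for (int k = 0; k < K; ++k) gam[k] = ginit(d, k);
    else      for (int k = 0; k < K; ++k) gam[k] = alpha[k] + Nd / K;

    for (int it = 0; it < max_inner; ++it) {
      double gsum = 0.0;
      for (int k = 0; k < K; ++k) gsum += gam[k];
      const double dgs = R::digamma(gsum);
      for (int k = 0; k < K; ++k) dg[k] = R::digamma(gam[k]) - dgs;

      std::vector<double> gnew(K, 0.0);
      for (int w = 0; w < W; ++w) {
        const int v = ids[w];
        double m = R_NegInf;
        for (int k = 0; k < K; ++k) {
          lp[k] = dg[k] + log_beta(k, v);
          if (lp[k] > m) m = lp[k];
        }
        double z = 0.0;
        for (int k = 0; k < K; ++k) { lp[k] = std::exp(lp[k] - m); z += lp[k]; }
        for (int k = 0; k < K; ++k) gnew[k] += cnt[w] * lp[k] / z;
      }
      double delta = 0.0;
      for (int k = 0; k < K; ++k) {
        gnew[k] += alpha[k];
        delta += std::fabs(gnew[k] - gam[k]);
        gam[k] = gnew[k];
      }
      // relative to total mass so the criterion is size-independent
      if (delta / (Nd + alpha_sum) < inner_tol) break;
    }

    // bound at final gamma with phi re-optimized for it
    double gsum = 0.0, lg_gam = 0.0, lin = 0.0;
    for (int k = 0; k < K; ++k) gsum += gam[k];
    const double dgs = R::digamma(gsum);
    for (int k = 0; k < K; ++k) {
      dg[k] = R::digamma(gam[k]) - dgs;
      lg_gam += R::lgammafn(gam[k]);
      lin += (alpha[k] - gam[k]) * dg[k];
    }
    double lik = 0.0;
    for (int w = 0; w < W; ++w) {
      const int v = ids[w];
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        lp[k] = dg[k] + log_beta(k, v);
        if (lp[k] > m) m = lp[k];
      }
      double z = 0.0;
      for (int k = 0; k < K; ++k) { lp[k] = std::exp(lp[k] - m); z += lp[k]; }
      lik += cnt[w] * (m + std::log(z));
      if (compute_ss)
        for (int k = 0; k < K; ++k) ss(k, v) += cnt[w] * lp[k] / z;
    }
    bound += alpha_const - R::lgammafn(gsum) + lg_gam + lin + lik;
    for (int k = 0; k < K; ++k) gamma_out(d, k) = gam[k];
  }

  List out = List::create(Named("gamma") = gamma_out,
                          Named("bound") = bound);
  if (compute_ss) out["ss"] = ss;
  return out;
}
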