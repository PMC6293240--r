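#include <Rcpp.h>
using namespace Rcpp;

// Minka fixed-point step for an asymmetric Dirichlet concentration given
// document-topic counts; shared by the sampler's periodic optimization and
// (through the same formula) the R-level optimizer.
static void minka_step(std::vector<double>& alpha,
                       const IntegerMatrix& n_dk,
                       const std::vector<int>& doc_len) {
  const int D = n_dk.nrow(), K = n_dk.ncol();
  double alpha_sum = 0.0;
  for (int k = 0; k < K; ++k) alpha_sum += alpha[k];
  double denom = 0.0;
  for (int d = 0; d < D; ++d)
    denom += R::digamma(doc_len[d] + alpha_sum);
  denom -= D * R::digamma(alpha_sum);
  if (denom <= 0.0) return;  // all documents empty; nothing to learn
  for (int k = 0; k < K; ++k) {
    double num = 0.0;
    for (int d = 0; d < D; ++d)
      num += R::digamma(n_dk(d, k) + alpha[k]);
    num -= D * R::digamma(alpha[k]);
    double a = alpha[k] * num / denom;
    alpha[k] = (a > 1e-6 && R_finite(a)) ? a : 1e-6;
  }
}

// Collapsed joint log p(w, z | alpha, beta).
static double joint_loglik(const IntegerMatrix& n_dk,
                           const IntegerMatrix& n_wk,
                           const std::vector<int>& topic_tot,
                           const std::vector<int>& doc_len,
                           const std::vector<double>& alpha,
                           double beta) {
  const int D = n_dk.nrow(), K = n_dk.ncol(), V = n_wk.nrow();
  double alpha_sum = 0.0, lg_alpha = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha_sum += alpha[k];
    lg_alpha += lgamma(alpha[k]);
  }
  double ll = 0.0;
  for (int d = 0; d < D; ++d) {
    ll += lgamma(alpha_sum) - lgamma(doc_len[d] + alpha_sum) - lg_alpha;
    for (int k = 0; k < K; ++k) ll += lgamma(n_dk(d, k) + alpha[k]);
  }
  for (int k = 0; k < K; ++k) {
    ll += lgamma(V * beta) - lgamma(topic_tot[k] + V * beta)
        - V * lgamma(beta);
    for (int w = 0; w < V; ++w) ll += lgamma(n_wk(w, k) + beta);
  }
  return ll;
}

// [[Rcpp::export(name = ".gibbs_lda_cpp")]]
List gibbs_lda_cpp(List docs, int V, int K, NumericVector alpha_init,
                   double beta, int n_iter, int optimize_every, int burnin,
                   bool track_loglik) {
  const int D = docs.size();
  std::vector<std::vector<int> > w(D);   // 0-based word ids
  std::vector<std::vector<int> > z(D);   // 0-based topic labels
  std::vector<int> doc_len(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector dd = docs[d];
    doc_len[d] = dd.size();
    w[d].resize(dd.size());
    z[d].resize(dd.size());
    for (int i = 0; i < dd.size(); ++i) w[d][i] = dd[i] - 1;
  }

  IntegerMatrix n_wk(V, K), n_dk(D, K);
  std::vector<int> topic_tot(K, 0);
  std::vector<double> alpha(alpha_init.begin(), alpha_init.end());

  RNGScope scope;  // draws come from R's RNG: seeded by set.seed() upstream

  // semirandom initialization: uniform random topic per token
  for (int d = 0; d < D; ++d) {
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      ++n_wk(w[d][i], k);
      ++n_dk(d, k);
      ++topic_tot[k];
    }
  }

  NumericVector loglik(track_loglik ? n_iter : 0);
  std::vector<double> weight(K);
  const double vbeta = V * beta;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      for (size_t i = 0; i < w[d].size(); ++i) {
        const int word = w[d][i];
        int k_old = z[d][i];
        --n_wk(word, k_old);
        --n_dk(d, k_old);
        --topic_tot[k_old];
        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          total += (n_dk(d, k) + alpha[k]) * (n_wk(word, k) + beta)
                 / (topic_tot[k] + vbeta);
          weight[k] = total;
        }
        double u = unif_rand() * total;
        int k_new = 0;
        while (k_new < K - 1 && weight[k_new] < u) ++k_new;
        z[d][i] = k_new;
        ++n_wk(word, k_new);
        ++n_dk(d, k_new);
        ++topic_tot[k_new];
      }
    }
    if (optimize_every > 0 && iter + 1 > burnin &&
        (iter + 1 - burnin) % optimize_every == 0) {
      minka_step(alpha, n_dk, doc_len);
    }
    if (track_loglik) {
      loglik[iter] = joint_loglik(n_dk, n_wk, topic_tot, doc_len, alpha, beta);
    }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }

  List assign(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector zz(z[d].size());
    for (size_t i = 0; i < z[d].size(); ++i) zz[i] = z[d][i] + 1;
    assign[d] = zz;
  }
  return List::create(_["assignments"] = assign,
                      _["n_wk"] = n_wk,
                      _["n_dk"] = n_dk,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["loglik"] = loglik);
}

// [[Rcpp::export(name = ".minka_step_cpp")]]
NumericVector minka_step_cpp(NumericVector alpha, IntegerMatrix n_dk) {
  std::vector<double> a(alpha.begin(), alpha.end());
  std::vector<int> doc_len(n_dk.nrow(), 0);
  for (int d = 0; d < n_dk.nrow(); ++d)
    for (int k = 0; k < n_dk.ncol(); ++k) doc_len[d] += n_dk(d, k);
  minka_step(a, n_dk, doc_len);
  return NumericVector(a.begin(), a.end());
}
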