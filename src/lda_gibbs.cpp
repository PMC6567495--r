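#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// Token-topic assignments z are sampled with the multinomial
// conditional p(z = t) proportional to
//   (n_wt + beta) / (n_t + V beta) * (n_dt + alpha),
// the document term needing no normalisation inside a document.
// doc and word are 0-based per-token indices.

// [[Rcpp::export]]
List lda_gibbs_fit(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_vocab, int n_topics,
                   double alpha, double beta,
                   int n_iter, int burn_in, int seed) {
  const int n_tok = doc.size();
  const int T = n_topics, V = n_vocab, D = n_docs;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> z(n_tok);
  std::vector<int> nwt(V * T, 0);   // word-topic counts, column-major [w + V*t]
  std::vector<int> ndt(D * T, 0);   // doc-topic counts [d + D*t]
  std::vector<int> nt(T, 0);        // tokens per topic
  std::vector<int> nd(D, 0);        // tokens per doc

  for (int i = 0; i < n_tok; ++i) {
    int t = static_cast<int>(unif(rng) * T);
    if (t == T) t = T - 1;
    z[i] = t;
    ++nwt[word[i] + V * t];
    ++ndt[doc[i] + D * t];
    ++nt[t];
    ++nd[doc[i]];
  }

  NumericVector loglik(n_iter);
  std::vector<double> p(T);
  const double vbeta = V * beta;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < n_tok; ++i) {
      const int w = word[i], d = doc[i], old = z[i];
      --nwt[w + V * old];
      --ndt[d + D * old];
      --nt[old];
      double total = 0.0;
      for (int t = 0; t < T; ++t) {
        p[t] = (nwt[w + V * t] + beta) / (nt[t] + vbeta) *
               (ndt[d + D * t] + alpha);
        total += p[t];
      }
      double u = unif(rng) * total;
      int t_new = 0;
      double cum = p[0];
      while (u > cum && t_new < T - 1) cum += p[++t_new];
      z[i] = t_new;
      ++nwt[w + V * t_new];
      ++ndt[d + D * t_new];
      ++nt[t_new];
    }
    // training log-likelihood under the current count-based estimates
    double ll = 0.0;
    for (int i = 0; i < n_tok; ++i) {
      const int w = word[i], d = doc[i];
      double pw = 0.0;
      for (int t = 0; t < T; ++t) {
        pw += (nwt[w + V * t] + beta) / (nt[t] + vbeta) *
              (ndt[d + D * t] + alpha) / (nd[d] + T * alpha);
      }
      ll += std::log(pw);
    }
    loglik[iter] = ll;
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix phi(T, V);
  for (int t = 0; t < T; ++t)
    for (int w = 0; w < V; ++w)
      phi(t, w) = (nwt[w + V * t] + beta) / (nt[t] + vbeta);
  NumericMatrix theta(D, T);
  for (int d = 0; d < D; ++d)
    for (int t = 0; t < T; ++t)
      theta(d, t) = (ndt[d + D * t] + alpha) / (nd[d] + T * alpha);

  return List::create(_["phi"] = phi, _["theta"] = theta,
                      _["loglik"] = loglik,
                      _["z"] = IntegerVector(z.begin(), z.end()));
}

// Fold-in sampling for held-out documents: Phi is frozen, only the
// document-topic counts move. Returns the smoothed theta-hat rows.

// [[Rcpp::export]]
NumericMatrix lda_fold_in(IntegerVector doc, IntegerVector word,
                          int n_docs, NumericMatrix phi,
                          double alpha, int n_iter, int seed) {
  const int n_tok = doc.size();
  const int T = phi.nrow(), D = n_docs;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> z(n_tok);
  std::vector<int> ndt(D * T, 0);
  std::vector<int> nd(D, 0);
  for (int i = 0; i < n_tok; ++i) {
    int t = static_cast<int>(unif(rng) * T);
    if (t == T) t = T - 1;
    z[i] = t;
    ++ndt[doc[i] + D * t];
    ++nd[doc[i]];
  }
  std::vector<double> p(T);
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < n_tok; ++i) {
      const int w = word[i], d = doc[i], old = z[i];
      --ndt[d + D * old];
      double total = 0.0;
      for (int t = 0; t < T; ++t) {
        p[t] = phi(t, w) * (ndt[d + D * t] + alpha);
        total += p[t];
      }
      double u = unif(rng) * total;
      int t_new = 0;
      double cum = p[0];
      while (u > cum && t_new < T - 1) cum += p[++t_new];
      z[i] = t_new;
      ++ndt[d + D * t_new];
    }
  }
  NumericMatrix theta(D, T);
  for (int d = 0; d < D; ++d)
    for (int t = 0; t < T; ++t)
      theta(d, t) = (ndt[d + D * t] + alpha) / (nd[d] + T * alpha);
  return theta;
}
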