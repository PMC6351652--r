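#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA on a tokenised corpus.
//
// doc, word: 0-based token-level indices (length = total token count).
// Posterior-mean theta and phi are averaged over retained sweeps
// (iterations >= burn_in, every `thin`-th). Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_vocab, int n_topics,
                   double alpha, double beta,
                   int n_iter, int burn_in, int thin) {
  const int n_tok = doc.size();
  const double vbeta = n_vocab * beta;
  const double kalpha = n_topics * alpha;

  std::vector<int> z(n_tok);
  std::vector<int> ndk((size_t)n_docs * n_topics, 0);
  std::vector<int> nkv((size_t)n_topics * n_vocab, 0);
  std::vector<int> nk(n_topics, 0), nd(n_docs, 0);

  RNGScope scope;

  for (int t = 0; t < n_tok; ++t) {
    int k = (int)(unif_rand() * n_topics);
    if (k >= n_topics) k = n_topics - 1;
    z[t] = k;
    ++ndk[(size_t)doc[t] * n_topics + k];
    ++nkv[(size_t)k * n_vocab + word[t]];
    ++nk[k];
    ++nd[doc[t]];
  }

  std::vector<double> cum(n_topics);
  NumericMatrix theta(n_docs, n_topics), phi(n_topics, n_vocab);
  NumericVector loglik(n_iter);
  int n_samples = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int t = 0; t < n_tok; ++t) {
      const int d = doc[t], w = word[t];
      int k = z[t];
      --ndk[(size_t)d * n_topics + k];
      --nkv[(size_t)k * n_vocab + w];
      --nk[k];
      double tot = 0.0;
      for (int j = 0; j < n_topics; ++j) {
        tot += (ndk[(size_t)d * n_topics + j] + alpha) *
               (nkv[(size_t)j * n_vocab + w] + beta) / (nk[j] + vbeta);
        cum[j] = tot;
      }
      const double u = unif_rand() * tot;
      k = 0;
      while (k < n_topics - 1 && cum[k] < u) ++k;
      z[t] = k;
      ++ndk[(size_t)d * n_topics + k];
      ++nkv[(size_t)k * n_vocab + w];
      ++nk[k];
    }

    // collapsed log-likelihood log p(w, z | alpha, beta)
    double ll = n_topics * (lgamma(vbeta) - n_vocab * lgamma(beta));
    for (int k = 0; k < n_topics; ++k) {
      for (int v = 0; v < n_vocab; ++v)
        ll += lgamma(nkv[(size_t)k * n_vocab + v] + beta);
      ll -= lgamma(nk[k] + vbeta);
    }
    ll += n_docs * (lgamma(kalpha) - n_topics * lgamma(alpha));
    for (int d = 0; d < n_docs; ++d) {
      for (int k = 0; k < n_topics; ++k)
        ll += lgamma(ndk[(size_t)d * n_topics + k] + alpha);
      ll -= lgamma(nd[d] + kalpha);
    }
    loglik[it] = ll;

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      ++n_samples;
      for (int d = 0; d < n_docs; ++d)
        for (int k = 0; k < n_topics; ++k)
          theta(d, k) += (ndk[(size_t)d * n_topics + k] + alpha) /
                         (nd[d] + kalpha);
      for (int k = 0; k < n_topics; ++k)
        for (int v = 0; v < n_vocab; ++v)
          phi(k, v) += (nkv[(size_t)k * n_vocab + v] + beta) /
                       (nk[k] + vbeta);
    }
  }

  if (n_samples > 0) {
    for (int d = 0; d < n_docs; ++d)
      for (int k = 0; k < n_topics; ++k) theta(d, k) /= n_samples;
    for (int k = 0; k < n_topics; ++k)
      for (int v = 0; v < n_vocab; ++v) phi(k, v) /= n_samples;
  }
  // zero-token documents sit exactly at the prior mean 1/K
  for (int d = 0; d < n_docs; ++d)
    if (nd[d] == 0)
      for (int k = 0; k < n_topics; ++k) theta(d, k) = 1.0 / n_topics;

  IntegerMatrix ndkOut(n_docs, n_topics);
  for (int d = 0; d < n_docs; ++d)
    for (int k = 0; k < n_topics; ++k)
      ndkOut(d, k) = ndk[(size_t)d * n_topics + k];
  IntegerMatrix nkvOut(n_topics, n_vocab);
  for (int k = 0; k < n_topics; ++k)
    for (int v = 0; v < n_vocab; ++v)
      nkvOut(k, v) = nkv[(size_t)k * n_vocab + v];

  return List::create(_["theta"] = theta, _["phi"] = phi,
                      _["loglik"] = loglik, _["n_samples"] = n_samples,
                      _["ndk"] = ndkOut, _["nkv"] = nkvOut,
                      _["doc_lengths"] = IntegerVector(nd.begin(), nd.end()));
}
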