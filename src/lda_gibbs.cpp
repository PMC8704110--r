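#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// Uses R's RNG (unif_rand), so results are reproducible under set.seed().
// doc and word are 0-based token-level indices.

// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word, int D, int V,
                   int K, double alpha, double beta, int iters) {
  const int N = doc.size();
  IntegerMatrix ndk(D, K), nkw(K, V);
  IntegerVector nk(K), z(N);
  const double Vb = V * beta;

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk(doc[i], k)++;
    nkw(k, word[i])++;
    nk[k]++;
  }

  std::vector<double> p(K);
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int k = z[i];
      ndk(d, k)--;
      nkw(k, w)--;
      nk[k]--;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        p[j] = (ndk(d, j) + alpha) * (nkw(j, w) + beta) / (nk[j] + Vb);
        tot += p[j];
      }
      double u = unif_rand() * tot, c = 0.0;
      k = K - 1;
      for (int j = 0; j < K; ++j) {
        c += p[j];
        if (u <= c) { k = j; break; }
      }
      z[i] = k;
      ndk(d, k)++;
      nkw(k, w)++;
      nk[k]++;
    }
  }
  return List::create(_["ndk"] = ndk, _["nkw"] = nkw);
}
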