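#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation with symmetric
// Dirichlet priors. Documents arrive as 0-based term-index vectors (one
// entry per token instance). Draws use R's RNG, so set.seed() upstream
// makes the full assignment trajectory reproducible.
//
// Token-count conservation (sum of topic-word counts == total tokens) is
// asserted after every sweep; a violation aborts, since it would mean the
// count bookkeeping is corrupt and the posterior estimates meaningless.

// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int V, int K, double alpha, double beta,
                   int iterations) {
  int D = docs.size();
  std::vector<std::vector<int>> w(D);
  long total = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector v = docs[d];
    w[d] = std::vector<int>(v.begin(), v.end());
    total += v.size();
  }

  IntegerMatrix nkw(K, V);   // topic-word counts
  IntegerMatrix ndk(D, K);   // document-topic counts
  IntegerVector nk(K);       // tokens per topic
  std::vector<std::vector<int>> z(D);

  RNGScope scope;

  // random initial assignment
  for (int d = 0; d < D; ++d) {
    int nd = w[d].size();
    z[d].resize(nd);
    for (int i = 0; i < nd; ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      ++nkw(k, w[d][i]);
      ++ndk(d, k);
      ++nk[k];
    }
  }

  std::vector<double> p(K);
  double Vbeta = V * beta;

  for (int iter = 0; iter < iterations; ++iter) {
    for (int d = 0; d < D; ++d) {
      int nd = w[d].size();
      for (int i = 0; i < nd; ++i) {
        int t = w[d][i];
        int k = z[d][i];
        --nkw(k, t); --ndk(d, k); --nk[k];

        double cum = 0.0;
        for (int j = 0; j < K; ++j) {
          cum += (nkw(j, t) + beta) / (nk[j] + Vbeta) * (ndk(d, j) + alpha);
          p[j] = cum;
        }
        double u = unif_rand() * cum;
        int knew = 0;
        while (knew < K - 1 && p[knew] < u) ++knew;

        z[d][i] = knew;
        ++nkw(knew, t); ++ndk(d, knew); ++nk[knew];
      }
    }
    long s = 0;
    for (int j = 0; j < K; ++j) s += nk[j];
    if (s != total) stop("token count not conserved at sweep %d", iter + 1);
  }

  List zout(D);
  for (int d = 0; d < D; ++d) zout[d] = IntegerVector(z[d].begin(), z[d].end());

  return List::create(_["nkw"] = nkw, _["ndk"] = ndk, _["nk"] = nk,
                      _["z"] = zout, _["total_tokens"] = (double)total,
                      _["conservation_checked"] = iterations);
}
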