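#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// Tokens are passed as parallel 0-based index vectors (doc, word); a family
// count of c in a document contributes c tokens.  The full conditional for
// token i is
//
//   P(z_i = t | z_-i, w) ∝ (n_{w,t} + beta) / (n_{.,t} + V beta) * (n_{d,t} + alpha)
//
// (the document-length denominator is constant in t and omitted).  Draws use
// R's RNG so a set.seed() on the R side makes the whole chain reproducible.
//
// After `burn_in` sweeps, `n_samples` states are collected every `sample_lag`
// sweeps; phi and theta accumulate the per-sample posterior-mean estimates
//   phi_t(w)   = (n_{w,t} + beta)  / (n_{.,t} + V beta)
//   theta_d(t) = (n_{d,t} + alpha) / (n_{d,.} + T alpha)
// and are divided by n_samples on return.

// [[Rcpp::export]]
List gibbs_lda_cpp(const IntegerVector& doc, const IntegerVector& word,
                   int n_docs, int n_vocab, int n_topics,
                   double alpha, double beta,
                   int burn_in, int n_samples, int sample_lag) {
  const int n_tok = doc.size();
  const int T = n_topics, V = n_vocab, N = n_docs;

  std::vector<int> z(n_tok);
  std::vector<int> nwt((size_t)V * T, 0);  // word-topic counts, column-major [w + V*t]
  std::vector<int> ndt((size_t)N * T, 0);  // doc-topic counts  [d + N*t]
  std::vector<int> nt(T, 0);               // tokens per topic
  std::vector<double> p(T);

  for (int i = 0; i < n_tok; ++i) {
    int t = (int)(unif_rand() * T);
    if (t >= T) t = T - 1;
    z[i] = t;
    ++nwt[word[i] + (size_t)V * t];
    ++ndt[doc[i] + (size_t)N * t];
    ++nt[t];
  }

  NumericMatrix phi(T, V), theta(N, T);
  const double Vb = V * beta;
  const int n_sweeps = burn_in + n_samples * sample_lag;
  int collected = 0;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int i = 0; i < n_tok; ++i) {
      const int w = word[i], d = doc[i], told = z[i];
      --nwt[w + (size_t)V * told];
      --ndt[d + (size_t)N * told];
      --nt[told];

      double total = 0.0;
      for (int t = 0; t < T; ++t) {
        total += (nwt[w + (size_t)V * t] + beta) / (nt[t] + Vb) *
                 (ndt[d + (size_t)N * t] + alpha);
        p[t] = total;
      }
      const double u = unif_rand() * total;
      int tnew = 0;
      while (tnew < T - 1 && p[tnew] < u) ++tnew;

      z[i] = tnew;
      ++nwt[w + (size_t)V * tnew];
      ++ndt[d + (size_t)N * tnew];
      ++nt[tnew];
    }

    if (sweep > burn_in && (sweep - burn_in) % sample_lag == 0) {
      ++collected;
      for (int t = 0; t < T; ++t) {
        const double denom = nt[t] + Vb;
        for (int w = 0; w < V; ++w)
          phi(t, w) += (nwt[w + (size_t)V * t] + beta) / denom;
      }
      for (int d = 0; d < N; ++d) {
        // document length = sum_t ndt; constant across sweeps
        double len = 0.0;
        for (int t = 0; t < T; ++t) len += ndt[d + (size_t)N * t];
        const double denom = len + T * alpha;
        for (int t = 0; t < T; ++t)
          theta(d, t) += (ndt[d + (size_t)N * t] + alpha) / denom;
      }
    }
    if (sweep % 100 == 0) Rcpp::checkUserInterrupt();
  }

  if (collected > 0) {
    for (R_xlen_t i = 0; i < phi.size(); ++i) phi[i] /= collected;
    for (R_xlen_t i = 0; i < theta.size(); ++i) theta[i] /= collected;
  }

  // final count state, exported so token-conservation invariants are testable
  IntegerMatrix ndt_out(N, T), nwt_out(V, T);
  for (int t = 0; t < T; ++t) {
    for (int d = 0; d < N; ++d) ndt_out(d, t) = ndt[d + (size_t)N * t];
    for (int w = 0; w < V; ++w) nwt_out(w, t) = nwt[w + (size_t)V * t];
  }

  return List::create(_["phi"] = phi, _["theta"] = theta,
                      _["n_collected"] = collected,
                      _["ndt"] = ndt_out, _["nwt"] = nwt_out,
                      _["nt"] = IntegerVector(nt.begin(), nt.end()));
}
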