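#include <Rcpp.h>
using namespace Rcpp;

// Collapsed joint log p(w, z | alpha, beta): Dirichlet-multinomial closed form
// over the current count tables.
static double joint_log_lik(const IntegerMatrix& n_dk, const IntegerMatrix& n_kw,
                            const IntegerVector& n_k, const IntegerVector& N_d,
                            double alpha, double beta) {
  const int D = n_dk.nrow(), K = n_dk.ncol(), V = n_kw.ncol();
  double ll = K * (R::lgammafn(V * beta) - V * R::lgammafn(beta)) +
              D * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha));
  for (int k = 0; k < K; ++k) {
    for (int w = 0; w < V; ++w) ll += R::lgammafn(n_kw(k, w) + beta);
    ll -= R::lgammafn(n_k[k] + V * beta);
  }
  for (int d = 0; d < D; ++d) {
    for (int k = 0; k < K; ++k) ll += R::lgammafn(n_dk(d, k) + alpha);
    ll -= R::lgammafn(N_d[d] + K * alpha);
  }
  return ll;
}

// Collapsed Gibbs sampler for LDA. `doc` and `word` are 0-based token vectors;
// randomness comes from R's RNG stream (seed with set.seed() before calling).
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word, int D, int V, int K,
                   double alpha, double beta, int n_iter, int burn_in,
                   int sample_lag, bool debug) {
  const int N = doc.size();
  IntegerVector z(N);
  IntegerMatrix n_dk(D, K), n_kw(K, V);
  IntegerVector n_k(K), N_d(D);

  for (int i = 0; i < N; ++i) {
    int t = (int)(unif_rand() * K);
    if (t >= K) t = K - 1;
    z[i] = t;
    n_dk(doc[i], t)++;
    n_kw(t, word[i])++;
    n_k[t]++;
    N_d[doc[i]]++;
  }

  NumericVector trace(n_iter);
  NumericMatrix theta_sum(D, K), phi_sum(K, V);
  int n_samples = 0;
  std::vector<double> cum(K);
  const double Vbeta = V * beta;

  for (int it = 1; it <= n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int t = z[i];
      n_dk(d, t)--; n_kw(t, w)--; n_k[t]--;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        tot += (n_kw(k, w) + beta) / (n_k[k] + Vbeta) * (n_dk(d, k) + alpha);
        cum[k] = tot;
      }
      const double u = unif_rand() * tot;
      t = 0;
      while (t < K - 1 && cum[t] < u) ++t;
      z[i] = t;
      n_dk(d, t)++; n_kw(t, w)++; n_k[t]++;
    }

    if (debug) {
      for (int d = 0; d < D; ++d) {
        int s = 0;
        for (int k = 0; k < K; ++k) {
          if (n_dk(d, k) < 0) stop("negative drug-topic count after sweep %d", it);
          s += n_dk(d, k);
        }
        if (s != N_d[d]) stop("drug-topic counts do not sum to N_d after sweep %d", it);
      }
      int tot_k = 0;
      for (int k = 0; k < K; ++k) {
        int s = 0;
        for (int w = 0; w < V; ++w) {
          if (n_kw(k, w) < 0) stop("negative topic-word count after sweep %d", it);
          s += n_kw(k, w);
        }
        if (s != n_k[k]) stop("topic-word counts do not sum to n_k after sweep %d", it);
        tot_k += n_k[k];
      }
      if (tot_k != N) stop("topic totals do not sum to token count after sweep %d", it);
    }

    trace[it - 1] = joint_log_lik(n_dk, n_kw, n_k, N_d, alpha, beta);

    if (it > burn_in && (it - burn_in) % sample_lag == 0) {
      for (int d = 0; d < D; ++d)
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) += (n_dk(d, k) + alpha) / (N_d[d] + K * alpha);
      for (int k = 0; k < K; ++k)
        for (int w = 0; w < V; ++w)
          phi_sum(k, w) += (n_kw(k, w) + beta) / (n_k[k] + Vbeta);
      n_samples++;
    }
  }

  return List::create(_["theta_sum"] = theta_sum, _["phi_sum"] = phi_sum,
                      _["n_samples"] = n_samples, _["trace"] = trace,
                      _["z"] = z, _["n_dk"] = n_dk, _["n_kw"] = n_kw,
                      _["n_k"] = n_k, _["N_d"] = N_d);
}
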