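#include <Rcpp.h>
using namespace Rcpp;

// Stage-marginalized EBM log-likelihood for one event order.
// logN / logA: n x K matrices of per-cell normal / abnormal log-densities,
// with 0 in cells that are missing (their factor is 1). ord is 0-based,
// earliest event first.
static double seq_loglik_core(const NumericMatrix& logN,
                              const NumericMatrix& logA,
                              const IntegerVector& ord) {
  const int n = logN.nrow(), K = logN.ncol();
  std::vector<double> stage_ll(K + 1);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double cur = 0.0;
    for (int j = 0; j < K; ++j) cur += logN(i, j);
    stage_ll[0] = cur;
    for (int k = 1; k <= K; ++k) {
      const int m = ord[k - 1];
      cur += logA(i, m) - logN(i, m);
      stage_ll[k] = cur;
    }
    double mx = stage_ll[0];
    for (int k = 1; k <= K; ++k) if (stage_ll[k] > mx) mx = stage_ll[k];
    double s = 0.0;
    for (int k = 0; k <= K; ++k) s += std::exp(stage_ll[k] - mx);
    total += mx + std::log(s) - std::log((double)(K + 1));
  }
  return total;
}

// [[Rcpp::export]]
double cpp_seq_loglik(NumericMatrix logN, NumericMatrix logA,
                      IntegerVector ord0) {
  return seq_loglik_core(logN, logA, ord0);
}

// Metropolis-Hastings over event permutations with symmetric two-event-swap
// proposals. Uses R's RNG so runs are reproducible via set.seed().
// [[Rcpp::export]]
List cpp_ebm_mcmc(NumericMatrix logN, NumericMatrix logA,
                  IntegerVector init0, int n_iter, int burn_in) {
  const int K = logN.ncol();
  RNGScope scope;
  IntegerVector cur = clone(init0);
  double cur_ll = seq_loglik_core(logN, logA, cur);

  const int n_keep = n_iter - burn_in;
  IntegerMatrix samples(n_keep, K);
  NumericVector sample_ll(n_keep);
  IntegerVector best = clone(cur);
  double best_ll = cur_ll;
  long accepted = 0;

  for (int it = 0; it < n_iter; ++it) {
    int a = (int)(unif_rand() * K);
    int b = (int)(unif_rand() * (K - 1));
    if (b >= a) ++b;
    std::swap(cur[a], cur[b]);
    double prop_ll = seq_loglik_core(logN, logA, cur);
    if (std::log(unif_rand()) < prop_ll - cur_ll) {
      cur_ll = prop_ll;
      ++accepted;
      if (cur_ll > best_ll) { best_ll = cur_ll; best = clone(cur); }
    } else {
      std::swap(cur[a], cur[b]);  // reject: undo
    }
    if (it >= burn_in) {
      const int r = it - burn_in;
      for (int j = 0; j < K; ++j) samples(r, j) = cur[j];
      sample_ll[r] = cur_ll;
    }
  }
  return List::create(_["samples"] = samples, _["sample_loglik"] = sample_ll,
                      _["best"] = best, _["best_loglik"] = best_ll,
                      _["acceptance_rate"] = (double)accepted / n_iter);
}
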