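#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding in log space. Ties broken toward the lowest state
// index (state 1 is the diploid state by convention), both in the
// per-step argmax and in the terminal argmax.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix log_emis, NumericVector log_init,
                          NumericMatrix log_trans) {
  const int n = log_emis.nrow();
  const int K = log_emis.ncol();
  if (log_init.size() != K || log_trans.nrow() != K || log_trans.ncol() != K)
    stop("viterbi: dimension mismatch");
  if (n == 0) return IntegerVector(0);

  NumericVector cur(K), prev(K);
  IntegerMatrix back(n, K);
  for (int k = 0; k < K; ++k) prev[k] = log_init[k] + log_emis(0, k);

  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = prev[0] + log_trans(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double s = prev[j] + log_trans(j, k);
        if (s > best) { best = s; arg = j; }
      }
      cur[k] = best + log_emis(t, k);
      back(t, k) = arg;
    }
    prev = clone(cur);
  }

  int last = 0;
  double best = prev[0];
  for (int k = 1; k < K; ++k) if (prev[k] > best) { best = prev[k]; last = k; }

  IntegerVector path(n);
  path[n - 1] = last + 1;
  for (int t = n - 1; t > 0; --t) {
    last = back(t, last);
    path[t - 1] = last + 1;
  }
  return path;
}
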