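#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding for a Gaussian-emission HMM on a 1-D FRET series.
//
// obs    : per-frame FRET values (finite wherever mask is FALSE)
// mask   : TRUE marks frames whose emission is ignored (e.g. summed
//          intensity <= 0); such frames contribute no emission term
// means  : per-state emission means
// sds    : per-state emission standard deviations (> 0)
// logA   : log transition probability matrix (S x S), -Inf allowed
// logPi  : log initial state probabilities, -Inf allowed
//
// Ties are broken toward the lower state index (strict > comparison).
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector viterbi_decode_cpp(NumericVector obs, LogicalVector mask,
                                 NumericVector means, NumericVector sds,
                                 NumericMatrix logA, NumericVector logPi) {
  const int T = obs.size();
  const int S = means.size();
  IntegerVector path(T);
  if (T == 0) return path;

  std::vector<double> ldet(S);
  for (int s = 0; s < S; ++s) ldet[s] = -std::log(sds[s]);

  NumericMatrix delta(S, T);
  IntegerMatrix psi(S, T);

  auto emis = [&](int t, int s) -> double {
    if (mask[t]) return 0.0;
    const double z = (obs[t] - means[s]) / sds[s];
    return ldet[s] - 0.5 * z * z;
  };

  for (int s = 0; s < S; ++s) delta(s, 0) = logPi[s] + emis(0, s);

  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < S; ++i) {
        const double v = delta(i, t - 1) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(j, t) = best + emis(t, j);
      psi(j, t) = arg;
    }
  }

  double best = R_NegInf;
  int arg = 0;
  for (int s = 0; s < S; ++s) {
    if (delta(s, T - 1) > best) { best = delta(s, T - 1); arg = s; }
  }
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(path[t], t);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
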