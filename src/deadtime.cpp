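#include <Rcpp.h>
using namespace Rcpp;

// Non-paralyzable dead-time filter: an attempt succeeds iff at least
// `dead_time` seconds have elapsed since the last *successful* attempt
// (the clock restarts on success only). The first attempt of a run
// always succeeds. Sequential by nature, hence C++.

// [[Rcpp::export]]
NumericVector dead_time_filter(NumericVector attempt_times, double dead_time) {
  std::vector<double> succ;
  succ.reserve(attempt_times.size() > 0 ? attempt_times.size() / 4 + 1 : 0);
  double last = R_NegInf;
  const int n = attempt_times.size();
  for (int i = 0; i < n; ++i) {
    const double t = attempt_times[i];
    if (t - last >= dead_time) {
      succ.push_back(t);
      last = t;
    }
  }
  return wrap(succ);
}
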