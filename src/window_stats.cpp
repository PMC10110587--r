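#include <Rcpp.h>
using namespace Rcpp;

// Base statistics (min, max, mean, population sd, amplitude) of many sample
// windows of one channel. i0/i1 are 1-based inclusive sample bounds.
// [[Rcpp::export(name = ".window_stats_cpp")]]
NumericMatrix window_stats_cpp(NumericVector samples, IntegerVector i0,
                               IntegerVector i1) {
  const int n = i0.size();
  NumericMatrix S(n, 5);
  for (int e = 0; e < n; ++e) {
    const int a = i0[e] - 1, b = i1[e] - 1;
    if (a < 0 || b >= samples.size() || b < a)
      stop("window bounds outside the recording");
    double mn = samples[a], mx = samples[a], s1 = 0.0, s2 = 0.0;
    const int len = b - a + 1;
    for (int i = a; i <= b; ++i) {
      const double x = samples[i];
      if (x < mn) mn = x;
      if (x > mx) mx = x;
      s1 += x;
      s2 += x * x;
    }
    const double m = s1 / len;
    double v = s2 / len - m * m;
    if (v < 0) v = 0;  // guard FP cancellation on constant windows
    S(e, 0) = mn;
    S(e, 1) = mx;
    S(e, 2) = m;
    S(e, 3) = std::sqrt(v);
    S(e, 4) = mx - mn;
  }
  return S;
}

// Hierarchical aggregation of one (test, topic, channel) block.
// S: per-event base stats [event, 5]; qcode: 0-based question index per
// event; rep: repetition index per event. Returns the 60 features in
// canonical (stat, rep_agg in {min,max,mean,diff}, q_agg in {min,max,mean})
// order. diff = first repetition minus the mean of the subsequent ones.
// [[Rcpp::export(name = ".agg_block_cpp")]]
NumericVector agg_block_cpp(NumericMatrix S, IntegerVector qcode,
                            IntegerVector rep) {
  const int n = S.nrow();
  int nq = 0;
  for (int e = 0; e < n; ++e) if (qcode[e] + 1 > nq) nq = qcode[e] + 1;

  // A[q][r][s], r in {min,max,mean,diff}
  std::vector<double> A(nq * 4 * 5);
  std::vector<int> idx;
  for (int q = 0; q < nq; ++q) {
    idx.clear();
    for (int e = 0; e < n; ++e) if (qcode[e] == q) idx.push_back(e);
    // order repetitions (insertion sort; repetition counts are tiny)
    for (size_t i = 1; i < idx.size(); ++i) {
      int v = idx[i];
      size_t j = i;
      while (j > 0 && rep[idx[j - 1]] > rep[v]) { idx[j] = idx[j - 1]; --j; }
      idx[j] = v;
    }
    const int m = idx.size();
    for (int s = 0; s < 5; ++s) {
      double mn = S(idx[0], s), mx = mn, sum = 0.0;
      for (int i = 0; i < m; ++i) {
        const double x = S(idx[i], s);
        if (x < mn) mn = x;
        if (x > mx) mx = x;
        sum += x;
      }
      const double first = S(idx[0], s);
      const double d = (m == 1) ? 0.0 : first - (sum - first) / (m - 1);
      double *a = &A[(q * 4) * 5 + s];
      a[0 * 5] = mn;
      a[1 * 5] = mx;
      a[2 * 5] = sum / m;
      a[3 * 5] = d;
    }
  }

  NumericVector out(5 * 4 * 3);
  for (int s = 0; s < 5; ++s) {
    for (int r = 0; r < 4; ++r) {
      double mn = A[r * 5 + s], mx = mn, sum = 0.0;
      for (int q = 0; q < nq; ++q) {
        const double x = A[(q * 4 + r) * 5 + s];
        if (x < mn) mn = x;
        if (x > mx) mx = x;
        sum += x;
      }
      const int base = s * 12 + r * 3;
      out[base + 0] = mn;
      out[base + 1] = mx;
      out[base + 2] = sum / nq;
    }
  }
  return out;
}
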