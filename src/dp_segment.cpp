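#include <Rcpp.h>
using namespace Rcpp;

// Exact penalized least-squares changepoint DP.
//
// Minimises  sum_segments sum_probes (x - segment mean)^2 + penalty * k
// over all partitions of x into k contiguous segments (segment length
// >= min_len; optionally <= band).  O(n * band) with prefix sums.
//
// Ties are broken toward fewer segments, then toward the longer last
// segment, so the result is deterministic.
//
// Returns the 1-based start index of each segment.
// [[Rcpp::export]]
IntegerVector dp_segment_cpp(NumericVector x, double penalty,
                             int min_len = 1, int band = 0) {
  const int n = x.size();
  if (n == 0) stop("empty profile");
  if (penalty < 0) stop("penalty must be >= 0");
  if (min_len < 1) min_len = 1;
  if (band <= 0 || band > n) band = n;
  if (min_len > n) min_len = n;

  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + x[i];
    s2[i + 1] = s2[i] + x[i] * x[i];
  }
  // cost[j]: optimal cost of x[0..j-1]; back[j]: start (0-based) of the
  // last segment in that optimum; nseg[j]: its segment count.
  std::vector<double> cost(n + 1, R_PosInf);
  std::vector<int> back(n + 1, -1), nseg(n + 1, 0);
  cost[0] = 0.0;

  for (int j = 1; j <= n; ++j) {
    int lo = j - band;       // earliest allowed segment start (0-based)
    if (lo < 0) lo = 0;
    int hi = j - min_len;    // latest allowed segment start
    for (int i = lo; i <= hi; ++i) {
      if (!R_finite(cost[i])) continue;
      const int len = j - i;
      const double sum = s1[j] - s1[i];
      const double sse = s2[j] - s2[i] - sum * sum / len;
      const double c = cost[i] + sse + penalty;
      const int k = nseg[i] + 1;
      if (c < cost[j] ||
          (c == cost[j] && (k < nseg[j] ||
                            (k == nseg[j] && i < back[j])))) {
        cost[j] = c;
        back[j] = i;
        nseg[j] = k;
      }
    }
  }
  // prefixes shorter than min_len are legitimately infeasible; only the
  // full profile must admit a partition
  if (!R_finite(cost[n]))
    stop("no feasible segmentation (min_len/band too restrictive)");

  std::vector<int> starts;
  for (int j = n; j > 0; j = back[j]) starts.push_back(back[j] + 1);
  std::reverse(starts.begin(), starts.end());
  return wrap(starts);
}
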