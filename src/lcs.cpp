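#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Token sequences arrive as integer codes (factor levels built in R across
// the corpora being compared); 0/NA never occur.

// [[Rcpp::export]]
int cpp_lcs_length(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      if (ai == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// LCS length of one generated sequence against every training sequence.
// [[Rcpp::export]]
IntegerVector cpp_lcs_length_many(IntegerVector gen, List train) {
  const int nt = train.size();
  IntegerVector out(nt);
  for (int t = 0; t < nt; ++t) {
    IntegerVector tr = train[t];
    out[t] = cpp_lcs_length(gen, tr);
  }
  return out;
}

// Longest common contiguous run of tokens (diagnostic companion for k = 1).
// [[Rcpp::export]]
int cpp_longest_common_run(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1 : 0;
      if (cur[j] > best) best = cur[j];
    }
    std::swap(prev, cur);
  }
  return best;
}

// Best penalized chain value: maximize over common-subsequence chains
//   L - sum over junctions of min(max(gap_a, gap_b) / k, 1)
// where gap = number of skipped tokens between consecutive matched
// positions (adjacent matches -> gap 0 -> no penalty). DP over match
// pairs (i, j) with a[i] == b[j], quadratic in the number of pairs.
// Returns the raw (unnormalized) best value; 0.0 when no token is shared.
// [[Rcpp::export]]
double cpp_penalized_best(IntegerVector a, IntegerVector b, double k) {
  const int n = a.size(), m = b.size();
  std::vector<int> mi, mj;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (a[i] == b[j]) { mi.push_back(i); mj.push_back(j); }
  const int M = (int) mi.size();
  if (M == 0) return 0.0;
  std::vector<double> f(M);
  double best = 0.0;
  // pairs are generated in lexicographic (i, j) order, so all potential
  // predecessors of pair p sit at indices < p
  for (int p = 0; p < M; ++p) {
    double fp = 1.0;  // chain starting here
    for (int q = 0; q < p; ++q) {
      if (mi[q] < mi[p] && mj[q] < mj[p]) {
        double gap = std::max(mi[p] - mi[q] - 1, mj[p] - mj[q] - 1);
        double pen = std::min(gap / k, 1.0);
        double cand = f[q] + 1.0 - pen;
        if (cand > fp) fp = cand;
      }
    }
    f[p] = fp;
    if (fp > best) best = fp;
  }
  return best;
}

// Penalize the canonical classic-LCS backtrace instead of re-optimizing:
// ties in the DP broken toward taking the match (contiguity), and the
// backtrace prefers diagonal moves. Returns the raw penalized value of
// that single chain.
// [[Rcpp::export]]
double cpp_penalized_classic_path(IntegerVector a, IntegerVector b, double k) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<std::vector<int> > L(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) L[i][j] = L[i - 1][j - 1] + 1;
      else L[i][j] = std::max(L[i - 1][j], L[i][j - 1]);
    }
  // backtrace, preferring matches, then the i-decreasing move
  std::vector<int> ci, cj;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    if (a[i - 1] == b[j - 1] && L[i][j] == L[i - 1][j - 1] + 1) {
      ci.push_back(i - 1); cj.push_back(j - 1); --i; --j;
    } else if (L[i - 1][j] >= L[i][j - 1]) --i;
    else --j;
  }
  std::reverse(ci.begin(), ci.end());
  std::reverse(cj.begin(), cj.end());
  const int len = (int) ci.size();
  if (len == 0) return 0.0;
  double val = (double) len;
  for (int t = 1; t < len; ++t) {
    double gap = std::max(ci[t] - ci[t - 1] - 1, cj[t] - cj[t - 1] - 1);
    val -= std::min(gap / k, 1.0);
  }
  return val;
}
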