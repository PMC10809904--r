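#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <vector>
using namespace Rcpp;

// Suffix array over an integer alphabet by prefix doubling with std::sort,
// O(N log^2 N).  Adequate for desk-scale texts; the contract is correctness,
// not linear time.
// [[Rcpp::export]]
IntegerVector sa_build_cpp(IntegerVector codes) {
  const int n = codes.size();
  if (n == 0) stop("empty text");
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = codes[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + k < n ? rnk[a + k] : -1;
      int rb = b + k < n ? rnk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sa[i] + 1;  // 1-based positions
  return out;
}

// Kasai's algorithm.  lcp[1] = 0 and lcp[i] (1-based) is the longest common
// prefix of the suffixes at ranks i-1 and i.
// [[Rcpp::export]]
IntegerVector lcp_kasai_cpp(IntegerVector codes, IntegerVector sa) {
  const int n = codes.size();
  std::vector<int> rnk(n);
  std::vector<int> lcp(n, 0);
  for (int i = 0; i < n; ++i) rnk[sa[i] - 1] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rnk[i] > 0) {
      int j = sa[rnk[i] - 1] - 1;
      while (i + h < n && j + h < n && codes[i + h] == codes[j + h]) ++h;
      lcp[rnk[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return IntegerVector(lcp.begin(), lcp.end());
}

// Enumerate every node of the LCP-interval tree with lcp value >= lmin,
// via the classic stack traversal of the LCP array.  Each node is a rank
// range [lo..hi] (1-based, inclusive) whose suffixes share a prefix of
// exactly match_len characters as a group; nested nodes are reported too,
// so longer matches inside a run at the threshold are not lost.
// [[Rcpp::export]]
IntegerMatrix lcp_interval_nodes_cpp(IntegerVector lcp, int lmin) {
  const int n = lcp.size();
  std::vector<std::array<int, 3>> out;
  // stack entries: (lcp value, left boundary as 0-based rank)
  std::vector<std::pair<int, int>> stk;
  stk.emplace_back(0, 0);
  for (int i = 1; i <= n; ++i) {
    int l = (i < n) ? lcp[i] : 0;
    int lb = i - 1;
    while (l < stk.back().first) {
      int v = stk.back().first;
      int left = stk.back().second;
      stk.pop_back();
      if (v >= lmin && (i - 1) > left)
        out.push_back({left + 1, i, v});  // 1-based [lo..hi], hi = (i-1)+1
      lb = left;
    }
    if (l > stk.back().first) stk.emplace_back(l, lb);
  }
  IntegerMatrix m(out.size(), 3);
  for (size_t r = 0; r < out.size(); ++r) {
    m(r, 0) = out[r][0];
    m(r, 1) = out[r][1];
    m(r, 2) = out[r][2];
  }
  colnames(m) = CharacterVector::create("lo", "hi", "match_len");
  return m;
}
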