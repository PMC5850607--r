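// Suffix-array maximal-unique-match (MUM) finder.
//
// A MUM between two sequences is an exact match that occurs exactly once in
// each sequence and cannot be extended in either direction. Candidates are
// adjacent entries of the generalized suffix array of s1 # s2 whose LCP is
// locally maximal (uniqueness) and whose preceding characters differ
// (left-maximality); right-maximality is implied by the LCP itself.
//
// Ambiguous bases (code 0 on input) and the separator are recoded to unique
// integers so they can never participate in a match.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// O(n log n) suffix array by prefix doubling with counting sort.
static void suffix_array(const std::vector<int>& s, std::vector<int>& sa) {
  const int n = (int)s.size();
  sa.resize(n);
  std::vector<int> r(n), r2(n), sa2(n);
  { // initial rank compression (input values may be large/sparse)
    std::vector<int> v(s);
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
    for (int i = 0; i < n; ++i)
      r[i] = (int)(std::lower_bound(v.begin(), v.end(), s[i]) - v.begin()) + 1;
  }
  std::iota(sa.begin(), sa.end(), 0);
  if (n == 1) return;
  std::vector<int> c(n + 2);
  for (int k = 1;; k <<= 1) {
    // counting sort by second key r[i+k] (0 past the end)
    std::fill(c.begin(), c.end(), 0);
    for (int i = 0; i < n; ++i) {
      int key = (i + k < n) ? r[i + k] : 0;
      ++c[key + 1];
    }
    for (int i = 1; i <= n + 1; ++i) c[i] += c[i - 1];
    for (int i = 0; i < n; ++i) {
      int key = (i + k < n) ? r[i + k] : 0;
      sa2[c[key]++] = i;
    }
    // stable counting sort by first key r[i]
    std::fill(c.begin(), c.end(), 0);
    for (int i = 0; i < n; ++i) ++c[r[i] + 1];
    for (int i = 1; i <= n + 1; ++i) c[i] += c[i - 1];
    for (int i = 0; i < n; ++i) sa[c[r[sa2[i]]]++] = sa2[i];
    // recompute ranks
    r2[sa[0]] = 1;
    for (int i = 1; i < n; ++i) {
      int a = sa[i - 1], b = sa[i];
      bool same = r[a] == r[b] &&
        ((a + k < n ? r[a + k] : 0) == (b + k < n ? r[b + k] : 0));
      r2[b] = r2[a] + (same ? 0 : 1);
    }
    r.swap(r2);
    if (r[sa[n - 1]] == n) break;
  }
}

// Kasai LCP array: lcp[k] = longest common prefix of suffixes sa[k], sa[k+1].
static void lcp_array(const std::vector<int>& s, const std::vector<int>& sa,
                      std::vector<int>& lcp) {
  const int n = (int)s.size();
  std::vector<int> rank_(n);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
  lcp.assign(n > 0 ? n - 1 : 0, 0);
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank_[i] - 1] = h;
      if (h) --h;
    } else {
      h = 0;
    }
  }
}

// One orientation: MUMs of s2 against s1 (both on the strands given).
static void mums_one(const std::vector<int>& s1, const std::vector<int>& s2,
                     int min_len, std::vector<int>& xs, std::vector<int>& ys,
                     std::vector<int>& ls) {
  const int L1 = (int)s1.size();
  int next_code = 5;
  std::vector<int> S;
  S.reserve(s1.size() + s2.size() + 1);
  for (int v : s1) S.push_back(v > 0 ? v : next_code++);
  S.push_back(next_code++);  // separator
  for (int v : s2) S.push_back(v > 0 ? v : next_code++);
  const int n = (int)S.size();
  if (n < 2) return;

  std::vector<int> sa, lcp;
  suffix_array(S, sa);
  lcp_array(S, sa, lcp);

  for (int k = 0; k + 1 < n; ++k) {
    const int l = lcp[k];
    if (l < min_len) continue;
    const int p = sa[k], q = sa[k + 1];
    const bool p_in_1 = p < L1, q_in_1 = q < L1;
    if (p_in_1 == q_in_1) continue;        // both suffixes from the same genome
    if (k > 0 && lcp[k - 1] >= l) continue;      // prefix not unique
    if (k + 1 < n - 1 && lcp[k + 1] >= l) continue;
    const int x = p_in_1 ? p : q;
    const int g2abs = p_in_1 ? q : p;      // absolute position of genome-2 suffix
    if (x > 0 && S[x - 1] == S[g2abs - 1]) continue;  // left-extendable
    xs.push_back(x);
    ys.push_back(g2abs - (L1 + 1));
    ls.push_back(l);
  }
}

// [[Rcpp::export]]
List find_mums_cpp(IntegerVector g1, IntegerVector g2, IntegerVector g2rc,
                   int min_len) {
  std::vector<int> s1(g1.begin(), g1.end());
  std::vector<int> s2(g2.begin(), g2.end());
  std::vector<int> s2r(g2rc.begin(), g2rc.end());
  const int L2 = (int)s2.size();

  std::vector<int> xs, ys, ls;
  mums_one(s1, s2, min_len, xs, ys, ls);
  const int n_fwd = (int)xs.size();

  std::vector<int> xr, yr, lr;
  mums_one(s1, s2r, min_len, xr, yr, lr);
  // convert reverse-strand start to forward-strand start of the matched segment
  for (size_t m = 0; m < xr.size(); ++m) {
    xs.push_back(xr[m]);
    ys.push_back(L2 - yr[m] - lr[m]);
    ls.push_back(lr[m]);
  }

  const int n = (int)xs.size();
  IntegerVector X(n), Y(n), L(n);
  LogicalVector fwd(n);
  for (int m = 0; m < n; ++m) {
    X[m] = xs[m];
    Y[m] = ys[m];
    L[m] = ls[m];
    fwd[m] = m < n_fwd;
  }
  return List::create(_["x"] = X, _["y"] = Y, _["len"] = L,
                      _["forward"] = fwd);
}

// X-type symmetry matrix over a grid. For MUM midpoint (px, py) and grid
// point (i, j), the forward residual is the circular vertical deviation of
// the point from the slope +1 line through (i, j), and the mirrored residual
// is the same after reflecting the point about the vertical axis at i.
// sw is +weight for forward MUMs and -weight for reverse MUMs, so each
// entry accumulates w*(f_m - f) for forward and w*(r - r_m) for reverse
// matches; normalization by total weight is done by the caller.
// [[Rcpp::export]]
NumericMatrix xmatrix_cpp(NumericVector px, NumericVector py,
                          NumericVector sw, NumericVector ig,
                          NumericVector jg, double L1, double L2) {
  const int n = px.size(), ni = ig.size(), nj = jg.size();
  NumericMatrix X(ni, nj);
  // arguments are within a few multiples of the modulus; reduce by
  // subtraction
  auto wrap = [](double v, double L) {
    while (v >= L) v -= L;
    while (v < 0) v += L;
    return v;
  };
  for (int a = 0; a < ni; ++a) {
    const double i = ig[a];
    for (int m = 0; m < n; ++m) {
      const double av = wrap(py[m] - px[m] + i, L2);
      // mirrored x is a genome-1 position, reduced on genome 1's circle
      const double pxm = wrap(2 * i - px[m], L1);
      const double bv = wrap(py[m] - pxm + i, L2);
      const double w = sw[m];
      for (int b = 0; b < nj; ++b) {
        double da = av > jg[b] ? av - jg[b] : jg[b] - av;
        if (da > L2 - da) da = L2 - da;
        double db = bv > jg[b] ? bv - jg[b] : jg[b] - bv;
        if (db > L2 - db) db = L2 - db;
        X(a, b) += w * (db - da);
      }
    }
  }
  return X;
}
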