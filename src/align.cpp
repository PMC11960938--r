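#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Three-state affine DP for global alignment with optionally free end gaps
// ("overlap" mode).  Gap cost convention: a run of length L costs
// gap_open + gap_extend * L, so the M -> gap transition pays
// gap_open + gap_extend and each extension pays gap_extend.  Runs touching
// either sequence end are free when free_end_gaps is true.
//
// States: 0 = M (a[i] ~ b[j]), 1 = X (gap in b, consumes a),
//         2 = Y (gap in a, consumes b).  Direct X <-> Y transitions are
// disallowed; with non-negative gap costs they are never optimal.

static const int NEG_INF = INT_MIN / 4;

// [[Rcpp::export]]
List align_overlap_cpp(std::string a, std::string b,
                       IntegerMatrix submat, std::string alphabet,
                       int gap_open, int gap_extend, bool free_end_gaps) {
  const int n = (int)a.size(), m = (int)b.size();
  int idx[256];
  for (int k = 0; k < 256; ++k) idx[k] = -1;
  for (int k = 0; k < (int)alphabet.size(); ++k)
    idx[(unsigned char)alphabet[k]] = k;
  for (int i = 0; i < n; ++i)
    if (idx[(unsigned char)a[i]] < 0)
      stop("non-IUPAC character '%s' in first sequence", std::string(1, a[i]));
  for (int j = 0; j < m; ++j)
    if (idx[(unsigned char)b[j]] < 0)
      stop("non-IUPAC character '%s' in second sequence", std::string(1, b[j]));

  const int go = gap_open, ge = gap_extend;
  const size_t ncell = (size_t)(n + 1) * (size_t)(m + 1);
  std::vector<int> M(ncell), X(ncell), Y(ncell);
  // traceback: for M, which state fed the diagonal move (0/1/2);
  // for X and Y, 0 = opened from M, 1 = extended same state
  std::vector<unsigned char> tbM(ncell), tbX(ncell), tbY(ncell);
  #define AT(i, j) ((size_t)(i) * (size_t)(m + 1) + (size_t)(j))

  M[AT(0, 0)] = 0;
  X[AT(0, 0)] = NEG_INF;
  Y[AT(0, 0)] = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M[AT(i, 0)] = NEG_INF;
    Y[AT(i, 0)] = NEG_INF;
    X[AT(i, 0)] = free_end_gaps ? 0 : -(go + ge * i);
    tbX[AT(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M[AT(0, j)] = NEG_INF;
    X[AT(0, j)] = NEG_INF;
    Y[AT(0, j)] = free_end_gaps ? 0 : -(go + ge * j);
    tbY[AT(0, j)] = (j == 1) ? 0 : 1;
  }

  for (int i = 1; i <= n; ++i) {
    const int ai = idx[(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const size_t c = AT(i, j), d = AT(i - 1, j - 1),
                   u = AT(i - 1, j), l = AT(i, j - 1);
      const int s = submat(ai, idx[(unsigned char)b[j - 1]]);
      // tie preference M > X > Y (diagonal > up > left)
      int best = M[d]; unsigned char from = 0;
      if (X[d] > best) { best = X[d]; from = 1; }
      if (Y[d] > best) { best = Y[d]; from = 2; }
      M[c] = (best <= NEG_INF) ? NEG_INF : best + s;
      tbM[c] = from;

      int openX = (M[u] <= NEG_INF) ? NEG_INF : M[u] - (go + ge);
      int extX  = (X[u] <= NEG_INF) ? NEG_INF : X[u] - ge;
      if (openX >= extX) { X[c] = openX; tbX[c] = 0; }
      else               { X[c] = extX;  tbX[c] = 1; }

      int openY = (M[l] <= NEG_INF) ? NEG_INF : M[l] - (go + ge);
      int extY  = (Y[l] <= NEG_INF) ? NEG_INF : Y[l] - ge;
      if (openY >= extY) { Y[c] = openY; tbY[c] = 0; }
      else               { Y[c] = extY;  tbY[c] = 1; }
    }
  }

  // endpoint: corner first, then last column bottom-up, then last row
  // right-to-left; update only on strictly greater score, so the endpoint
  // consuming the most of both sequences wins ties
  int bi = n, bj = m, bstate = 0;
  int bscore = NEG_INF;
  auto consider = [&](int i, int j) {
    const size_t c = AT(i, j);
    int v = M[c]; int st = 0;
    if (X[c] > v) { v = X[c]; st = 1; }
    if (Y[c] > v) { v = Y[c]; st = 2; }
    if (v > bscore) { bscore = v; bi = i; bj = j; bstate = st; }
  };
  if (free_end_gaps) {
    consider(n, m);
    for (int i = n - 1; i >= 0; --i) consider(i, m);
    for (int j = m - 1; j >= 0; --j) consider(n, j);
  } else {
    consider(n, m);
  }

  // traceback
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  for (int i = n; i > bi; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > bj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  // (only one of the two loops above can run: bi < n implies bj == m)
  int i = bi, j = bj, st = bstate;
  while (i > 0 || j > 0) {
    const size_t c = AT(i, j);
    if (st == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      st = tbM[c]; --i; --j;
    } else if (st == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      st = (tbX[c] == 0) ? 0 : 1; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      st = (tbY[c] == 0) ? 0 : 2; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int n_identical = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] != '-' && ra[k] == rb[k]) ++n_identical;

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = bscore, _["n_identical"] = n_identical,
                      _["len_shorter"] = std::min(n, m));
}

// Window-sum substitution scores of a self-comparison, for dot plots.
// scores(i, j) = sum over offsets k in [-h, h] with both i+k and j+k in
// range of submat(seq[i+k], seq[j+k]); partial windows at the edges.
// [[Rcpp::export]]
NumericMatrix dotplot_self_cpp(std::string seq, int window,
                               IntegerMatrix submat, std::string alphabet) {
  const int n = (int)seq.size(), h = window / 2;
  int idx[256];
  for (int k = 0; k < 256; ++k) idx[k] = -1;
  for (int k = 0; k < (int)alphabet.size(); ++k)
    idx[(unsigned char)alphabet[k]] = k;
  std::vector<int> si(n);
  for (int i = 0; i < n; ++i) {
    si[i] = idx[(unsigned char)seq[i]];
    if (si[i] < 0)
      stop("non-IUPAC character '%s' in sequence", std::string(1, seq[i]));
  }
  NumericMatrix out(n, n);
  // run along diagonals with a cumulative-sum window
  for (int d = 0; d < n; ++d) {   // d = j - i >= 0; mirror for symmetry
    const int len = n - d;
    std::vector<int> cum(len + 1, 0);
    for (int t = 0; t < len; ++t)
      cum[t + 1] = cum[t] + submat(si[t], si[t + d]);
    for (int t = 0; t < len; ++t) {
      const int lo = std::max(0, t - h), hi = std::min(len - 1, t + h);
      const int v = cum[hi + 1] - cum[lo];
      out(t, t + d) = v;
      out(t + d, t) = v;
    }
  }
  return out;
}
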