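#include <Rcpp.h>
#include <climits>
#include <vector>

using namespace Rcpp;

// Affine gap model throughout: a gap of length k costs gap_open + k * gap_extend
// (BLAST convention; gap_open 11, gap_extend 1 reproduces BLASTP defaults).
// Sequences arrive as 0-based integer codes into the substitution matrix.

static const int NEG = INT_MIN / 4;

// Traceback provenance codes for the H (match) state.
enum { P_STOP = 0, P_DIAG = 1, P_UP = 2, P_LEFT = 3 };

// Smith-Waterman-Gotoh, score only. Row-major sweep (query i outer, subject j
// inner) with O(m) memory, so 100 kb translated frames stay cheap.
// [[Rcpp::export]]
int cpp_local_score(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                    int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size(), K = mat.nrow();
  const int *M = INTEGER(mat);
  const int go = gap_open + gap_extend, ge = gap_extend;
  std::vector<int> H(m + 1, 0), F(m + 1, NEG);
  std::vector<int> soff(m);
  for (int j = 0; j < m; ++j) soff[j] = s[j] * K;
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1];
    int diag = H[0];
    int e = NEG;
    int hleft = 0;
    for (int j = 1; j <= m; ++j) {
      const int eo = hleft - go, ee = e - ge;
      e = eo >= ee ? eo : ee;
      const int fo = H[j] - go, fe = F[j] - ge;
      const int f = fo >= fe ? fo : fe;
      int h = diag + M[qi + soff[j - 1]];
      if (f > h) h = f;
      if (e > h) h = e;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      F[j] = f;
      hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full Smith-Waterman-Gotoh with traceback. Provenance kept as bytes
// (3 matrices of n*m), so a 300 x 17000 winner frame needs ~15 MB.
// Tie-breaking: best cell = highest score, then smallest subject end, then
// smallest query end; path preference diagonal > up (gap in subject) > left.
// [[Rcpp::export]]
List cpp_local_align(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                     int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size(), K = mat.nrow();
  const int *M = INTEGER(mat);
  const int go = gap_open + gap_extend, ge = gap_extend;

  std::vector<unsigned char> ph((size_t)n * m), pe((size_t)n * m), pf((size_t)n * m);
  std::vector<int> H(m + 1, 0), F(m + 1, NEG);
  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1];
    int diag = H[0];
    int e = NEG;
    int hleft = 0;
    for (int j = 1; j <= m; ++j) {
      const size_t at = (size_t)(i - 1) * m + (j - 1);
      const int eo = hleft - go, ee = e - ge;
      if (eo >= ee) { e = eo; pe[at] = 1; } else { e = ee; pe[at] = 0; }
      const int fo = H[j] - go, fe = F[j] - ge;
      int f;
      if (fo >= fe) { f = fo; pf[at] = 1; } else { f = fe; pf[at] = 0; }
      int h = diag + M[qi + (size_t)s[j - 1] * K];
      unsigned char src = P_DIAG;
      if (f > h) { h = f; src = P_UP; }
      if (e > h) { h = e; src = P_LEFT; }
      if (h <= 0) { h = 0; src = P_STOP; }
      ph[at] = src;
      diag = H[j];
      H[j] = h;
      F[j] = f;
      hleft = h;
      if (h > best || (h == best && h > 0 && (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
  }

  std::vector<int> ops;  // reversed path: 0 diag, 1 up (consume query), 2 left
  int i = bi, j = bj;
  if (best > 0) {
    int state = 0;  // 0 = H, 1 = F(up), 2 = E(left)
    while (i > 0 && j > 0) {
      const size_t at = (size_t)(i - 1) * m + (j - 1);
      if (state == 0) {
        const unsigned char src = ph[at];
        if (src == P_STOP) break;
        if (src == P_DIAG) { ops.push_back(0); --i; --j; }
        else if (src == P_UP) state = 1;
        else state = 2;
      } else if (state == 1) {
        ops.push_back(1);
        state = pf[at] ? 0 : 1;
        --i;
      } else {
        ops.push_back(2);
        state = pe[at] ? 0 : 2;
        --j;
      }
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best,
                      _["q_start"] = best > 0 ? i + 1 : NA_INTEGER,
                      _["q_end"] = best > 0 ? bi : NA_INTEGER,
                      _["s_start"] = best > 0 ? j + 1 : NA_INTEGER,
                      _["s_end"] = best > 0 ? bj : NA_INTEGER,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}

// Needleman-Wunsch-Gotoh global alignment (end gaps penalised). Used by the
// center-star MSA; sequences there are full-length proteins, so full DP
// matrices are fine.
// [[Rcpp::export]]
List cpp_global_align(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                      int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size(), K = mat.nrow();
  const int *M = INTEGER(mat);
  const int go = gap_open + gap_extend, ge = gap_extend;

  std::vector<int> H((size_t)(n + 1) * (m + 1), NEG);
  std::vector<int> E((size_t)(n + 1) * (m + 1), NEG);
  std::vector<int> F((size_t)(n + 1) * (m + 1), NEG);
  std::vector<unsigned char> ph((size_t)(n + 1) * (m + 1)),
      pe((size_t)(n + 1) * (m + 1)), pf((size_t)(n + 1) * (m + 1));
  const size_t W = m + 1;

  H[0] = 0;
  for (int j = 1; j <= m; ++j) {
    E[j] = -go - (j - 1) * ge;
    H[j] = E[j];
    ph[j] = P_LEFT;
    pe[j] = (j == 1);
  }
  for (int i = 1; i <= n; ++i) {
    F[i * W] = -go - (i - 1) * ge;
    H[i * W] = F[i * W];
    ph[i * W] = P_UP;
    pf[i * W] = (i == 1);
  }
  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t at = i * W + j;
      const int eo = H[at - 1] - go, ee = E[at - 1] - ge;
      if (eo >= ee) { E[at] = eo; pe[at] = 1; } else { E[at] = ee; pe[at] = 0; }
      const int fo = H[at - W] - go, fe = F[at - W] - ge;
      if (fo >= fe) { F[at] = fo; pf[at] = 1; } else { F[at] = fe; pf[at] = 0; }
      int h = H[at - W - 1] + M[qi + (size_t)s[j - 1] * K];
      unsigned char src = P_DIAG;
      if (F[at] > h) { h = F[at]; src = P_UP; }
      if (E[at] > h) { h = E[at]; src = P_LEFT; }
      H[at] = h;
      ph[at] = src;
    }
  }

  std::vector<int> ops;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    const size_t at = (size_t)i * W + j;
    if (i == 0) { ops.push_back(2); --j; continue; }
    if (j == 0) { ops.push_back(1); --i; continue; }
    if (state == 0) {
      const unsigned char src = ph[at];
      if (src == P_DIAG) { ops.push_back(0); --i; --j; }
      else if (src == P_UP) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back(1);
      state = pf[at] ? 0 : 1;
      --i;
    } else {
      ops.push_back(2);
      state = pe[at] ? 0 : 2;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = H[(size_t)n * W + m],
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}

// Global score only (used by the center-star pair scoring and the oracle).
static int global_score(const int *q, int n, const int *s, int m,
                        const int *M, int K, int go, int ge) {
  if (n == 0 && m == 0) return 0;
  std::vector<int> H(m + 1), E(m + 1), F(m + 1, NEG);
  H[0] = 0;
  E[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    E[j] = -go - (j - 1) * ge;
    H[j] = E[j];
  }
  for (int i = 1; i <= n; ++i) {
    int diag = H[0];
    H[0] = -go - (i - 1) * ge;
    int e = NEG;
    int hleft = H[0];
    for (int j = 1; j <= m; ++j) {
      const int eo = hleft - go, ee = e - ge;
      e = eo >= ee ? eo : ee;
      const int fo = H[j] - go, fe = F[j] - ge;
      const int f = fo >= fe ? fo : fe;
      int h = diag + M[q[i - 1] + (size_t)s[j - 1] * K];
      if (f > h) h = f;
      if (e > h) h = e;
      diag = H[j];
      H[j] = h;
      F[j] = f;
      hleft = h;
    }
  }
  return H[m];
}

// [[Rcpp::export]]
int cpp_global_score(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                     int gap_open, int gap_extend) {
  return global_score(q.begin(), q.size(), s.begin(), s.size(),
                      INTEGER(mat), mat.nrow(),
                      gap_open + gap_extend, gap_extend);
}

// Brute-force local score: exhaustively enumerate every substring pair and
// take the best global alignment score over them (empty alignment scores 0).
// Deliberately a different decomposition from the SW recurrence; O(n^3 m^3),
// only for short sequences -- this is the test oracle.
// [[Rcpp::export]]
int cpp_bruteforce_local_score(IntegerVector q, IntegerVector s,
                               IntegerMatrix mat, int gap_open,
                               int gap_extend) {
  const int n = q.size(), m = s.size(), K = mat.nrow();
  const int *M = INTEGER(mat);
  const int go = gap_open + gap_extend, ge = gap_extend;
  int best = 0;
  for (int i1 = 0; i1 < n; ++i1)
    for (int i2 = i1; i2 < n; ++i2)
      for (int j1 = 0; j1 < m; ++j1)
        for (int j2 = j1; j2 < m; ++j2) {
          const int sc = global_score(q.begin() + i1, i2 - i1 + 1,
                                      s.begin() + j1, j2 - j1 + 1,
                                      M, K, go, ge);
          if (sc > best) best = sc;
        }
  return best;
}
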