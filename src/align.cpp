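#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Dynamic-programming alignment kernels (Gotoh affine-gap recurrences).
// Residues arrive as 0-based indices into the substitution matrix; character
// handling stays on the R side. A gap of length L scores gap_open +
// L * gap_extend (both <= 0), i.e. the BLAST existence/extension convention.

static const int NEG_INF = INT_MIN / 4;

// Local (Smith-Waterman) alignment, score and coordinates of the best hit.
// Start coordinates are propagated through the DP so ties at the best score
// resolve to the smallest (q_start, s_start), then the shortest alignment.
// [[Rcpp::export]]
List sw_align_idx(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                  int gap_open, int gap_extend) {
  const int m = q.size(), n = s.size();
  const int W = n + 1;
  std::vector<int> H((m + 1) * W, 0), E((m + 1) * W, NEG_INF),
      F((m + 1) * W, NEG_INF);
  // packed alignment start (q0 * (n+2) + s0) per state
  std::vector<int> Hs((m + 1) * W, 0), Es((m + 1) * W, 0), Fs((m + 1) * W, 0);
  const int PK = n + 2;

  int best = 0, best_i = 0, best_j = 0, best_start = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j, up = (i - 1) * W + j, left = i * W + (j - 1),
                diag = (i - 1) * W + (j - 1);
      // E: gap in query (consumes subject)
      int e_open = H[left] + gap_open + gap_extend;
      int e_ext = E[left] + gap_extend;
      if (e_open > e_ext || (e_open == e_ext && Hs[left] <= Es[left])) {
        E[idx] = e_open; Es[idx] = Hs[left];
      } else {
        E[idx] = e_ext; Es[idx] = Es[left];
      }
      // F: gap in subject (consumes query)
      int f_open = H[up] + gap_open + gap_extend;
      int f_ext = F[up] + gap_extend;
      if (f_open > f_ext || (f_open == f_ext && Hs[up] <= Fs[up])) {
        F[idx] = f_open; Fs[idx] = Hs[up];
      } else {
        F[idx] = f_ext; Fs[idx] = Fs[up];
      }
      // H: best of fresh start, diagonal, gap states
      int sub = mat(q[i - 1], s[j - 1]);
      int h_diag = H[diag] + sub;
      int h_start = (H[diag] == 0) ? i * PK + j : Hs[diag];
      int h = h_diag, hs = h_start;
      if (E[idx] > h || (E[idx] == h && Es[idx] < hs)) { h = E[idx]; hs = Es[idx]; }
      if (F[idx] > h || (F[idx] == h && Fs[idx] < hs)) { h = F[idx]; hs = Fs[idx]; }
      if (h <= 0) { h = 0; hs = (i + 1) * PK + (j + 1); }
      H[idx] = h; Hs[idx] = hs;
      if (h > best ||
          (h == best && h > 0 &&
           (hs < best_start ||
            (hs == best_start && (i + j) < (best_i + best_j))))) {
        best = h; best_i = i; best_j = j; best_start = hs;
      }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER);
  return List::create(_["score"] = best, _["q_start"] = best_start / PK,
                      _["q_end"] = best_i, _["s_start"] = best_start % PK,
                      _["s_end"] = best_j);
}

// Global alignment with free end gaps ("overlap" alignment). Returns the two
// aligned rows as index vectors with -1 marking a gap, plus the score of the
// aligned (non-end-gap) region.
// [[Rcpp::export]]
List overlap_align_idx(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                       int gap_open, int gap_extend) {
  const int m = q.size(), n = s.size();
  const int W = n + 1;
  std::vector<int> H((m + 1) * W, 0), E((m + 1) * W, NEG_INF),
      F((m + 1) * W, NEG_INF);
  // pointers: H: 0 = diag, 1 = from E, 2 = from F, 3 = free boundary start
  // E/F: 0 = opened from H, 1 = extended
  std::vector<signed char> Hp((m + 1) * W, 3), Ep((m + 1) * W, 0),
      Fp((m + 1) * W, 0);

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j, up = (i - 1) * W + j, left = i * W + (j - 1),
                diag = (i - 1) * W + (j - 1);
      int e_open = H[left] + gap_open + gap_extend;
      int e_ext = E[left] + gap_extend;
      if (e_open >= e_ext) { E[idx] = e_open; Ep[idx] = 0; }
      else { E[idx] = e_ext; Ep[idx] = 1; }
      int f_open = H[up] + gap_open + gap_extend;
      int f_ext = F[up] + gap_extend;
      if (f_open >= f_ext) { F[idx] = f_open; Fp[idx] = 0; }
      else { F[idx] = f_ext; Fp[idx] = 1; }
      int h = H[diag] + mat(q[i - 1], s[j - 1]);
      signed char hp = 0;
      // on ties prefer the gap state: keeps gaps internal rather than
      // trading them for free end gaps during traceback
      if (E[idx] >= h) { h = E[idx]; hp = 1; }
      if (F[idx] > h) { h = F[idx]; hp = 2; }
      H[idx] = h; Hp[idx] = hp;
    }
  }
  // free trailing gap: best cell on the last row or column (corner preferred)
  int best = H[m * W + n], bi = m, bj = n;
  for (int j = n - 1; j >= 0; --j)
    if (H[m * W + j] > best) { best = H[m * W + j]; bi = m; bj = j; }
  for (int i = m - 1; i >= 0; --i)
    if (H[i * W + n] > best) { best = H[i * W + n]; bi = i; bj = n; }

  std::vector<int> qa, sa;
  // trailing end gaps
  for (int j = n; j > bj; --j) { qa.push_back(-1); sa.push_back(s[j - 1]); }
  for (int i = m; i > bi; --i) { qa.push_back(q[i - 1]); sa.push_back(-1); }
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      signed char p = Hp[idx];
      if (p == 0) {
        qa.push_back(q[i - 1]); sa.push_back(s[j - 1]); --i; --j;
      } else if (p == 1) state = 1;
      else if (p == 2) state = 2;
      else break; // boundary start
    } else if (state == 1) {
      qa.push_back(-1); sa.push_back(s[j - 1]);
      state = (Ep[idx] == 0) ? 0 : 1; --j;
    } else {
      qa.push_back(q[i - 1]); sa.push_back(-1);
      state = (Fp[idx] == 0) ? 0 : 2; --i;
    }
  }
  // leading end gaps
  while (i > 0) { qa.push_back(q[i - 1]); sa.push_back(-1); --i; }
  while (j > 0) { qa.push_back(-1); sa.push_back(s[j - 1]); --j; }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(_["score"] = best, _["q_aln"] = wrap(qa),
                      _["s_aln"] = wrap(sa));
}
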