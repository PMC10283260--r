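#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels.
//
// Sequences arrive as 1-based integer codes into the substitution
// matrix. Gap scoring: the first residue of a gap costs `gap_open`,
// each further residue `gap_extend` (both negative).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector q, IntegerVector s, NumericMatrix sub,
              double gap_open, double gap_extend) {
  const int n = q.size(), m = s.size();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG_INF; F(0, j) = NEG_INF; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG_INF; F(i, 0) = NEG_INF; }

  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) + gap_open, E(i, j - 1) + gap_extend);
      F(i, j) = std::max(H(i - 1, j) + gap_open, F(i - 1, j) + gap_extend);
      double diag = H(i - 1, j - 1) + sub(q[i - 1] - 1, s[j - 1] - 1);
      double h = std::max(0.0, std::max(diag, std::max(E(i, j), F(i, j))));
      H(i, j) = h;
      if (h > best) best = h;
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["query_start"] = NA_INTEGER,
                        _["query_end"] = NA_INTEGER,
                        _["subject_start"] = NA_INTEGER,
                        _["subject_end"] = NA_INTEGER);

  // all optimal end cells -> traceback each -> tie-break on
  // (subject_start, query_start, subject_end, query_end)
  int bq0 = -1, bq1 = -1, bs0 = -1, bs1 = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (H(i, j) != best) continue;
      int ci = i, cj = j;
      char state = 'H';
      while (true) {
        if (state == 'H') {
          double h = H(ci, cj);
          if (h == 0.0) break;
          double diag = H(ci - 1, cj - 1) + sub(q[ci - 1] - 1, s[cj - 1] - 1);
          if (h == diag) { --ci; --cj; }
          else if (h == E(ci, cj)) state = 'E';
          else state = 'F';
        } else if (state == 'E') {
          if (E(ci, cj) == H(ci, cj - 1) + gap_open) { --cj; state = 'H'; }
          else { --cj; }
        } else {
          if (F(ci, cj) == H(ci - 1, cj) + gap_open) { --ci; state = 'H'; }
          else { --ci; }
        }
      }
      // alignment covers query (ci+1 .. i), subject (cj+1 .. j), 1-based
      int q0 = ci + 1, s0 = cj + 1;
      bool better = false;
      if (bs0 < 0) better = true;
      else if (s0 != bs0) better = s0 < bs0;
      else if (q0 != bq0) better = q0 < bq0;
      else if (j != bs1) better = j < bs1;
      else better = i < bq1;
      if (better) { bq0 = q0; bq1 = i; bs0 = s0; bs1 = j; }
    }
  }
  return List::create(_["score"] = best, _["query_start"] = bq0,
                      _["query_end"] = bq1, _["subject_start"] = bs0,
                      _["subject_end"] = bs1);
}

// Global (end-gap penalized) alignment; returns the score and, for each
// query position, the 1-based subject position aligned to it (0 = gap).
// Traceback prefers diagonal, then vertical, then horizontal moves.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(IntegerVector q, IntegerVector s, NumericMatrix sub,
              double gap_open, double gap_extend) {
  const int n = q.size(), m = s.size();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  H(0, 0) = 0.0; E(0, 0) = NEG_INF; F(0, 0) = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    E(0, j) = gap_open + (j - 1) * gap_extend;
    H(0, j) = E(0, j);
    F(0, j) = NEG_INF;
  }
  for (int i = 1; i <= n; ++i) {
    F(i, 0) = gap_open + (i - 1) * gap_extend;
    H(i, 0) = F(i, 0);
    E(i, 0) = NEG_INF;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) + gap_open, E(i, j - 1) + gap_extend);
      F(i, j) = std::max(H(i - 1, j) + gap_open, F(i - 1, j) + gap_extend);
      double diag = H(i - 1, j - 1) + sub(q[i - 1] - 1, s[j - 1] - 1);
      H(i, j) = std::max(diag, std::max(E(i, j), F(i, j)));
    }
  }

  IntegerVector map(n, 0);
  int ci = n, cj = m;
  char state = 'H';
  while (ci > 0 || cj > 0) {
    if (state == 'H') {
      if (ci > 0 && cj > 0 &&
          H(ci, cj) == H(ci - 1, cj - 1) + sub(q[ci - 1] - 1, s[cj - 1] - 1)) {
        map[ci - 1] = cj; --ci; --cj;
      } else if (ci > 0 && H(ci, cj) == F(ci, cj)) {
        state = 'F';
      } else if (cj > 0 && H(ci, cj) == E(ci, cj)) {
        state = 'E';
      } else if (ci > 0) {  // boundary column
        --ci;
      } else {
        --cj;
      }
    } else if (state == 'F') {
      if (F(ci, cj) == H(ci - 1, cj) + gap_open) { --ci; state = 'H'; }
      else { --ci; }
    } else {
      if (E(ci, cj) == H(ci, cj - 1) + gap_open) { --cj; state = 'H'; }
      else { --cj; }
    }
  }
  return List::create(_["score"] = H(n, m), _["subject_map"] = map);
}
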