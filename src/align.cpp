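// Alignment and duplex-energy dynamic programming kernels.
//
// Sequences arrive as integer vectors with A=0, C=1, G=2, U=3.
// All tie-breaks are deterministic and documented at the R wrappers.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- local SW

// Smith-Waterman with linear gap penalty; returns best score and, via
// traceback, the 1-based closed intervals of the optimal hit. Among co-optimal
// hits the one with the lowest subject start, then lowest query start, then
// lowest subject end, then lowest query end is chosen. Traceback prefers
// diagonal, then up (gap in subject), then left (gap in query).
// [[Rcpp::export]]
List cw_smith_waterman(IntegerVector q, IntegerVector s,
                       double match, double mismatch, double gap) {
  const int n = q.size(), m = s.size();
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, 0.0));
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H[i - 1][j - 1] + (q[i - 1] == s[j - 1] ? match : mismatch);
      double up = H[i - 1][j] + gap;
      double left = H[i][j - 1] + gap;
      double v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0.0) v = 0.0;
      H[i][j] = v;
      if (v > best) best = v;
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);
  }
  int bqs = -1, bqe = -1, bss = -1, bse = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (H[i][j] != best) continue;
      // traceback from (i, j)
      int ci = i, cj = j;
      while (H[ci][cj] > 0.0) {
        double v = H[ci][cj];
        double diag = (ci > 0 && cj > 0)
          ? H[ci - 1][cj - 1] + (q[ci - 1] == s[cj - 1] ? match : mismatch)
          : -INF;
        if (ci > 0 && cj > 0 && v == diag) { --ci; --cj; continue; }
        if (ci > 0 && v == H[ci - 1][cj] + gap) { --ci; continue; }
        if (cj > 0 && v == H[ci][cj - 1] + gap) { --cj; continue; }
        break;  // v == 0 handled by loop condition; safety
      }
      int qs = ci + 1, ss = cj + 1;  // 1-based starts
      bool better = false;
      if (bss < 0) better = true;
      else if (ss != bss) better = ss < bss;
      else if (qs != bqs) better = qs < bqs;
      else if (j != bse) better = j < bse;
      else better = i < bqe;
      if (better) { bqs = qs; bqe = i; bss = ss; bse = j; }
    }
  }
  return List::create(_["score"] = best, _["q_start"] = bqs, _["q_end"] = bqe,
                      _["s_start"] = bss, _["s_end"] = bse);
}

// Batch SW scores only (no traceback); used for Monte-Carlo E-value checks.
// [[Rcpp::export]]
NumericVector cw_sw_score_many(List qs, List ss,
                               double match, double mismatch, double gap) {
  const int N = qs.size();
  NumericVector out(N);
  for (int k = 0; k < N; ++k) {
    IntegerVector q = qs[k], s = ss[k];
    const int n = q.size(), m = s.size();
    std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
      cur[0] = 0.0;
      for (int j = 1; j <= m; ++j) {
        double diag = prev[j - 1] + (q[i - 1] == s[j - 1] ? match : mismatch);
        double up = prev[j] + gap;
        double left = cur[j - 1] + gap;
        double v = diag;
        if (up > v) v = up;
        if (left > v) v = left;
        if (v < 0.0) v = 0.0;
        cur[j] = v;
        if (v > best) best = v;
      }
      std::swap(prev, cur);
    }
    out[k] = best;
  }
  return out;
}

// ---------------------------------------------------------------- global NW

// Needleman-Wunsch, linear gap penalty, full global alignment. Returns the
// optimal score plus the match and column counts of one optimal alignment,
// chosen by a traceback that prefers diagonal, then up, then left.
// [[Rcpp::export]]
List cw_needleman(IntegerVector a, IntegerVector b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, 0.0));
  for (int i = 1; i <= n; ++i) H[i][0] = i * gap;
  for (int j = 1; j <= m; ++j) H[0][j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up = H[i - 1][j] + gap;
      double left = H[i][j - 1] + gap;
      double v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      H[i][j] = v;
    }
  }
  int i = n, j = m, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        H[i][j] == H[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch)) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && H[i][j] == H[i - 1][j] + gap) {
      --i;
    } else {
      --j;
    }
    ++columns;
  }
  return List::create(_["score"] = H[n][m], _["matches"] = matches,
                      _["columns"] = columns);
}

// ------------------------------------------------- tail dissimilarity (edit)

// Minimum unit-cost edit alignment of `tail` against a prefix-anchored region
// of `rext` (the reverse complement of the target-side extension, so that a
// perfectly pairing tail matches it letter for letter). Gaps on either strand
// cost 1 per nucleotide and at most `max_bulge` total gap nucleotides are
// allowed; unused trailing rext is free.
static double tail_dissim_one(const IntegerVector& tail, const IntegerVector& rext,
                              int max_bulge) {
  const int n = tail.size(), m = rext.size(), B = max_bulge;
  if (n == 0) return 0.0;
  // D[g][i][j]: min cost aligning tail[0..i) to rext[0..j) using g gap nts
  std::vector<std::vector<std::vector<double>>> D(
      B + 1, std::vector<std::vector<double>>(n + 1, std::vector<double>(m + 1, INF)));
  for (int g = 0; g <= B; ++g)
    for (int i = 0; i <= std::min(g, n); ++i) D[g][i][0] = i;    // leading gaps in rext
  for (int g = 0; g <= B; ++g)
    for (int j = 0; j <= std::min(g, m); ++j) D[g][0][j] = j;    // leading gaps in tail
  for (int g = 0; g <= B; ++g) {
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        double v = D[g][i - 1][j - 1] + (tail[i - 1] == rext[j - 1] ? 0.0 : 1.0);
        if (g > 0) {
          double up = D[g - 1][i - 1][j] + 1.0;   // unpaired tail nt
          double left = D[g - 1][i][j - 1] + 1.0; // unpaired rext nt (bulge)
          if (up < v) v = up;
          if (left < v) v = left;
        }
        D[g][i][j] = v;
      }
    }
  }
  double best = INF;
  for (int g = 0; g <= B; ++g)
    for (int j = 0; j <= m; ++j)
      if (D[g][n][j] < best) best = D[g][n][j];
  return best;
}

// [[Rcpp::export]]
double cw_tail_dissim(IntegerVector tail, IntegerVector rext, int max_bulge) {
  return tail_dissim_one(tail, rext, max_bulge);
}

// [[Rcpp::export]]
NumericVector cw_tail_dissim_many(List tails, List rexts, int max_bulge) {
  const int N = tails.size();
  NumericVector out(N);
  for (int k = 0; k < N; ++k)
    out[k] = tail_dissim_one(tails[k], rexts[k], max_bulge);
  return out;
}

// ------------------------------------------------------------ duplex energy

// Base-pair type id for (x, y): AU=0 UA=1 CG=2 GC=3 GU=4 UG=5, -1 if unpaired.
static int pair_id(int x, int y) {
  if (x == 0 && y == 3) return 0;
  if (x == 3 && y == 0) return 1;
  if (x == 1 && y == 2) return 2;
  if (x == 2 && y == 1) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

// Minimum free energy of a co-linear antiparallel duplex between strand a
// (5'->3') and strand b, where b has already been REVERSED (not complemented)
// by the caller so both indices increase together. `stack` is a 6x6 matrix of
// nearest-neighbor stack energies indexed by (pair1, pair2). Consecutive pairs
// with no intervening unpaired nucleotides gain the stack energy; otherwise a
// loop/bulge penalty `loop_open + loop_ext * (extra unpaired nt)` applies,
// with at most `max_loop` unpaired nucleotides per strand between pairs.
// A duplex with no pairs (or none possible) costs `init` alone.
static double duplex_one(const IntegerVector& a, const IntegerVector& b,
                         const NumericMatrix& stack, double init,
                         double loop_open, double loop_ext, int max_loop) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<double>> E(n, std::vector<double>(m, INF));
  double best = init;  // no pairing at all
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      int p = pair_id(a[i], b[j]);
      if (p < 0) continue;
      double v = init;  // (i, j) opens the duplex
      const int ilo = std::max(0, i - 1 - max_loop);
      const int jlo = std::max(0, j - 1 - max_loop);
      for (int ip = i - 1; ip >= ilo; --ip) {
        for (int jp = j - 1; jp >= jlo; --jp) {
          if (E[ip][jp] == INF) continue;
          int pp = pair_id(a[ip], b[jp]);
          double step;
          if (ip == i - 1 && jp == j - 1) {
            step = stack(pp, p);
          } else {
            int extra = (i - ip - 1) + (j - jp - 1);
            step = loop_open + loop_ext * (extra - 1);
          }
          double cand = E[ip][jp] + step;
          if (cand < v) v = cand;
        }
      }
      E[i][j] = v;
      if (v < best) best = v;
    }
  }
  return best;
}

// [[Rcpp::export]]
double cw_duplex_energy(IntegerVector a, IntegerVector b_rev, NumericMatrix stack,
                        double init, double loop_open, double loop_ext,
                        int max_loop) {
  return duplex_one(a, b_rev, stack, init, loop_open, loop_ext, max_loop);
}

// [[Rcpp::export]]
NumericVector cw_duplex_energy_many(List as, List bs_rev, NumericMatrix stack,
                                    double init, double loop_open,
                                    double loop_ext, int max_loop) {
  const int N = as.size();
  NumericVector out(N);
  for (int k = 0; k < N; ++k)
    out[k] = duplex_one(as[k], bs_rev[k], stack, init, loop_open, loop_ext,
                        max_loop);
  return out;
}
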