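#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP). A gap of length L
// costs gapOpen + L * gapExt (both arguments are negative scores).
// States: M (a[i] ~ b[j]), X (gap in b, a consumed), Y (gap in a).
// local = Smith-Waterman (M may restart at 0, best cell wins);
// global = Needleman-Wunsch over the full sequences.

static const double NEG = -1e18;

// [[Rcpp::export(name = ".align_cpp")]]
List align_cpp(std::string a, std::string b,
               double match, double mismatch,
               double gapOpen, double gapExt,
               bool local) {
  const int n = (int)a.size(), m = (int)b.size();
  const int w = m + 1;
  std::vector<double> M((size_t)(n + 1) * w, NEG), X((size_t)(n + 1) * w, NEG),
      Y((size_t)(n + 1) * w, NEG);
  // traceback codes: 0 = (re)start, 1 = from M, 2 = from X, 3 = from Y
  std::vector<unsigned char> tM((size_t)(n + 1) * w, 0),
      tX((size_t)(n + 1) * w, 0), tY((size_t)(n + 1) * w, 0);

  M[0] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      X[(size_t)i * w] = gapOpen + i * gapExt;
      tX[(size_t)i * w] = (i == 1) ? 1 : 2;
    }
    for (int j = 1; j <= m; ++j) {
      Y[j] = gapOpen + j * gapExt;
      tY[j] = (j == 1) ? 1 : 3;
    }
  }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t k = (size_t)i * w + j, kd = (size_t)(i - 1) * w + (j - 1),
                   ku = (size_t)(i - 1) * w + j, kl = (size_t)i * w + (j - 1);
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double v = M[kd];
      unsigned char t = 1;
      if (X[kd] > v) { v = X[kd]; t = 2; }
      if (Y[kd] > v) { v = Y[kd]; t = 3; }
      if (local && v < 0.0) { v = 0.0; t = 0; }
      M[k] = v + s; tM[k] = t;
      double vo = M[ku] + gapOpen + gapExt, ve = X[ku] + gapExt;
      if (vo >= ve) { X[k] = vo; tX[k] = 1; } else { X[k] = ve; tX[k] = 2; }
      vo = M[kl] + gapOpen + gapExt; ve = Y[kl] + gapExt;
      if (vo >= ve) { Y[k] = vo; tY[k] = 1; } else { Y[k] = ve; tY[k] = 3; }
      if (local && M[k] > best) { best = M[k]; bi = i; bj = j; }
    }
  }

  int i, j;
  unsigned char state;
  if (local) {
    if (bi == 0) // no positive-scoring pair
      return List::create(_["score"] = 0.0, _["a_aln"] = "", _["b_aln"] = "",
                          _["a_start"] = 0, _["a_end"] = -1,
                          _["b_start"] = 0, _["b_end"] = -1);
    i = bi; j = bj; state = 1;
  } else {
    const size_t k = (size_t)n * w + m;
    best = M[k]; state = 1;
    if (X[k] > best) { best = X[k]; state = 2; }
    if (Y[k] > best) { best = Y[k]; state = 3; }
    i = n; j = m;
  }
  const int ae = local ? bi : n, be = local ? bj : m;

  std::string aa, bb;
  while (i > 0 || j > 0) {
    if (state == 1) {
      if (i == 0 || j == 0) break; // global corner via edge inits
      const size_t k = (size_t)i * w + j;
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      const unsigned char prev = tM[k];
      --i; --j;
      if (local && prev == 0) break;
      state = prev == 0 ? 1 : prev;
    } else if (state == 2) {
      aa.push_back(a[i - 1]); bb.push_back('-');
      const unsigned char prev = tX[(size_t)i * w + j];
      --i; state = prev;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]);
      const unsigned char prev = tY[(size_t)i * w + j];
      --j; state = prev;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(_["score"] = best, _["a_aln"] = aa, _["b_aln"] = bb,
                      _["a_start"] = local ? i + 1 : 1, _["a_end"] = ae,
                      _["b_start"] = local ? j + 1 : 1, _["b_end"] = be);
}

// Ungapped X-drop extension along a fixed diagonal, used by the copy
// finder. Walks outward from the already-matching anchor (ga, ca)
// (1-based) in direction dir (+1 right, -1 left) and stops once the
// running score falls more than xdrop below its maximum. Returns the
// number of additional bases included at the score maximum.
// [[Rcpp::export(name = ".xdrop_extend_cpp")]]
int xdrop_extend_cpp(std::string g, std::string c,
                     int ga, int ca, int dir,
                     double match, double mismatch, double xdrop) {
  int best_k = 0, k = 0;
  double sc = 0.0, best = 0.0;
  const int ng = (int)g.size(), nc = (int)c.size();
  while (true) {
    ++k;
    const int gi = ga - 1 + dir * k, ci = ca - 1 + dir * k;
    if (gi < 0 || ci < 0 || gi >= ng || ci >= nc) break;
    sc += (g[gi] == c[ci]) ? match : mismatch;
    if (sc > best) { best = sc; best_k = k; }
    if (best - sc > xdrop) break;
  }
  return best_k;
}
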