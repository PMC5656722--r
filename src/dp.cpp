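// Dynamic-programming cores for multi-layer wall segmentation.
//
// The 4D front propagation relaxes states (y1, y2, y3) column by column.
// The joint min over (dy1, dy2, dy3) is computed as three nested 1D mins
// (dy1 outermost), which is exact because the transition cost is additive
// across interfaces; nested smallest-dy tie-breaks therefore realise the
// lexicographically smallest minimising (dy1, dy2, dy3).
#include <Rcpp.h>
#include <vector>
#include <array>
#include <functional>
#include <limits>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const int8_t NOPRED = 127;

// state layout: y3 is the fastest-varying axis so that every relaxation
// pass can stream contiguous memory
static inline int idx3(int y1, int y2, int y3, int d) {
  return y3 + d * (y2 + d * y1);
}

// Forward pass of the 4D cumulative cost. Cp/Cm are depth x width cost maps
// (C+ drives interfaces 1 and 3, C- interface 2). States obey
// y1 + gap <= y2 <= y3 - gap. Column 0 is initialised to zero cost.
// Returns the final-column value cube and per-column argmin displacement
// cubes for the three nested minimisations (needed for backtracking).
// [[Rcpp::export(name = ".ml_dp_forward")]]
List ml_dp_forward(NumericMatrix Cp, NumericMatrix Cm, NumericVector omega,
                   double kappa, int N, int gap) {
  const int d = Cp.nrow(), w = Cp.ncol();
  if (d < 2 * gap + 1) stop("depth too small for gap constraint");
  const double w1 = omega[0], w2 = omega[1], w3 = omega[2];
  const size_t cube = (size_t)d * d * d;

  std::vector<double> V(cube, INF), A(cube, INF), B(cube, INF), Vn(cube, INF);
  // admissible initial states: zero cost
  for (int y3 = 2 * gap; y3 < d; ++y3)
    for (int y2 = gap; y2 <= y3 - gap; ++y2)
      for (int y1 = 0; y1 <= y2 - gap; ++y1)
        V[idx3(y1, y2, y3, d)] = 0.0;

  RawVector a1(cube * w), a2(cube * w), a3(cube * w);
  std::fill(a1.begin(), a1.end(), (Rbyte)NOPRED);
  std::fill(a2.begin(), a2.end(), (Rbyte)NOPRED);
  std::fill(a3.begin(), a3.end(), (Rbyte)NOPRED);

  for (int x = 1; x < w; ++x) {
    const size_t off = cube * (size_t)x;
    // pass A: min over dy3. A(y1p, y2p, y3new); y3 contiguous
    std::fill(A.begin(), A.end(), INF);
    for (int y1p = 0; y1p < d - 2 * gap; ++y1p) {
      for (int y2p = y1p + gap; y2p < d - gap; ++y2p) {
        const size_t base = (size_t)idx3(y1p, y2p, 0, d);
        const double* Vb = V.data() + base;
        double* Ab = A.data() + base;
        Rbyte* a3b = a3.begin() + off + base;
        for (int y3 = std::max(0, y2p + gap - N); y3 < d; ++y3) {
          double best = INF; int bdy = NOPRED;
          for (int dy = -N; dy <= N; ++dy) {
            const int y3p = y3 + dy;
            if (y3p < y2p + gap || y3p >= d) continue;
            const double v = Vb[y3p];
            if (v == INF) continue;
            const double c = v + w3 * (1.0 + kappa * std::abs((double)dy)) *
                                      (Cp(y3, x) + Cp(y3p, x - 1));
            if (c < best) { best = c; bdy = dy; }
          }
          if (bdy != NOPRED) {
            Ab[y3] = best;
            a3b[y3] = (Rbyte)(int8_t)bdy;
          }
        }
      }
    }
    // pass B: min over dy2. B(y1p, y2new, y3new); dy2 outer, y3 inner
    std::fill(B.begin(), B.end(), INF);
    for (int y1p = 0; y1p < d - 2 * gap; ++y1p) {
      for (int y2 = std::max(0, y1p + gap - N); y2 < d - gap; ++y2) {
        double* Bb = B.data() + idx3(y1p, y2, 0, d);
        Rbyte* a2b = a2.begin() + off + idx3(y1p, y2, 0, d);
        const int y3lo = y2 + gap;
        for (int dy = -N; dy <= N; ++dy) {
          const int y2p = y2 + dy;
          if (y2p < y1p + gap || y2p >= d) continue;
          const double t = w2 * (1.0 + kappa * std::abs((double)dy)) ;
          const double tc = t * (Cm(y2, x) + Cm(y2p, x - 1));
          const double* Apb = A.data() + idx3(y1p, y2p, 0, d);
          for (int y3 = y3lo; y3 < d; ++y3) {
            const double v = Apb[y3];
            if (v == INF) continue;
            const double c = v + tc;
            if (c < Bb[y3]) { Bb[y3] = c; a2b[y3] = (Rbyte)(int8_t)dy; }
          }
        }
      }
    }
    // pass C: min over dy1, onto admissible new states; dy1 outer
    std::fill(Vn.begin(), Vn.end(), INF);
    for (int y1 = 0; y1 < d - 2 * gap; ++y1) {
      for (int y2 = y1 + gap; y2 < d - gap; ++y2) {
        double* Vb = Vn.data() + idx3(y1, y2, 0, d);
        Rbyte* a1b = a1.begin() + off + idx3(y1, y2, 0, d);
        const int y3lo = y2 + gap;
        for (int dy = -N; dy <= N; ++dy) {
          const int y1p = y1 + dy;
          if (y1p < 0 || y1p >= d) continue;
          const double tc = w1 * (1.0 + kappa * std::abs((double)dy)) *
                            (Cp(y1, x) + Cp(y1p, x - 1));
          const double* Bpb = B.data() + idx3(y1p, y2, 0, d);
          for (int y3 = y3lo; y3 < d; ++y3) {
            const double v = Bpb[y3];
            if (v == INF) continue;
            const double c = v + tc;
            if (c < Vb[y3]) { Vb[y3] = c; a1b[y3] = (Rbyte)(int8_t)dy; }
          }
        }
      }
    }
    V.swap(Vn);
  }

  NumericVector fin(cube);
  for (size_t i = 0; i < cube; ++i) fin[i] = V[i];
  return List::create(_["final"] = fin, _["a1"] = a1, _["a2"] = a2,
                      _["a3"] = a3, _["depth"] = d, _["width"] = w,
                      _["N"] = N, _["gap"] = gap);
}

// Backtrack the stored argmins from the lexicographically smallest minimal
// final state. Returns 0-based path rows (3 x width) plus the optimal cost.
// [[Rcpp::export(name = ".ml_dp_backtrack")]]
List ml_dp_backtrack(NumericVector fin, RawVector a1, RawVector a2,
                     RawVector a3, int d, int w, int gap) {
  const size_t cube = (size_t)d * d * d;
  double best = INF; int by1 = -1, by2 = -1, by3 = -1;
  for (int y1 = 0; y1 < d - 2 * gap; ++y1)
    for (int y2 = y1 + gap; y2 < d - gap; ++y2)
      for (int y3 = y2 + gap; y3 < d; ++y3) {
        const double v = fin[idx3(y1, y2, y3, d)];
        if (v < best) { best = v; by1 = y1; by2 = y2; by3 = y3; }
      }
  if (by1 < 0) stop("cumulative cost has no admissible final state");

  IntegerMatrix path(3, w);
  int y1 = by1, y2 = by2, y3 = by3;
  path(0, w - 1) = y1; path(1, w - 1) = y2; path(2, w - 1) = y3;
  for (int x = w - 1; x >= 1; --x) {
    const size_t off = cube * (size_t)x;
    const int dy1 = (int8_t)a1[off + idx3(y1, y2, y3, d)];
    const int y1p = y1 + dy1;
    const int dy2 = (int8_t)a2[off + idx3(y1p, y2, y3, d)];
    const int y2p = y2 + dy2;
    const int dy3 = (int8_t)a3[off + idx3(y1p, y2p, y3, d)];
    const int y3p = y3 + dy3;
    y1 = y1p; y2 = y2p; y3 = y3p;
    path(0, x - 1) = y1; path(1, x - 1) = y2; path(2, x - 1) = y3;
  }
  return List::create(_["path"] = path, _["cost"] = best);
}

// Single-contour DP on a cost matrix, restricted to a per-column band
// [center - half, center + half] (half < 0 means the full depth range) and
// to rows >= lower (per column; < 0 means unrestricted). Same transition
// cost model as one interface of the 4D scheme.
// [[Rcpp::export(name = ".band_dp")]]
List band_dp(NumericMatrix C, IntegerVector center, int half,
             IntegerVector lower, double omega, double kappa, int N) {
  const int d = C.nrow(), w = C.ncol();
  auto lo = [&](int x) {
    int l = 0;
    if (half >= 0) l = std::max(l, center[x] - half);
    if (lower[x] >= 0) l = std::max(l, lower[x]);
    return std::min(l, d - 1);
  };
  auto hi = [&](int x) {
    int h = d - 1;
    if (half >= 0) h = std::min(h, center[x] + half);
    return std::max(h, lo(x));
  };
  std::vector<double> V(d, INF), Vn(d, INF);
  std::vector<int8_t> pred((size_t)d * w, NOPRED);
  for (int y = lo(0); y <= hi(0); ++y) V[y] = 0.0;
  for (int x = 1; x < w; ++x) {
    std::fill(Vn.begin(), Vn.end(), INF);
    const int l = lo(x), h = hi(x), lp = lo(x - 1), hp = hi(x - 1);
    for (int y = l; y <= h; ++y) {
      double best = INF; int bdy = NOPRED;
      for (int dy = -N; dy <= N; ++dy) {
        const int yp = y + dy;
        if (yp < lp || yp > hp) continue;
        if (V[yp] == INF) continue;
        const double c = V[yp] + omega * (1.0 + kappa * std::abs((double)dy)) *
                                   (C(y, x) + C(yp, x - 1));
        if (c < best) { best = c; bdy = dy; }
      }
      if (bdy != NOPRED) { Vn[y] = best; pred[(size_t)d * x + y] = (int8_t)bdy; }
    }
    V.swap(Vn);
  }
  double best = INF; int by = -1;
  for (int y = 0; y < d; ++y) if (V[y] < best) { best = V[y]; by = y; }
  if (by < 0) stop("band DP has no feasible path");
  IntegerVector path(w);
  int y = by; path[w - 1] = y;
  for (int x = w - 1; x >= 1; --x) {
    y += pred[(size_t)d * x + y];
    path[x - 1] = y;
  }
  return List::create(_["path"] = path, _["cost"] = best);
}

// Exhaustive-enumeration oracle over all admissible non-crossing triple
// paths with |dy| <= N per step. Independent of the front-propagation code
// path: it walks the full enumeration tree, accumulating cost, and keeps
// the best path under the same tie rule as backtracking (smaller cost; on
// ties, lexicographically smaller state sequence read from the last column
// backwards). Aborts once the number of path extensions exceeds `bound`.
// [[Rcpp::export(name = ".ml_dp_oracle")]]
List ml_dp_oracle(NumericMatrix Cp, NumericMatrix Cm, NumericVector omega,
                  double kappa, int N, int gap, double bound) {
  const int d = Cp.nrow(), w = Cp.ncol();
  if (d < 2 * gap + 1) stop("depth too small for gap constraint");
  const double w1 = omega[0], w2 = omega[1], w3 = omega[2];

  std::vector<std::array<int, 3>> states;
  for (int y1 = 0; y1 < d - 2 * gap; ++y1)
    for (int y2 = y1 + gap; y2 < d - gap; ++y2)
      for (int y3 = y2 + gap; y3 < d; ++y3)
        states.push_back({y1, y2, y3});

  double bestCost = INF;
  std::vector<std::array<int, 3>> bestPath, cur((size_t)w);
  double nExt = 0.0;
  bool exceeded = false;
  const double tol = 1e-12;

  // compare candidate `cur` against bestPath: reverse-lexicographic
  auto betterTie = [&](void) {
    for (int x = w - 1; x >= 0; --x)
      for (int k = 0; k < 3; ++k) {
        if (cur[x][k] < bestPath[x][k]) return true;
        if (cur[x][k] > bestPath[x][k]) return false;
      }
    return false;
  };

  std::function<void(int, double)> rec = [&](int x, double cost) {
    if (exceeded) return;
    if (x == w) {
      if (cost < bestCost - tol) { bestCost = cost; bestPath = cur; }
      else if (cost <= bestCost + tol && !bestPath.empty() && betterTie()) {
        bestCost = std::min(bestCost, cost); bestPath = cur;
      }
      return;
    }
    const auto& p = cur[x - 1];
    for (int dy1 = -N; dy1 <= N; ++dy1) {
      const int y1 = p[0] + dy1; // note: dy here is new - old; sign symmetric
      if (y1 < 0 || y1 >= d) continue;
      for (int dy2 = -N; dy2 <= N; ++dy2) {
        const int y2 = p[1] + dy2;
        if (y2 < y1 + gap || y2 >= d) continue;
        for (int dy3 = -N; dy3 <= N; ++dy3) {
          const int y3 = p[2] + dy3;
          if (y3 < y2 + gap || y3 >= d) continue;
          nExt += 1.0;
          if (nExt > bound) { exceeded = true; return; }
          const double step =
              w1 * (1.0 + kappa * std::abs((double)dy1)) * (Cp(y1, x) + Cp(p[0], x - 1)) +
              w2 * (1.0 + kappa * std::abs((double)dy2)) * (Cm(y2, x) + Cm(p[1], x - 1)) +
              w3 * (1.0 + kappa * std::abs((double)dy3)) * (Cp(y3, x) + Cp(p[2], x - 1));
          cur[x] = {y1, y2, y3};
          rec(x + 1, cost + step);
          if (exceeded) return;
        }
      }
    }
  };

  for (const auto& s : states) {
    cur[0] = s;
    nExt += 1.0;
    if (nExt > bound) { exceeded = true; break; }
    if (w == 1) {
      if (0.0 < bestCost - tol) { bestCost = 0.0; bestPath = cur; }
      else if (!bestPath.empty() && betterTie()) bestPath = cur;
      continue;
    }
    rec(1, 0.0);
    if (exceeded) break;
  }
  if (exceeded) stop("oracle bound exceeded");

  IntegerMatrix path(3, w);
  for (int x = 0; x < w; ++x)
    for (int k = 0; k < 3; ++k) path(k, x) = bestPath[x][k];
  return List::create(_["path"] = path, _["cost"] = bestCost,
                      _["extensions"] = nExt);
}
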