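#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
using namespace Rcpp;

// Minimum-free-energy secondary structure by Zuker-style dynamic programming
// over a simplified nearest-neighbor model:
//   - non-crossing base pairs (AT/TA/GC/CG/GT/TG), min hairpin loop 3 nt
//   - helix stacks scored by a 6x6 pair-type table (kcal/mol)
//   - hairpin / interior-bulge loops: logarithmic size penalties
//   - multiloops: affine closure + per-branch penalty, unpaired bases free
// Interior loops larger than max_interior are disallowed.
// Parameters are passed in from R so the exhaustive enumerator used as a
// test oracle scores structures under the identical model.

static const double INF = 1e9;

static inline int pair_type(char a, char b) {
  // 0 AT, 1 TA, 2 CG, 3 GC, 4 GT, 5 TG; -1 not pairable
  if (a == 'A' && b == 'T') return 0;
  if (a == 'T' && b == 'A') return 1;
  if (a == 'C' && b == 'G') return 2;
  if (a == 'G' && b == 'C') return 3;
  if (a == 'G' && b == 'T') return 4;
  if (a == 'T' && b == 'G') return 5;
  return -1;
}

// [[Rcpp::export]]
double mfe_cpp(std::string seq, NumericMatrix stack, List par) {
  const int n = (int) seq.size();
  if (n == 0) return 0.0;
  const double hairpin_a = as<double>(par["hairpin_a"]);
  const double hairpin_ln = as<double>(par["hairpin_ln"]);
  const double loop_a = as<double>(par["loop_a"]);
  const double loop_ln = as<double>(par["loop_ln"]);
  const double ml_a = as<double>(par["ml_a"]);
  const double ml_b = as<double>(par["ml_b"]);
  const int min_hairpin = as<int>(par["min_hairpin"]);
  const int max_interior = as<int>(par["max_interior"]);

  std::vector<double> V((size_t) n * n, INF), WM((size_t) n * n, INF);
  #define IDX(i, j) ((size_t)(i) * (size_t)(n) + (size_t)(j))

  for (int d = min_hairpin + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int pt = pair_type(seq[i], seq[j]);
      double v = INF;
      if (pt >= 0) {
        int L = j - i - 1;
        // hairpin closed by (i,j)
        v = hairpin_a + (L > min_hairpin ?
                         hairpin_ln * std::log((double) L / min_hairpin) : 0.0);
        // helix stack / interior loop with single inner pair (p,q)
        for (int p = i + 1; p < j; ++p) {
          int lo = p - i - 1;
          if (lo > max_interior) break;
          for (int q = j - 1; q > p; --q) {
            int size = lo + (j - q - 1);
            if (size > max_interior) continue;
            int pt2 = pair_type(seq[p], seq[q]);
            if (pt2 < 0) continue;
            double inner = V[IDX(p, q)];
            if (inner >= INF) continue;
            double e;
            if (size == 0)
              e = stack(pt, pt2);
            else
              e = loop_a + loop_ln * std::log((double) size);
            if (inner + e < v) v = inner + e;
          }
        }
        // multiloop: >= 2 branches inside, closing pair is a branch too
        for (int k = i + 1; k < j - 1; ++k) {
          double a = WM[IDX(i + 1, k)], b = WM[IDX(k + 1, j - 1)];
          if (a >= INF || b >= INF) continue;
          double e = ml_a + ml_b + a + b;
          if (e < v) v = e;
        }
      }
      V[IDX(i, j)] = v;
      // WM: minimum energy of >= 1 branches within [i, j], ml_b per branch
      double wm = INF;
      if (v < INF && v + ml_b < wm) wm = v + ml_b;
      if (WM[IDX(i + 1, j)] < wm) wm = WM[IDX(i + 1, j)];
      if (WM[IDX(i, j - 1)] < wm) wm = WM[IDX(i, j - 1)];
      for (int k = i + 1; k < j; ++k) {
        double a = WM[IDX(i, k)], b = WM[IDX(k + 1, j)];
        if (a < INF && b < INF && a + b < wm) wm = a + b;
      }
      WM[IDX(i, j)] = wm;
    }
  }

  // exterior loop
  std::vector<double> W(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    W[j] = W[j - 1];
    for (int i = 1; i <= j; ++i) {
      double v = V[IDX(i - 1, j - 1)];
      if (v < INF && W[i - 1] + v < W[j]) W[j] = W[i - 1] + v;
    }
  }
  #undef IDX
  return W[n];
}
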