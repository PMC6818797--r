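#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap Needleman-Wunsch (Gotoh three-state formulation).
//
// An internal gap of length l costs go + ge * l: the opening charge is paid
// once and the extension on every gap column, including the first. With
// free_ends (semi-global threading convention) residues before the first
// and after the last matched pair are unpenalised in BOTH sequences,
// implemented with restart semantics: D(i,j) = S(i,j) + max(0, V(i-1,j-1))
// and the final score is max(0, max_ij D(i,j)). Without free_ends the
// alignment is fully global and terminal gaps are charged like internal
// ones.
//
// Determinism: the end cell is the first maximum in row-major order; state
// ties resolve diagonal > up (unaligned query residue) > left; gap close
// is preferred over gap extension on ties; with free_ends, continuing a
// non-negative prefix is preferred over restarting.

static const double NEG_INF = -1e300;

// [[Rcpp::export]]
List nw_affine_cpp(NumericMatrix S, double go, double ge, bool free_ends) {
  const int n = S.nrow(), m = S.ncol();
  if (n == 0 || m == 0) stop("empty score matrix");

  const int W = m + 1;
  std::vector<double> D((n + 1) * W, NEG_INF), E((n + 1) * W, NEG_INF),
      F((n + 1) * W, NEG_INF), V((n + 1) * W, NEG_INF);
  // Predecessor codes: 0 = none/start, 1 = D, 2 = F, 3 = E; for E/F a
  // value of 4 means "extend the same gap state".
  std::vector<signed char> pD((n + 1) * W, 0), pE((n + 1) * W, 0),
      pF((n + 1) * W, 0);
#define AT(M, i, j) M[(i) * W + (j)]

  AT(V, 0, 0) = 0.0;
  if (!free_ends) {
    for (int j = 1; j <= m; ++j) {
      AT(E, 0, j) = go + ge * j;
      AT(V, 0, j) = AT(E, 0, j);
      AT(pE, 0, j) = (j == 1) ? 1 : 4;  // open from origin, then extend
    }
    for (int i = 1; i <= n; ++i) {
      AT(F, i, 0) = go + ge * i;
      AT(V, i, 0) = AT(F, i, 0);
      AT(pF, i, 0) = (i == 1) ? 1 : 4;
    }
  }

  // best predecessor state at (i,j) with tie order D > F > E
  auto best_state = [&](int i, int j) -> int {
    double v = AT(V, i, j);
    if (v == AT(D, i, j)) return 1;
    if (v == AT(F, i, j)) return 2;
    return 3;
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // D: match i with j
      double prev = AT(V, i - 1, j - 1);
      if (free_ends) {
        if (prev >= 0.0) {            // continue a non-negative prefix
          AT(pD, i, j) = (i > 1 && j > 1) ? (signed char)best_state(i - 1, j - 1)
                                          : (signed char)0;
          if (i == 1 || j == 1) prev = (prev > 0.0) ? prev : 0.0;
        } else {
          prev = 0.0;                 // restart: leading gaps are free
          AT(pD, i, j) = 0;
        }
        // note: V(i-1,j-1) >= 0 with i,j > 1 implies a real path exists
      } else {
        if (i == 1 && j == 1) {
          prev = 0.0;
          AT(pD, i, j) = 0;
        } else {
          AT(pD, i, j) = (signed char)best_state(i - 1, j - 1);
        }
      }
      AT(D, i, j) = S(i - 1, j - 1) + prev;

      // E: gap consuming template residue j (left move)
      double e_open = AT(V, i, j - 1) > NEG_INF / 2 ? AT(V, i, j - 1) + go + ge
                                                    : NEG_INF;
      double e_ext = AT(E, i, j - 1) > NEG_INF / 2 ? AT(E, i, j - 1) + ge
                                                   : NEG_INF;
      if (e_open >= e_ext) {          // prefer closing/opening over extending
        AT(E, i, j) = e_open;
        AT(pE, i, j) = (signed char)best_state(i, j - 1);
      } else {
        AT(E, i, j) = e_ext;
        AT(pE, i, j) = 4;
      }

      // F: gap consuming query residue i (up move)
      double f_open = AT(V, i - 1, j) > NEG_INF / 2 ? AT(V, i - 1, j) + go + ge
                                                    : NEG_INF;
      double f_ext = AT(F, i - 1, j) > NEG_INF / 2 ? AT(F, i - 1, j) + ge
                                                   : NEG_INF;
      if (f_open >= f_ext) {
        AT(F, i, j) = f_open;
        AT(pF, i, j) = (signed char)best_state(i - 1, j);
      } else {
        AT(F, i, j) = f_ext;
        AT(pF, i, j) = 4;
      }

      double v = AT(D, i, j);
      if (AT(F, i, j) > v) v = AT(F, i, j);
      if (AT(E, i, j) > v) v = AT(E, i, j);
      AT(V, i, j) = v;
    }
  }

  double best;
  int bi = 0, bj = 0, bstate = 1;
  if (free_ends) {
    best = 0.0;  // the empty alignment
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (AT(D, i, j) > best) { best = AT(D, i, j); bi = i; bj = j; }
  } else {
    best = AT(V, n, m);
    bi = n; bj = m;
    bstate = best_state(n, m);
  }

  std::vector<int> qi, tj;
  if (bi > 0 || bj > 0) {
    int i = bi, j = bj, state = bstate;
    while (i > 0 || j > 0) {
      if (state == 1) {
        qi.push_back(i);
        tj.push_back(j);
        int p = AT(pD, i, j);
        --i; --j;
        if (p == 0) break;  // alignment starts here (leading gaps free)
        state = p;
      } else if (state == 2) {
        int p = AT(pF, i, j);
        --i;
        if (free_ends && i == 0) break;
        state = (p == 4) ? 2 : p;
        if (p == 1 && i == 0 && j == 0) break;
      } else {
        int p = AT(pE, i, j);
        --j;
        if (free_ends && j == 0) break;
        state = (p == 4) ? 3 : p;
        if (p == 1 && i == 0 && j == 0) break;
      }
      if (!free_ends && i == 0 && j == 0) break;
    }
  }

  const int np = (int)qi.size();
  IntegerMatrix pairs(np, 2);
  for (int k = 0; k < np; ++k) {
    pairs(k, 0) = qi[np - 1 - k];
    pairs(k, 1) = tj[np - 1 - k];
  }
#undef AT
  return List::create(_["score"] = best, _["pairs"] = pairs);
}
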