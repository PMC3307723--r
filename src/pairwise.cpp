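#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

// Gotoh three-state affine-gap alignment. States:
//   0 = column (a_i, b_j)  (diagonal)
//   1 = column (a_i, '-')  (gap in b, consumes a)
//   2 = column ('-', b_j)  (gap in a, consumes b)
// A maximal gap run of length l costs open + ext * l, charged once per run;
// open may be +Inf (indels forbidden). Ties are broken in state order
// 0 > 1 > 2 everywhere, which fixes the traceback deterministically.

static const double INF = std::numeric_limits<double>::infinity();

struct Costs {
  double match, ts, tv, open, ext;
};

static Costs asCosts(NumericVector v) {
  Costs c;
  c.match = v[0];
  c.ts = v[1];
  c.tv = v[2];
  c.open = v[3];
  c.ext = v[4];
  return c;
}

static inline bool isTransition(char x, char y) {
  return (x == 'A' && y == 'G') || (x == 'G' && y == 'A') ||
         (x == 'C' && y == 'T') || (x == 'T' && y == 'C');
}

// N matches anything at cost 0 (permissive ambiguity extension).
static inline double subCost(char x, char y, const Costs &C) {
  if (x == 'N' || y == 'N') return 0.0;
  if (x == y) return C.match;
  return isTransition(x, y) ? C.ts : C.tv;
}

static inline int pick3(double c0, double c1, double c2) {
  double m = std::min(c0, std::min(c1, c2));
  if (c0 == m) return 0;
  if (c1 == m) return 1;
  return 2;
}

static double gotohCost(const std::string &a, const std::string &b,
                        const Costs &C) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 && m == 0) return 0.0;
  std::vector<double> A(m + 1), Ga(m + 1), Gb(m + 1);
  A[0] = 0.0;
  Ga[0] = INF;
  Gb[0] = INF;
  for (int j = 1; j <= m; ++j) {
    A[j] = INF;
    Ga[j] = INF;
    Gb[j] = C.open + C.ext * j;
  }
  for (int i = 1; i <= n; ++i) {
    double Ad = A[0], Gad = Ga[0], Gbd = Gb[0]; // (i-1, j-1)
    A[0] = INF;
    Ga[0] = C.open + C.ext * i;
    Gb[0] = INF;
    for (int j = 1; j <= m; ++j) {
      double pa = A[j], pga = Ga[j], pgb = Gb[j]; // (i-1, j)
      double na = subCost(a[i - 1], b[j - 1], C) +
                  std::min(Ad, std::min(Gad, Gbd));
      double nga = std::min(std::min(pa, pgb) + C.open + C.ext, pga + C.ext);
      double ngb = std::min(std::min(A[j - 1], Ga[j - 1]) + C.open + C.ext,
                            Gb[j - 1] + C.ext);
      Ad = pa;
      Gad = pga;
      Gbd = pgb;
      A[j] = na;
      Ga[j] = nga;
      Gb[j] = ngb;
    }
  }
  return std::min(A[m], std::min(Ga[m], Gb[m]));
}

// [[Rcpp::export]]
double C_edit_distance(std::string a, std::string b, NumericVector costs) {
  return gotohCost(a, b, asCosts(costs));
}

// [[Rcpp::export]]
NumericMatrix C_edit_distance_matrix(CharacterVector x, CharacterVector y,
                                     NumericVector costs, bool symmetric) {
  Costs C = asCosts(costs);
  int nx = x.size(), ny = y.size();
  std::vector<std::string> xs(nx), ys(ny);
  for (int i = 0; i < nx; ++i) xs[i] = as<std::string>(x[i]);
  for (int j = 0; j < ny; ++j) ys[j] = as<std::string>(y[j]);
  NumericMatrix D(nx, ny);
  if (symmetric && nx == ny) {
    for (int i = 0; i < nx; ++i) {
      D(i, i) = gotohCost(xs[i], ys[i], C);
      for (int j = i + 1; j < ny; ++j) {
        double d = gotohCost(xs[i], ys[j], C);
        D(i, j) = d;
        D(j, i) = d;
      }
    }
  } else {
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) D(i, j) = gotohCost(xs[i], ys[j], C);
  }
  return D;
}

// [[Rcpp::export]]
List C_align_pair(std::string a, std::string b, NumericVector costs) {
  Costs C = asCosts(costs);
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 && m == 0)
    return List::create(_["cost"] = 0.0, _["row_a"] = "", _["row_b"] = "");

  size_t W = (size_t)(m + 1);
  std::vector<double> V(3 * (n + 1) * W, INF);
  std::vector<signed char> P(3 * (n + 1) * W, -1);
  // index helper: state s at (i, j) -> s * (n+1) * W + i * W + j
  size_t plane = (size_t)(n + 1) * W;
#define IDX(s, i, j) ((size_t)(s) * plane + (size_t)(i) * W + (size_t)(j))

  V[IDX(0, 0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    V[IDX(1, i, 0)] = C.open + C.ext * i;
    P[IDX(1, i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    V[IDX(2, 0, j)] = C.open + C.ext * j;
    P[IDX(2, 0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // diagonal
      {
        double c0 = V[IDX(0, i - 1, j - 1)];
        double c1 = V[IDX(1, i - 1, j - 1)];
        double c2 = V[IDX(2, i - 1, j - 1)];
        int s = pick3(c0, c1, c2);
        double base = (s == 0) ? c0 : (s == 1 ? c1 : c2);
        V[IDX(0, i, j)] = subCost(a[i - 1], b[j - 1], C) + base;
        P[IDX(0, i, j)] = (signed char)s;
      }
      // gap in b (consume a_i), from (i-1, j)
      {
        double c0 = V[IDX(0, i - 1, j)] + C.open + C.ext;
        double c1 = V[IDX(1, i - 1, j)] + C.ext;
        double c2 = V[IDX(2, i - 1, j)] + C.open + C.ext;
        int s = pick3(c0, c1, c2);
        V[IDX(1, i, j)] = (s == 0) ? c0 : (s == 1 ? c1 : c2);
        P[IDX(1, i, j)] = (signed char)s;
      }
      // gap in a (consume b_j), from (i, j-1)
      {
        double c0 = V[IDX(0, i, j - 1)] + C.open + C.ext;
        double c1 = V[IDX(1, i, j - 1)] + C.open + C.ext;
        double c2 = V[IDX(2, i, j - 1)] + C.ext;
        int s = pick3(c0, c1, c2);
        V[IDX(2, i, j)] = (s == 0) ? c0 : (s == 1 ? c1 : c2);
        P[IDX(2, i, j)] = (signed char)s;
      }
    }
  }
  int s = pick3(V[IDX(0, n, m)], V[IDX(1, n, m)], V[IDX(2, n, m)]);
  double best = V[IDX(s, n, m)];
  if (!R_finite(best))
    return List::create(_["cost"] = best, _["row_a"] = CharacterVector::create(NA_STRING),
                        _["row_b"] = CharacterVector::create(NA_STRING));
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int ps = P[IDX(s, i, j)];
    if (s == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i;
      --j;
    } else if (s == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    }
    s = ps;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
#undef IDX
  return List::create(_["cost"] = best, _["row_a"] = ra, _["row_b"] = rb);
}
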