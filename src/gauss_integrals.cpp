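#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Closed-form mutual Gauss integral of two line segments.
//
// Segments a0->a1 and b0->b1. The connecting vectors between the four
// endpoints span a spherical quadrilateral on the unit sphere of directions;
// its signed area, divided by 2*pi, is the total mutual contribution of the
// pair to the writhe (both integration orders). |value| equals the
// probability that the two segments cross in a projection along a uniformly
// random direction; the sign is the crossing handedness.
// ---------------------------------------------------------------------------

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
// Signed solid angle of the spherical triangle (a, b, c) via the
// van Oosterom-Strackee formula; numerically stable near degeneracy.
static inline double tri_solid_angle(const double* a, const double* b,
                                     const double* c) {
  double bc[3];
  vcross(b, c, bc);
  double num = vdot(a, bc);
  double den = 1.0 + vdot(a, b) + vdot(b, c) + vdot(c, a);
  return 2.0 * std::atan2(num, den);
}

static double seg_writhe_core(const double* p1, const double* p2,
                              const double* p3, const double* p4) {
  const double eps = 1e-12;
  double r13[3], r14[3], r23[3], r24[3];
  vsub(p3, p1, r13); vsub(p4, p1, r14);
  vsub(p3, p2, r23); vsub(p4, p2, r24);

  double l13 = std::sqrt(vdot(r13, r13)), l14 = std::sqrt(vdot(r14, r14));
  double l24 = std::sqrt(vdot(r24, r24)), l23 = std::sqrt(vdot(r23, r23));
  // Shared endpoints (or coincident points): zero solid angle by convention.
  if (l13 < eps || l14 < eps || l24 < eps || l23 < eps) return 0.0;
  double uA[3], uB[3], uC[3], uD[3];
  for (int k = 0; k < 3; ++k) {
    uA[k] = r13[k] / l13; uB[k] = r14[k] / l14;
    uC[k] = r24[k] / l24; uD[k] = r23[k] / l23;
  }
  // Signed area of the spherical quadrilateral (uA, uB, uC, uD), split into
  // two triangles; the sign already encodes the crossing handedness. The
  // total mutual contribution (both integration orders) is area / (2*pi).
  double area = tri_solid_angle(uA, uB, uC) + tri_solid_angle(uA, uC, uD);
  return -area / (2.0 * M_PI);
}

// [[Rcpp::export(name = ".cpp_segment_writhe")]]
double cpp_segment_writhe(NumericVector a0, NumericVector a1,
                          NumericVector b0, NumericVector b1) {
  double p1[3], p2[3], p3[3], p4[3];
  for (int k = 0; k < 3; ++k) {
    p1[k] = a0[k]; p2[k] = a1[k]; p3[k] = b0[k]; p4[k] = b1[k];
  }
  return seg_writhe_core(p1, p2, p3, p4);
}

// coords: n x 3 matrix of consecutive C-alpha positions (one chain).
// Returns the (n-1) x (n-1) symmetric matrix of pairwise segment
// contributions; entries with |i-j| <= 1 are exactly zero.
// [[Rcpp::export(name = ".cpp_writhe_matrix")]]
NumericMatrix cpp_writhe_matrix(NumericMatrix coords) {
  int n = coords.nrow();
  int ns = n - 1;
  NumericMatrix W(ns, ns);
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) {
    P[3 * i] = coords(i, 0); P[3 * i + 1] = coords(i, 1); P[3 * i + 2] = coords(i, 2);
  }
  for (int i = 0; i < ns; ++i) {
    for (int j = i + 2; j < ns; ++j) {
      double w = seg_writhe_core(&P[3 * i], &P[3 * (i + 1)],
                                 &P[3 * j], &P[3 * (j + 1)]);
      W(i, j) = w;
      W(j, i) = w;
    }
  }
  return W;
}

// ---------------------------------------------------------------------------
// Chord-pattern invariant engine.
//
// invariant value = sum over strictly increasing index tuples i1 < ... < i2k
// of the product over chords (a,b) of M_chord[i_a][i_b], where M_chord is the
// writhe matrix or its elementwise absolute value. Evaluated with cumulative
// tables: order 1 and 2 in O(n^2); order 3 via per-pattern prefix-sum
// reductions leaving at most a triple loop (O(n^3) time, O(n^2) memory).
// ---------------------------------------------------------------------------

typedef std::vector<double> dvec;

// Row prefix: CP(t, j) = sum_{i <= t} M(i, j); CP(-1, .) = 0.
static dvec row_prefix(const NumericMatrix& M) {
  int n = M.nrow();
  dvec CP((size_t)n * n, 0.0);
  for (int j = 0; j < n; ++j) {
    double acc = 0.0;
    for (int t = 0; t < n; ++t) { acc += M(t, j); CP[(size_t)t * n + j] = acc; }
  }
  return CP;
}
// Column suffix: RS(i, u) = sum_{j >= u} M(i, j); RS(., n) = 0.
static dvec col_suffix(const NumericMatrix& M) {
  int n = M.nrow();
  dvec RS((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int u = n - 1; u >= 0; --u) { acc += M(i, u); RS[(size_t)i * n + u] = acc; }
  }
  return RS;
}
// Column prefix of a row-indexed table T(r, j): out(r, t) = sum_{j <= t} T(r, j).
static dvec col_prefix_of(const dvec& T, int n) {
  dvec out((size_t)n * n, 0.0);
  for (int r = 0; r < n; ++r) {
    double acc = 0.0;
    for (int t = 0; t < n; ++t) { acc += T[(size_t)r * n + t]; out[(size_t)r * n + t] = acc; }
  }
  return out;
}
// Column suffix of a table T(r, j): out(r, u) = sum_{j >= u} T(r, j).
static dvec col_suffix_of(const dvec& T, int n) {
  dvec out((size_t)n * n, 0.0);
  for (int r = 0; r < n; ++r) {
    double acc = 0.0;
    for (int u = n - 1; u >= 0; --u) { acc += T[(size_t)r * n + u]; out[(size_t)r * n + u] = acc; }
  }
  return out;
}
// Row prefix of a table T(i, u): out(t, u) = sum_{i <= t} T(i, u).
static dvec row_prefix_of(const dvec& T, int n) {
  dvec out((size_t)n * n, 0.0);
  for (int u = 0; u < n; ++u) {
    double acc = 0.0;
    for (int t = 0; t < n; ++t) { acc += T[(size_t)t * n + u]; out[(size_t)t * n + u] = acc; }
  }
  return out;
}
// Pair prefix: SP(t) = sum_{i < j <= t} M(i, j); SP(-1) = SP(0) = 0.
static dvec pair_prefix(const NumericMatrix& M) {
  int n = M.nrow();
  dvec SP(n, 0.0);
  double acc = 0.0;
  for (int t = 0; t < n; ++t) {
    for (int i = 0; i < t; ++i) acc += M(i, t);
    SP[t] = acc;
  }
  return SP;
}
// Pair suffix: SS(u) = sum_{u <= i < j} M(i, j); SS(n) = 0.
static dvec pair_suffix(const NumericMatrix& M) {
  int n = M.nrow();
  dvec SS(n + 1, 0.0);
  for (int u = n - 1; u >= 0; --u) {
    double add = 0.0;
    for (int j = u + 1; j < n; ++j) add += M(u, j);
    SS[u] = SS[u + 1] + add;
  }
  return SS;
}
// Interior pair sum: V(p, q) = sum_{p < a < b < q} M(a, b).
static dvec interior_pair(const NumericMatrix& M) {
  int n = M.nrow();
  dvec CP = row_prefix(M);
  dvec V((size_t)n * n, 0.0);
  for (int p = 0; p < n; ++p) {
    for (int q = p + 3; q < n; ++q) {
      // V(p,q) = V(p,q-1) + sum_{p < a < q-1} M(a, q-1)
      double add = CP[(size_t)(q - 2) * n + (q - 1)] - CP[(size_t)p * n + (q - 1)];
      V[(size_t)p * n + q] = V[(size_t)p * n + (q - 1)] + add;
    }
  }
  return V;
}

static inline double at(const dvec& T, int n, int r, int c) {
  if (r < 0 || c < 0 || r >= n || c >= n) return 0.0;
  return T[(size_t)r * n + c];
}
static inline double at1(const dvec& T, int r) {
  if (r < 0 || r >= (int)T.size()) return 0.0;
  return T[r];
}

// [[Rcpp::export(name = ".cpp_order1")]]
double cpp_order1(NumericMatrix M) {
  int n = M.nrow();
  double acc = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) acc += M(i, j);
  return acc;
}

// pattern: 1 = (1,2)(3,4), 2 = (1,3)(2,4), 3 = (1,4)(2,3).
// X is the chord containing slot 1, Y the other chord.
// [[Rcpp::export(name = ".cpp_order2")]]
double cpp_order2(int pattern, NumericMatrix X, NumericMatrix Y) {
  int n = X.nrow();
  double acc = 0.0;
  if (pattern == 1) {
    dvec SSY = pair_suffix(Y);
    dvec CPX = row_prefix(X);
    for (int i2 = 1; i2 < n; ++i2) {
      double a1 = at(CPX, n, i2 - 1, i2);      // sum_{i1 < i2} X(i1, i2)
      acc += a1 * at1(SSY, i2 + 1);
    }
  } else if (pattern == 2) {
    dvec CPX = row_prefix(X);
    dvec RSY = col_suffix(Y);
    for (int i2 = 1; i2 < n; ++i2)
      for (int i3 = i2 + 1; i3 < n; ++i3)
        acc += at(CPX, n, i2 - 1, i3) * at(RSY, n, i2, i3 + 1);
  } else if (pattern == 3) {
    dvec VY = interior_pair(Y);
    for (int i1 = 0; i1 < n; ++i1)
      for (int i4 = i1 + 3; i4 < n; ++i4)
        acc += X(i1, i4) * at(VY, n, i1, i4);
  } else {
    stop("unknown order-2 pattern id");
  }
  return acc;
}

// pattern 1..15 enumerates the perfect matchings of slots {1..6} in
// lexicographic order (smaller slot first within a chord, chords sorted by
// first slot). X = chord containing slot 1, Y = chord containing the smallest
// remaining slot, Z = the last chord.
// [[Rcpp::export(name = ".cpp_order3")]]
double cpp_order3(int pattern, NumericMatrix X, NumericMatrix Y, NumericMatrix Z) {
  int n = X.nrow();
  double acc = 0.0;
  switch (pattern) {
  case 1: { // (1,2)(3,4)(5,6)
    dvec SPX = pair_prefix(X);
    dvec SSZ = pair_suffix(Z);
    for (int i3 = 0; i3 < n; ++i3)
      for (int i4 = i3 + 1; i4 < n; ++i4)
        acc += Y(i3, i4) * at1(SPX, i3 - 1) * at1(SSZ, i4 + 1);
    break;
  }
  case 2: { // (1,2)(3,5)(4,6)
    dvec SPX = pair_prefix(X);
    dvec RSZ = col_suffix(Z);
    for (int i3 = 0; i3 < n; ++i3) {
      double spx = at1(SPX, i3 - 1);
      if (spx == 0.0) continue;
      for (int i4 = i3 + 1; i4 < n; ++i4)
        for (int i5 = i4 + 1; i5 < n; ++i5)
          acc += spx * Y(i3, i5) * at(RSZ, n, i4, i5 + 1);
    }
    break;
  }
  case 3: { // (1,2)(3,6)(4,5)
    dvec SPX = pair_prefix(X);
    dvec RSY = col_suffix(Y);
    for (int i3 = 0; i3 < n; ++i3) {
      double spx = at1(SPX, i3 - 1);
      if (spx == 0.0) continue;
      for (int i4 = i3 + 1; i4 < n; ++i4)
        for (int i5 = i4 + 1; i5 < n; ++i5)
          acc += spx * at(RSY, n, i3, i5 + 1) * Z(i4, i5);
    }
    break;
  }
  case 4: { // (1,3)(2,4)(5,6)
    dvec CPX = row_prefix(X);
    dvec SSZ = pair_suffix(Z);
    for (int i2 = 0; i2 < n; ++i2)
      for (int i3 = i2 + 1; i3 < n; ++i3)
        for (int i4 = i3 + 1; i4 < n; ++i4)
          acc += at(CPX, n, i2 - 1, i3) * Y(i2, i4) * at1(SSZ, i4 + 1);
    break;
  }
  case 5: { // (1,3)(2,5)(4,6)
    dvec CPX = row_prefix(X);
    dvec PCPX = col_prefix_of(CPX, n); // PCPX(r, t) = sum_{j <= t} CPX(r, j)
    dvec RSZ = col_suffix(Z);
    for (int i2 = 0; i2 < n; ++i2)
      for (int i4 = i2 + 2; i4 < n; ++i4) {
        double g = at(PCPX, n, i2 - 1, i4 - 1) - at(PCPX, n, i2 - 1, i2);
        if (g == 0.0) continue;
        for (int i5 = i4 + 1; i5 < n; ++i5)
          acc += g * Y(i2, i5) * at(RSZ, n, i4, i5 + 1);
      }
    break;
  }
  case 6: { // (1,3)(2,6)(4,5)
    dvec CPX = row_prefix(X);
    dvec PCPX = col_prefix_of(CPX, n);
    dvec RSY = col_suffix(Y);
    for (int i2 = 0; i2 < n; ++i2)
      for (int i4 = i2 + 2; i4 < n; ++i4) {
        double g = at(PCPX, n, i2 - 1, i4 - 1) - at(PCPX, n, i2 - 1, i2);
        if (g == 0.0) continue;
        for (int i5 = i4 + 1; i5 < n; ++i5)
          acc += g * at(RSY, n, i2, i5 + 1) * Z(i4, i5);
      }
    break;
  }
  case 7: { // (1,4)(2,3)(5,6)
    dvec VY = interior_pair(Y);
    dvec SSZ = pair_suffix(Z);
    for (int i1 = 0; i1 < n; ++i1)
      for (int i4 = i1 + 3; i4 < n; ++i4)
        acc += X(i1, i4) * at(VY, n, i1, i4) * at1(SSZ, i4 + 1);
    break;
  }
  case 8: { // (1,4)(2,5)(3,6)
    dvec CPX = row_prefix(X);
    dvec RSZ = col_suffix(Z);
    dvec PRSZ = row_prefix_of(RSZ, n); // PRSZ(t, u) = sum_{i <= t} RSZ(i, u)
    for (int i2 = 0; i2 < n; ++i2)
      for (int i4 = i2 + 2; i4 < n; ++i4) {
        double cx = at(CPX, n, i2 - 1, i4);
        if (cx == 0.0) continue;
        for (int i5 = i4 + 1; i5 < n; ++i5) {
          double zi = at(PRSZ, n, i4 - 1, i5 + 1) - at(PRSZ, n, i2, i5 + 1);
          acc += cx * Y(i2, i5) * zi;
        }
      }
    break;
  }
  case 9: { // (1,4)(2,6)(3,5)
    dvec CPX = row_prefix(X);
    dvec RSY = col_suffix(Y);
    dvec CPZ = row_prefix(Z);
    for (int i2 = 0; i2 < n; ++i2)
      for (int i4 = i2 + 2; i4 < n; ++i4) {
        double cx = at(CPX, n, i2 - 1, i4);
        if (cx == 0.0) continue;
        for (int i5 = i4 + 1; i5 < n; ++i5) {
          double zi = at(CPZ, n, i4 - 1, i5) - at(CPZ, n, i2, i5);
          acc += cx * at(RSY, n, i2, i5 + 1) * zi;
        }
      }
    break;
  }
  case 10: { // (1,5)(2,3)(4,6)
    dvec VY = interior_pair(Y);
    dvec RSZ = col_suffix(Z);
    for (int i1 = 0; i1 < n; ++i1)
      for (int i4 = i1 + 3; i4 < n; ++i4) {
        double vy = at(VY, n, i1, i4);
        if (vy == 0.0) continue;
        for (int i5 = i4 + 1; i5 < n; ++i5)
          acc += X(i1, i5) * vy * at(RSZ, n, i4, i5 + 1);
      }
    break;
  }
  case 11: { // (1,5)(2,4)(3,6)
    dvec CPX = row_prefix(X);
    dvec RSZ = col_suffix(Z);
    dvec PRSZ = row_prefix_of(RSZ, n);
    for (int i2 = 0; i2 < n; ++i2)
      for (int i4 = i2 + 2; i4 < n; ++i4) {
        double yv = Y(i2, i4);
        if (yv == 0.0) continue;
        for (int i5 = i4 + 1; i5 < n; ++i5) {
          double zi = at(PRSZ, n, i4 - 1, i5 + 1) - at(PRSZ, n, i2, i5 + 1);
          acc += at(CPX, n, i2 - 1, i5) * yv * zi;
        }
      }
    break;
  }
  case 12: { // (1,5)(2,6)(3,4)
    dvec CPX = row_prefix(X);
    dvec RSY = col_suffix(Y);
    dvec CPZ = row_prefix(Z);
    for (int i2 = 0; i2 < n; ++i2)
      for (int i4 = i2 + 2; i4 < n; ++i4) {
        double zi = at(CPZ, n, i4 - 1, i4) - at(CPZ, n, i2, i4);
        if (zi == 0.0) continue;
        for (int i5 = i4 + 1; i5 < n; ++i5)
          acc += at(CPX, n, i2 - 1, i5) * at(RSY, n, i2, i5 + 1) * zi;
      }
    break;
  }
  case 13: { // (1,6)(2,3)(4,5)
    dvec VY = interior_pair(Y);
    dvec RSX = col_suffix(X);
    for (int i1 = 0; i1 < n; ++i1)
      for (int i4 = i1 + 3; i4 < n; ++i4) {
        double vy = at(VY, n, i1, i4);
        if (vy == 0.0) continue;
        for (int i5 = i4 + 1; i5 < n; ++i5)
          acc += at(RSX, n, i1, i5 + 1) * vy * Z(i4, i5);
      }
    break;
  }
  case 14: { // (1,6)(2,4)(3,5)
    dvec CPX = row_prefix(X);
    dvec SCPX = col_suffix_of(CPX, n); // SCPX(t, u) = sum_{j >= u} CPX(t, j)
    dvec CPZ = row_prefix(Z);
    for (int i2 = 0; i2 < n; ++i2)
      for (int i4 = i2 + 2; i4 < n; ++i4) {
        double yv = Y(i2, i4);
        if (yv == 0.0) continue;
        for (int i5 = i4 + 1; i5 < n; ++i5) {
          double zi = at(CPZ, n, i4 - 1, i5) - at(CPZ, n, i2, i5);
          acc += at(SCPX, n, i2 - 1, i5 + 1) * yv * zi;
        }
      }
    break;
  }
  case 15: { // (1,6)(2,5)(3,4)
    dvec CPX = row_prefix(X);
    dvec SCPX = col_suffix_of(CPX, n);
    dvec CPZ = row_prefix(Z);
    for (int i2 = 0; i2 < n; ++i2)
      for (int i4 = i2 + 2; i4 < n; ++i4) {
        double zi = at(CPZ, n, i4 - 1, i4) - at(CPZ, n, i2, i4);
        if (zi == 0.0) continue;
        for (int i5 = i4 + 1; i5 < n; ++i5)
          acc += at(SCPX, n, i2 - 1, i5 + 1) * Y(i2, i5) * zi;
      }
    break;
  }
  default:
    stop("unknown order-3 pattern id");
  }
  return acc;
}
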