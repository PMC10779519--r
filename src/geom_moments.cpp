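#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Accumulated per-facet simplex recurrence sums for the exact, volume-like
// geometric moments of a triangular mesh.
//
// For one facet with vertices v1, v2, v3 the monomial integral over the
// oriented tetrahedron (origin, v1, v2, v3) is
//
//   det[v1 v2 v3] * S_ijk * i! j! k! / (i+j+k+3)!
//
// where S is obtained from three chained arrays sharing one recurrence
// pattern (each array descends along one vertex and folds in the previous
// array, a weighted Pascal-pyramid convolution of the per-vertex monomial
// expansions over the unit simplex):
//
//   C_ijk = x1*C_(i-1)jk + y1*C_i(j-1)k + z1*C_ij(k-1)            C_000 = 1
//   D_ijk = x2*D_(i-1)jk + y2*D_i(j-1)k + z2*D_ij(k-1) + C_ijk    D_000 = 1
//   S_ijk = x3*S_(i-1)jk + y3*S_i(j-1)k + z3*S_ij(k-1) + D_ijk    S_000 = 1
//
// Only indices with i+j+k <= N are visited, so each facet costs O(N^3).
// The i!j!k!/(n+3)! prefactor is facet-independent and applied once in R.
// Returns the flat (N+1)^3 array of sums, index i + (N+1)*j + (N+1)^2*k.
//
// Accumulation over facets is compensated (Kahan), so the result is
// independent of facet ordering to near machine precision, not just to the
// O(f * eps) drift of naive summation.
//
// [[Rcpp::export]]
NumericVector pk_geom_moment_sums(NumericMatrix vertices,
                                  IntegerMatrix facets,
                                  int N) {
  const int M = N + 1;
  const int sj = M, sk = M * M;
  std::vector<double> C(M * M * M), D(M * M * M), S(M * M * M);
  std::vector<long double> acc(M * M * M, 0.0L), comp(M * M * M, 0.0L);
  NumericVector out(M * M * M);
  const int nf = facets.nrow();

  auto kahan_add = [&](int idx, long double val) {
    const long double y = val - comp[idx];
    const long double t = acc[idx] + y;
    comp[idx] = (t - acc[idx]) - y;
    acc[idx] = t;
  };

  for (int t = 0; t < nf; ++t) {
    const int a = facets(t, 0) - 1, b = facets(t, 1) - 1,
              c = facets(t, 2) - 1;
    const double x1 = vertices(a, 0), y1 = vertices(a, 1), z1 = vertices(a, 2);
    const double x2 = vertices(b, 0), y2 = vertices(b, 1), z2 = vertices(b, 2);
    const double x3 = vertices(c, 0), y3 = vertices(c, 1), z3 = vertices(c, 2);
    const double det = x1 * (y2 * z3 - z2 * y3)
                     - y1 * (x2 * z3 - z2 * x3)
                     + z1 * (x2 * y3 - y2 * x3);
    C[0] = 1.0; D[0] = 1.0; S[0] = 1.0;
    kahan_add(0, det);
    for (int k = 0; k <= N; ++k) {
      for (int j = 0; j + k <= N; ++j) {
        for (int i = 0; i + j + k <= N; ++i) {
          if (i + j + k == 0) continue;
          const int idx = i + sj * j + sk * k;
          double cv = 0.0, dv, sv;
          if (i) cv += x1 * C[idx - 1];
          if (j) cv += y1 * C[idx - sj];
          if (k) cv += z1 * C[idx - sk];
          C[idx] = cv;
          dv = cv;
          if (i) dv += x2 * D[idx - 1];
          if (j) dv += y2 * D[idx - sj];
          if (k) dv += z2 * D[idx - sk];
          D[idx] = dv;
          sv = dv;
          if (i) sv += x3 * S[idx - 1];
          if (j) sv += y3 * S[idx - sj];
          if (k) sv += z3 * S[idx - sk];
          S[idx] = sv;
          kahan_add(idx, (long double)det * sv);
        }
      }
    }
  }
  for (int idx = 0; idx < M * M * M; ++idx)
    out[idx] = (double)(acc[idx] - comp[idx]);
  return out;
}
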