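#include <Rcpp.h>
using namespace Rcpp;

// Pairwise abundance-weighted beta mean nearest taxon distance.
//
// D    : S x S patristic distance matrix (symmetric, zero diagonal)
// F    : n x S relative-abundance matrix (rows sum to 1)
// perm : length-S permutation (0-based) applied to the taxon labels of D,
//        i.e. the distance used for taxa (i, j) is D(perm[i], perm[j]).
//        The identity permutation gives the observed statistic.
//
// betaMNTD(a, b) = 0.5 * [ sum_i F(a,i) * min_{j in b} D(i,j)
//                        + sum_j F(b,j) * min_{i in a} D(i,j) ]
// A taxon present in both communities contributes 0 to its own minimum
// because the diagonal of D is zero.
// [[Rcpp::export]]
NumericMatrix cpp_pair_mntd(NumericMatrix D, NumericMatrix F,
                            IntegerVector perm) {
  const int n = F.nrow();
  const int S = F.ncol();
  if (D.nrow() != S || D.ncol() != S)
    stop("distance matrix does not match taxon count");
  if (perm.size() != S)
    stop("permutation length does not match taxon count");

  std::vector<std::vector<int>> pres(n);
  for (int s = 0; s < n; ++s) {
    pres[s].reserve(S);
    for (int i = 0; i < S; ++i)
      if (F(s, i) > 0.0) pres[s].push_back(i);
    if (pres[s].empty()) stop("empty community in row %d", s + 1);
  }

  // minD(i, s) = distance from taxon i to its nearest taxon present in s
  NumericMatrix minD(S, n);
  for (int s = 0; s < n; ++s) {
    const std::vector<int>& ps = pres[s];
    for (int i = 0; i < S; ++i) {
      const int pi = perm[i];
      double m = R_PosInf;
      for (size_t k = 0; k < ps.size(); ++k) {
        const double d = D(pi, perm[ps[k]]);
        if (d < m) m = d;
      }
      minD(i, s) = m;
    }
  }

  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = 0; b < n; ++b) {
      if (a == b) continue;
      double t = 0.0;
      const std::vector<int>& pa = pres[a];
      for (size_t k = 0; k < pa.size(); ++k)
        t += F(a, pa[k]) * minD(pa[k], b);
      out(a, b) = t;
    }
  }
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      const double v = 0.5 * (out(a, b) + out(b, a));
      out(a, b) = v;
      out(b, a) = v;
    }
  return out;
}
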