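#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Victor-Purpura edit distance between two sorted spike-time vectors.
// Insert/delete cost 1, shift cost q*|dt|. Standard O(|a|*|b|) dynamic
// program with two rolling rows:
//   D[i][0] = i, D[0][j] = j,
//   D[i][j] = min(D[i-1][j] + 1, D[i][j-1] + 1,
//                 D[i-1][j-1] + q*|a_i - b_j|)
static double vp_core(const double* a, int na, const double* b, int nb,
                      double q) {
  if (na == 0) return nb;
  if (nb == 0) return na;
  std::vector<double> prev(nb + 1), cur(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    for (int j = 1; j <= nb; ++j) {
      double shift = prev[j - 1] + q * std::fabs(a[i - 1] - b[j - 1]);
      double indel = std::min(prev[j], cur[j - 1]) + 1.0;
      cur[j] = std::min(shift, indel);
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export(name = ".vp_distance_cpp")]]
double vp_distance_cpp(NumericVector a, NumericVector b, double q) {
  return vp_core(a.begin(), a.size(), b.begin(), b.size(), q);
}

// All S(S-1)/2 unique pairwise distances among a list of sorted spike-time
// vectors; returns the symmetric S x S matrix with zero diagonal.
// [[Rcpp::export(name = ".vp_distance_matrix_cpp")]]
NumericMatrix vp_distance_matrix_cpp(List trains, double q) {
  int s = trains.size();
  std::vector<NumericVector> tv;
  tv.reserve(s);
  for (int i = 0; i < s; ++i) tv.push_back(as<NumericVector>(trains[i]));
  NumericMatrix out(s, s);
  for (int i = 0; i < s; ++i) {
    for (int j = i + 1; j < s; ++j) {
      double d = vp_core(tv[i].begin(), tv[i].size(),
                         tv[j].begin(), tv[j].size(), q);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
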