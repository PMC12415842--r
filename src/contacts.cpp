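#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Summed heavy-atom contact counts per residue pair for one frame.
//
// xyz: n x 3 coordinates (Angstrom) of the atoms to consider (caller has
//      already restricted to heavy atoms of the component of interest).
// res: 1-based residue id per atom (ids need not be contiguous).
// box: length-3 orthorhombic box for minimum-image distances, or length 0.
// cutoff: strict upper bound d < cutoff.
//
// Returns a triplet list (res_i, res_j, count) with res_i < res_j.
// Brute force over atom pairs with squared-distance comparison; the pure-R
// residue-pair double loop in the test suite is the independent oracle.
// [[Rcpp::export(name = ".contact_counts_cpp")]]
DataFrame contact_counts_cpp(NumericMatrix xyz, IntegerVector res,
                             NumericVector box, double cutoff) {
  const int n = xyz.nrow();
  const bool pbc = box.size() == 3;
  const double c2 = cutoff * cutoff;
  double bx = 0, by = 0, bz = 0;
  if (pbc) { bx = box[0]; by = box[1]; bz = box[2]; }
  std::unordered_map<long long, int> acc;
  for (int a = 0; a < n; ++a) {
    const double xa = xyz(a, 0), ya = xyz(a, 1), za = xyz(a, 2);
    const int ra = res[a];
    for (int b = a + 1; b < n; ++b) {
      const int rb = res[b];
      if (rb == ra) continue;
      double dx = xyz(b, 0) - xa;
      double dy = xyz(b, 1) - ya;
      double dz = xyz(b, 2) - za;
      if (pbc) {
        dx -= bx * std::round(dx / bx);
        dy -= by * std::round(dy / by);
        dz -= bz * std::round(dz / bz);
      }
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < c2) {
        int i = ra < rb ? ra : rb;
        int j = ra < rb ? rb : ra;
        acc[static_cast<long long>(i) * 2147483647LL + j] += 1;
      }
    }
  }
  const int m = acc.size();
  IntegerVector ri(m), rj(m), count(m);
  int k = 0;
  for (auto &kv : acc) {
    ri[k] = static_cast<int>(kv.first / 2147483647LL);
    rj[k] = static_cast<int>(kv.first % 2147483647LL);
    count[k] = kv.second;
    ++k;
  }
  return DataFrame::create(_["res_i"] = ri, _["res_j"] = rj,
                           _["count"] = count);
}
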