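// Lightweight secondary-structure ensemble model for site accessibility.
//
// Nussinov-style base-pair model with Boltzmann weights per pair
// (GC -3.0, AU -2.0, GU -1.0 kcal/mol at 37 C), minimum hairpin loop of 3.
// Inside-outside recursions over the unambiguous decomposition
//   Z(i,j) = Z(i+1,j) + sum_k w(i,k) Z(i+1,k-1) Z(k+1,j)
// give exact per-base unpaired probabilities; the opening free energy of a
// window is RT * (ln Z - ln Z_constrained) with the window forced unpaired,
// mirroring the ddG-opening idea of RNAplfold/PITA at a fraction of the cost.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

namespace {

const double RT37 = 0.0019872 * 310.15;  // kcal/mol
const int MIN_LOOP = 3;

double pair_w(char a, char b) {
  double e = 0.0;
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) e = -3.0;
  else if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) e = -2.0;
  else if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) e = -1.0;
  else return 0.0;
  return std::exp(-e / RT37);
}

class Grid {
 public:
  explicit Grid(int n) : n_(n), v_((size_t)n * n, 0.0) {}
  double get(int i, int j) const {          // weight of segment [i, j]
    if (i > j) return 1.0;                  // empty segment
    return v_[(size_t)i * n_ + j];
  }
  void set(int i, int j, double x) { v_[(size_t)i * n_ + j] = x; }
  void add(int i, int j, double x) {
    if (i > j) return;
    v_[(size_t)i * n_ + j] += x;
  }
 private:
  int n_;
  std::vector<double> v_;
};

// Inside partition function; `blocked[i]` bases may not pair.
Grid inside(const std::string& s, const std::vector<bool>& blocked) {
  const int n = (int)s.size();
  Grid Z(n);
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double z = Z.get(i + 1, j);           // i unpaired
      if (!blocked[i]) {
        for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
          if (blocked[k]) continue;
          double w = pair_w(s[i], s[k]);
          if (w == 0.0) continue;
          z += w * Z.get(i + 1, k - 1) * Z.get(k + 1, j);
        }
      }
      Z.set(i, j, z);
    }
  }
  return Z;
}

}  // namespace

// Returns per-base unpaired probabilities and, when 0 <= open_start <
// open_end <= n, the free energy (>= 0) of forcing [open_start, open_end)
// to be unpaired.
// [[Rcpp::export]]
List fold_profile_cpp(std::string seq, int open_start, int open_end) {
  const int n = (int)seq.size();
  if (n == 0) {
    return List::create(Named("p_unpaired") = NumericVector(0),
                        Named("dg_open") = NA_REAL);
  }
  std::vector<bool> none(n, false);
  Grid Z = inside(seq, none);
  const double Ztot = Z.get(0, n - 1);

  // Outside pass over the same decomposition; O(i,j) is the total weight of
  // configurations outside segment [i,j] in which [i,j] is independent.
  Grid O(n);
  O.set(0, n - 1, 1.0);
  std::vector<double> p_paired(n, 0.0);
  for (int len = n; len >= 1; --len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double o = O.get(i, j);
      if (o == 0.0) continue;
      O.add(i + 1, j, o);                   // i unpaired
      for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
        double w = pair_w(seq[i], seq[k]);
        if (w == 0.0) continue;
        double zin = Z.get(i + 1, k - 1);
        double zr = Z.get(k + 1, j);
        double pp = o * w * zin * zr / Ztot;
        p_paired[i] += pp;
        p_paired[k] += pp;
        O.add(i + 1, k - 1, o * w * zr);
        O.add(k + 1, j, o * w * zin);
      }
    }
  }

  NumericVector pu(n);
  for (int i = 0; i < n; ++i) {
    double p = 1.0 - p_paired[i];
    pu[i] = p < 0.0 ? 0.0 : (p > 1.0 ? 1.0 : p);
  }

  double dg_open = NA_REAL;
  if (open_start >= 0 && open_end > open_start && open_end <= n) {
    std::vector<bool> blocked(n, false);
    for (int i = open_start; i < open_end; ++i) blocked[i] = true;
    Grid Zo = inside(seq, blocked);
    dg_open = RT37 * (std::log(Ztot) - std::log(Zo.get(0, n - 1)));
    if (dg_open < 0.0) dg_open = 0.0;       // guard rounding
  }
  return List::create(Named("p_unpaired") = pu,
                      Named("dg_open") = dg_open);
}
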