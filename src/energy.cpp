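#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Width of the Gaussian attractive well in surface distance (Angstrom).
static const double GAUSS_SIGMA = 0.5;

static inline void pair_terms(double r, double r0, double e_cap,
                              double &att, double &rep) {
  double d = r - r0;
  att = std::exp(-(d * d) / (GAUSS_SIGMA * GAUSS_SIGMA));
  rep = 0.0;
  if (d < 0.0) {
    rep = d * d;
    if (e_cap >= 0.0 && rep > e_cap) rep = e_cap; // soft-core plateau
  }
}

// Receptor-ligand vdW sums over heavy-atom pairs within `cutoff`,
// neighbor-searched with a uniform cell list over the receptor atoms.
// e_cap < 0 means uncapped (normal mode).
// [[Rcpp::export]]
NumericVector cpp_pair_energy(NumericMatrix lig, NumericVector lig_rad,
                              NumericMatrix rec, NumericVector rec_rad,
                              double cutoff, double e_cap) {
  int nl = lig.nrow(), nr = rec.nrow();
  double att_sum = 0.0, rep_sum = 0.0;
  if (nl == 0 || nr == 0)
    return NumericVector::create(_["att"] = 0.0, _["rep"] = 0.0);

  // cell list on receptor atoms, cell edge = cutoff
  double ox = rec(0, 0), oy = rec(0, 1), oz = rec(0, 2);
  for (int i = 1; i < nr; ++i) {
    if (rec(i, 0) < ox) ox = rec(i, 0);
    if (rec(i, 1) < oy) oy = rec(i, 1);
    if (rec(i, 2) < oz) oz = rec(i, 2);
  }
  std::unordered_map<long long, std::vector<int> > cells;
  cells.reserve(nr * 2);
  const long long K = 1 << 20;
  for (int i = 0; i < nr; ++i) {
    long long cx = (long long)std::floor((rec(i, 0) - ox) / cutoff);
    long long cy = (long long)std::floor((rec(i, 1) - oy) / cutoff);
    long long cz = (long long)std::floor((rec(i, 2) - oz) / cutoff);
    cells[(cx * K + cy) * K + cz].push_back(i);
  }
  double c2 = cutoff * cutoff;
  for (int j = 0; j < nl; ++j) {
    double x = lig(j, 0), y = lig(j, 1), z = lig(j, 2);
    long long cx = (long long)std::floor((x - ox) / cutoff);
    long long cy = (long long)std::floor((y - oy) / cutoff);
    long long cz = (long long)std::floor((z - oz) / cutoff);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
              cells.find(((cx + dx) * K + (cy + dy)) * K + (cz + dz));
          if (it == cells.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t q = 0; q < v.size(); ++q) {
            int i = v[q];
            double ddx = rec(i, 0) - x, ddy = rec(i, 1) - y,
                   ddz = rec(i, 2) - z;
            double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (r2 > c2) continue;
            double r = std::sqrt(r2);
            if (r <= 0.0) stop("coincident receptor/ligand atoms (r = 0)");
            double att, rep;
            pair_terms(r, lig_rad[j] + rec_rad[i], e_cap, att, rep);
            att_sum += att;
            rep_sum += rep;
          }
        }
  }
  return NumericVector::create(_["att"] = att_sum, _["rep"] = rep_sum);
}

// Ligand self-clash: uncapped quadratic overlap over the supplied atom
// pairs (1-based index matrix; pairs separated by >= 4 bonds).
// [[Rcpp::export]]
double cpp_internal_energy(NumericMatrix lig, NumericVector rad,
                           IntegerMatrix pairs) {
  double s = 0.0;
  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double dx = lig(i, 0) - lig(j, 0), dy = lig(i, 1) - lig(j, 1),
           dz = lig(i, 2) - lig(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - (rad[i] + rad[j]);
    if (d < 0.0) s += d * d;
  }
  return s;
}

// Heavy-atom RMSD between two conformations minimized over the supplied
// atom mappings (perms: n_maps x n_atoms, 1-based; row 1 should be the
// identity). No re-superposition: poses share the receptor frame.
// [[Rcpp::export]]
double cpp_sym_rmsd(NumericMatrix a, NumericMatrix b, IntegerMatrix perms) {
  int n = a.nrow();
  double best = R_PosInf;
  for (int m = 0; m < perms.nrow(); ++m) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      int j = perms(m, i) - 1;
      double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1),
             dz = a(i, 2) - b(j, 2);
      s += dx * dx + dy * dy + dz * dz;
    }
    double r = std::sqrt(s / n);
    if (r < best) best = r;
  }
  return best;
}

// Greedy leader clustering over score-sorted poses. coords is a list of
// n_atoms x 3 matrices in ascending-score order; a pose is kept iff its
// symmetry-corrected RMSD to every kept pose exceeds `cutoff`.
// [[Rcpp::export]]
LogicalVector cpp_leader_cluster(List coords, IntegerMatrix perms,
                                 double cutoff) {
  int n = coords.size();
  LogicalVector keep(n, false);
  std::vector<NumericMatrix> kept;
  for (int i = 0; i < n; ++i) {
    NumericMatrix ci = coords[i];
    bool ok = true;
    for (size_t k = 0; k < kept.size(); ++k) {
      if (cpp_sym_rmsd(ci, kept[k], perms) <= cutoff) {
        ok = false;
        break;
      }
    }
    if (ok) {
      keep[i] = true;
      kept.push_back(ci);
    }
  }
  return keep;
}
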