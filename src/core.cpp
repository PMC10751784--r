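// Hot kernels of the pose search: pairwise energy evaluation and genome
// application. Everything here mirrors the R-level definitions in
// R/scoring.R and R/docking.R; the R oracle tests compare against
// independent double-loop implementations.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double COULOMB_K = 332.06;

// Mehler-Solmajer sigmoidal distance-dependent dielectric.
static inline double ms_dielectric(double r) {
  const double A = -8.5525, B = 78.4 - A, lam = 0.003627, k = 7.7839;
  return A + B / (1.0 + k * std::exp(-lam * B * r));
}

// Pairwise intermolecular energy. Matrices are nl x nr, indices 0-based
// (metal/dummy = -1 when absent). form10 == 1 marks 12-10 pairs, hbflag
// marks the angularly weighted metal-acceptor pairs. Returns
// (vdw, hbond_metal, electrostatic, total).
// [[Rcpp::export(name = ".pose_energy_cpp")]]
NumericVector pose_energy_cpp(const NumericMatrix& lxyz,
                              const NumericMatrix& rxyz,
                              const NumericMatrix& rmin,
                              const NumericMatrix& repc,
                              const NumericMatrix& attc,
                              const IntegerMatrix& form10,
                              const IntegerMatrix& hbflag,
                              const NumericMatrix& qq,
                              int metal, int dummy,
                              double lj_cutoff, double elec_cutoff,
                              double rep_cap = 0.0) {
  const int nl = lxyz.nrow(), nr = rxyz.nrow();
  double ux = 0, uy = 0, uz = 0;
  bool have_dummy = metal >= 0 && dummy >= 0;
  if (have_dummy) {
    ux = lxyz(dummy, 0) - lxyz(metal, 0);
    uy = lxyz(dummy, 1) - lxyz(metal, 1);
    uz = lxyz(dummy, 2) - lxyz(metal, 2);
    double n = std::sqrt(ux * ux + uy * uy + uz * uz);
    if (n > 1e-12) { ux /= n; uy /= n; uz /= n; }
  }
  double evdw = 0, ehb = 0, eel = 0;
  const double lj2 = lj_cutoff * lj_cutoff, el2 = elec_cutoff * elec_cutoff;
  for (int j = 0; j < nr; ++j) {
    const double rx = rxyz(j, 0), ry = rxyz(j, 1), rz = rxyz(j, 2);
    for (int i = 0; i < nl; ++i) {
      double dx = lxyz(i, 0) - rx, dy = lxyz(i, 1) - ry, dz = lxyz(i, 2) - rz;
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 0.0025) r2 = 0.0025;
      double q = qq(i, j);
      if (q != 0.0 && r2 <= el2) {
        double r = std::sqrt(r2);
        if (rep_cap > 0.0 && r < 1.5) r = 1.5;  // soft-core floor
        eel += COULOMB_K * q / (ms_dielectric(r) * r);
      }
      if (r2 > lj2) continue;
      double rm = rmin(i, j);
      if (rm <= 0.0) continue;
      double x2 = rm * rm / r2;
      // soft-core search mode: flatten the whole pair potential inside the
      // radius where the repulsion reaches rep_cap
      if (rep_cap > 0.0 && repc(i, j) > 0.0) {
        double x2max = std::pow(rep_cap / repc(i, j), 1.0 / 6.0);
        if (x2 > x2max) x2 = x2max;
      }
      double x6 = x2 * x2 * x2;
      double rep = repc(i, j) * x6 * x6;
      double att = attc(i, j) * (form10(i, j) ? x6 * x2 * x2 : x6);
      if (hbflag(i, j)) {
        double w = 1.0;
        if (have_dummy) {
          double vx = rx - lxyz(metal, 0), vy = ry - lxyz(metal, 1),
                 vz = rz - lxyz(metal, 2);
          double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
          double ct = vn > 1e-12 ? (vx * ux + vy * uy + vz * uz) / vn : 0.0;
          w = ct > 0 ? ct * ct : 0.0;
        }
        ehb += rep - w * att;
      } else {
        evdw += rep - att;
      }
    }
  }
  return NumericVector::create(evdw, ehb, eel, evdw + ehb + eel);
}

// Apply a genome (translation, unit quaternion, torsions) to conformer
// coordinates. torsion_bonds: k x 2 (1-based pivot atoms, proximal then
// distal); moving sets: list of 1-based index vectors (distal subtree
// without the pivot); root: 1-based root atom.
// [[Rcpp::export(name = ".apply_genome_cpp")]]
NumericMatrix apply_genome_cpp(const NumericMatrix& xyz_in,
                               const IntegerMatrix& torsion_bonds,
                               const List& moving_sets,
                               int root,
                               const NumericVector& genome) {
  NumericMatrix xyz = clone(xyz_in);
  const int n = xyz.nrow(), k = torsion_bonds.nrow();
  for (int t = 0; t < k; ++t) {
    int a = torsion_bonds(t, 0) - 1, b = torsion_bonds(t, 1) - 1;
    double axx = xyz(b, 0) - xyz(a, 0), axy = xyz(b, 1) - xyz(a, 1),
           axz = xyz(b, 2) - xyz(a, 2);
    double an = std::sqrt(axx * axx + axy * axy + axz * axz);
    if (an < 1e-12) continue;
    axx /= an; axy /= an; axz /= an;
    double ang = genome[7 + t], c = std::cos(ang), s = std::sin(ang);
    IntegerVector mov = moving_sets[t];
    for (int m = 0; m < mov.size(); ++m) {
      int i = mov[m] - 1;
      double px = xyz(i, 0) - xyz(b, 0), py = xyz(i, 1) - xyz(b, 1),
             pz = xyz(i, 2) - xyz(b, 2);
      // Rodrigues rotation about (axx, axy, axz)
      double dot = axx * px + axy * py + axz * pz;
      double cx = axy * pz - axz * py, cy = axz * px - axx * pz,
             cz = axx * py - axy * px;
      xyz(i, 0) = xyz(b, 0) + px * c + cx * s + axx * dot * (1 - c);
      xyz(i, 1) = xyz(b, 1) + py * c + cy * s + axy * dot * (1 - c);
      xyz(i, 2) = xyz(b, 2) + pz * c + cz * s + axz * dot * (1 - c);
    }
  }
  // rigid rotation about the root, then translation of the root
  double qw = genome[3], qx = genome[4], qy = genome[5], qz = genome[6];
  double qn = std::sqrt(qw * qw + qx * qx + qy * qy + qz * qz);
  qw /= qn; qx /= qn; qy /= qn; qz /= qn;
  double R[3][3] = {
    {1 - 2 * (qy * qy + qz * qz), 2 * (qx * qy - qw * qz), 2 * (qx * qz + qw * qy)},
    {2 * (qx * qy + qw * qz), 1 - 2 * (qx * qx + qz * qz), 2 * (qy * qz - qw * qx)},
    {2 * (qx * qz - qw * qy), 2 * (qy * qz + qw * qx), 1 - 2 * (qx * qx + qy * qy)}
  };
  const int r0 = root - 1;
  const double ox = xyz(r0, 0), oy = xyz(r0, 1), oz = xyz(r0, 2);
  for (int i = 0; i < n; ++i) {
    double px = xyz(i, 0) - ox, py = xyz(i, 1) - oy, pz = xyz(i, 2) - oz;
    xyz(i, 0) = R[0][0] * px + R[0][1] * py + R[0][2] * pz + genome[0];
    xyz(i, 1) = R[1][0] * px + R[1][1] * py + R[1][2] * pz + genome[1];
    xyz(i, 2) = R[2][0] * px + R[2][1] * py + R[2][2] * pz + genome[2];
  }
  return xyz;
}
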