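// Lattice-sum kernels: exp-6 repulsion-dispersion with analytic tail,
// Ewald summation for the charge-charge term, direct-sum dipole and
// quadrupole electrostatics, atom-centred symmetry functions, and
// geometry/contact checks. Energies are per molecule of the unit cell
// contents (kJ/mol); lengths in Angstrom, charges in e.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KWALL = 1.0e4; // kJ/mol/A^2, inner-cap stiffness
static const double TAPER_W = 1.0; // A, width of the cutoff switching zone

// C2-continuous quintic switch: 1 below rc - TAPER_W, 0 at rc. Keeps the
// lattice energy smooth in the packing variables as pairs cross the
// cutoff (a hard cutoff leaves O(C/rc^6) jumps that break line searches).
static inline double switch5(double r, double rc) {
  double ron = rc - TAPER_W;
  if (rc <= 2.0 || r <= ron) return 1.0;
  if (r >= rc) return 0.0;
  double x = (r - ron) / (rc - ron);
  return 1.0 - x * x * x * (10.0 - 15.0 * x + 6.0 * x * x);
}

struct Vec3 { double x, y, z; };

static inline double dot3(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// columns of M are the lattice vectors
static inline Vec3 mat_vec(const double *M, double f1, double f2, double f3) {
  Vec3 v;
  v.x = M[0] * f1 + M[3] * f2 + M[6] * f3;
  v.y = M[1] * f1 + M[4] * f2 + M[7] * f3;
  v.z = M[2] * f1 + M[5] * f2 + M[8] * f3;
  return v;
}

// column-major 3x3 inverse; element (r,c) of X is X[3c+r]
static void inv3(const double *M, double det, double *X) {
  const double a = M[0], d = M[1], g = M[2];
  const double b = M[3], e = M[4], h = M[5];
  const double c = M[6], f = M[7], i = M[8];
  X[0] = (e * i - f * h) / det;  // (0,0)
  X[3] = (c * h - b * i) / det;  // (0,1)
  X[6] = (b * f - c * e) / det;  // (0,2)
  X[1] = (f * g - d * i) / det;  // (1,0)
  X[4] = (a * i - c * g) / det;  // (1,1)
  X[7] = (c * d - a * f) / det;  // (1,2)
  X[2] = (d * h - e * g) / det;  // (2,0)
  X[5] = (b * g - a * h) / det;  // (2,1)
  X[8] = (a * e - b * d) / det;  // (2,2)
}

static double cell_volume3(const double *M) {
  return M[0] * (M[4] * M[8] - M[5] * M[7])
       - M[3] * (M[1] * M[8] - M[2] * M[7])
       + M[6] * (M[1] * M[5] - M[2] * M[4]);
}

// image ranges so that all |ri - rj + t| <= rc are covered
static void image_range(const double *M, const NumericMatrix &coords,
                        double rc, int *nmax) {
  double V = std::fabs(cell_volume3(M));
  const int N = coords.nrow();
  for (int ax = 0; ax < 3; ++ax) {
    int j = (ax + 1) % 3, k = (ax + 2) % 3;
    // normal of the (a_j, a_k) plane
    double nx = M[3 * j + 1] * M[3 * k + 2] - M[3 * j + 2] * M[3 * k + 1];
    double ny = M[3 * j + 2] * M[3 * k + 0] - M[3 * j + 0] * M[3 * k + 2];
    double nz = M[3 * j + 0] * M[3 * k + 1] - M[3 * j + 1] * M[3 * k + 0];
    double area = std::sqrt(nx * nx + ny * ny + nz * nz);
    double h = V / area; // perpendicular spacing along axis ax
    nx /= area; ny /= area; nz /= area;
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < N; ++i) {
      double p = coords(i, 0) * nx + coords(i, 1) * ny + coords(i, 2) * nz;
      if (p < lo) lo = p;
      if (p > hi) hi = p;
    }
    nmax[ax] = (int)std::ceil((rc + (hi - lo)) / h) + 0;
  }
}

struct EnergyResult {
  double repdisp, tail, e_qq, e_multi, min_r;
  bool clash;
};

static EnergyResult cell_energy_core(const NumericMatrix &coords,
                                     const IntegerVector &molid,
                                     const IntegerVector &type,
                                     const NumericMatrix &Apar,
                                     const NumericMatrix &Bpar,
                                     const NumericMatrix &Cpar,
                                     const NumericMatrix &rwall,
                                     const NumericMatrix &uwall,
                                     const NumericVector &q,
                                     const NumericMatrix &dip,
                                     const NumericMatrix &quad,
                                     const NumericMatrix &cellM,
                                     const List &settings) {
  const int N = coords.nrow();
  double M[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) M[3 * c + r] = cellM(r, c);
  const double V = std::fabs(cell_volume3(M));

  const double rd_cut = as<double>(settings["rd_cutoff"]);
  const double el_cut = as<double>(settings["elec_cutoff"]);
  const int rank = as<int>(settings["elec_rank"]);
  const bool tail_on = as<bool>(settings["tail_correction"]);
  const double kcoul = as<double>(settings["kcoul"]);
  double alpha = as<double>(settings["ewald_alpha"]);
  const double ewald_eps = as<double>(settings["ewald_eps"]);
  const double clash_floor = as<double>(settings["clash_floor"]);
  if (alpha <= 0) alpha = 4.5 / el_cut;

  int Z = 0;
  for (int i = 0; i < N; ++i) if (molid[i] > Z) Z = molid[i];

  EnergyResult res; res.repdisp = 0; res.tail = 0; res.e_qq = 0;
  res.e_multi = 0; res.min_r = R_PosInf; res.clash = false;

  bool any_q = false, any_mp = false;
  for (int i = 0; i < N; ++i) {
    if (std::fabs(q[i]) > 1e-14) any_q = true;
    for (int k = 0; k < 3; ++k) if (std::fabs(dip(i, k)) > 1e-14) any_mp = true;
    for (int k = 0; k < 9; ++k) if (std::fabs(quad(i, k)) > 1e-14) any_mp = true;
  }
  if (rank < 1) any_mp = false;

  // ---------------- exp-6 repulsion-dispersion -------------------------
  {
    int nmax[3];
    image_range(M, coords, rd_cut, nmax);
    const double rc2 = rd_cut * rd_cut;
    double acc = 0;
    for (int n1 = -nmax[0]; n1 <= nmax[0]; ++n1)
      for (int n2 = -nmax[1]; n2 <= nmax[1]; ++n2)
        for (int n3 = -nmax[2]; n3 <= nmax[2]; ++n3) {
          const bool home = (n1 == 0 && n2 == 0 && n3 == 0);
          Vec3 t = mat_vec(M, n1, n2, n3);
          for (int i = 0; i < N; ++i) {
            const int ti = type[i] - 1;
            for (int j = 0; j < N; ++j) {
              if (home && (i == j || molid[i] == molid[j])) continue;
              double dx = coords(j, 0) + t.x - coords(i, 0);
              double dy = coords(j, 1) + t.y - coords(i, 1);
              double dz = coords(j, 2) + t.z - coords(i, 2);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 > rc2) continue;
              double r = std::sqrt(r2);
              if (r < res.min_r) res.min_r = r;
              if (r < clash_floor) res.clash = true;
              const int tj = type[j] - 1;
              double rw = rwall(ti, tj);
              if (r < rw) {
                double d = rw - r;
                acc += uwall(ti, tj) + KWALL * d * d;
              } else {
                double r6 = r2 * r2 * r2;
                acc += (Apar(ti, tj) * std::exp(-Bpar(ti, tj) * r) -
                        Cpar(ti, tj) / r6) * switch5(r, rd_cut);
              }
            }
          }
        }
    res.repdisp = 0.5 * acc / Z;
    if (tail_on) {
      double csum = 0;
      for (int i = 0; i < N; ++i)
        for (int j = 0; j < N; ++j) csum += Cpar(type[i] - 1, type[j] - 1);
      // uniform-density integral of C/r^6 over the switched-out sliver
      // [rc - TAPER_W, rc] plus everything beyond rc
      double I = 1.0 / (3.0 * rd_cut * rd_cut * rd_cut);
      if (rd_cut > 2.0) {
        const int ns = 32;
        double ron = rd_cut - TAPER_W, h = TAPER_W / ns, simp = 0;
        for (int k = 0; k <= ns; ++k) {
          double r = ron + k * h;
          double f = (1.0 - switch5(r, rd_cut)) / (r * r * r * r);
          double wgt = (k == 0 || k == ns) ? 1.0 : (k % 2 ? 4.0 : 2.0);
          simp += wgt * f;
        }
        I += simp * h / 3.0;
      }
      res.tail = -2.0 * M_PI * csum * I / V / Z;
    }
  }

  // ---------------- Ewald charge-charge --------------------------------
  if (any_q) {
    int nmax[3];
    image_range(M, coords, el_cut, nmax);
    const double rc2 = el_cut * el_cut;
    double real = 0;
    for (int n1 = -nmax[0]; n1 <= nmax[0]; ++n1)
      for (int n2 = -nmax[1]; n2 <= nmax[1]; ++n2)
        for (int n3 = -nmax[2]; n3 <= nmax[2]; ++n3) {
          const bool home = (n1 == 0 && n2 == 0 && n3 == 0);
          Vec3 t = mat_vec(M, n1, n2, n3);
          for (int i = 0; i < N; ++i) {
            if (q[i] == 0) continue;
            for (int j = 0; j < N; ++j) {
              if (home && (i == j || molid[i] == molid[j])) continue;
              if (q[j] == 0) continue;
              double dx = coords(j, 0) + t.x - coords(i, 0);
              double dy = coords(j, 1) + t.y - coords(i, 1);
              double dz = coords(j, 2) + t.z - coords(i, 2);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 > rc2) continue;
              double r = std::sqrt(r2);
              // coincident images (special positions) are unphysical but
              // must stay finite so the minimiser can escape them
              if (r < clash_floor) r = clash_floor;
              real += q[i] * q[j] * std::erfc(alpha * r) / r;
            }
          }
        }
    real *= 0.5;

    // reciprocal space: B = 2 pi (M^-1)^T, k = B %*% (h1,h2,h3)
    double Minv[9];
    inv3(M, cell_volume3(M), Minv);
    const double kcut = 2.0 * alpha * std::sqrt(-std::log(ewald_eps));
    const double kcut2 = kcut * kcut;
    int hmax[3];
    for (int ax = 0; ax < 3; ++ax) {
      double alen = std::sqrt(M[3 * ax] * M[3 * ax] +
                              M[3 * ax + 1] * M[3 * ax + 1] +
                              M[3 * ax + 2] * M[3 * ax + 2]);
      hmax[ax] = (int)std::ceil(kcut * alen / (2.0 * M_PI));
    }
    double recip = 0;
    const double pref = 2.0 * M_PI / V;
    const double inv4a2 = 1.0 / (4.0 * alpha * alpha);
    for (int h1 = -hmax[0]; h1 <= hmax[0]; ++h1)
      for (int h2 = -hmax[1]; h2 <= hmax[1]; ++h2)
        for (int h3 = -hmax[2]; h3 <= hmax[2]; ++h3) {
          if (h1 == 0 && h2 == 0 && h3 == 0) continue;
          // k = 2 pi * (h1,h2,h3) %*% Minv  (rows of Minv)
          double kx = 2 * M_PI * (h1 * Minv[0] + h2 * Minv[1] + h3 * Minv[2]);
          double ky = 2 * M_PI * (h1 * Minv[3] + h2 * Minv[4] + h3 * Minv[5]);
          double kz = 2 * M_PI * (h1 * Minv[6] + h2 * Minv[7] + h3 * Minv[8]);
          double k2 = kx * kx + ky * ky + kz * kz;
          if (k2 > kcut2) continue;
          double sre = 0, sim = 0;
          for (int i = 0; i < N; ++i) {
            if (q[i] == 0) continue;
            double ph = kx * coords(i, 0) + ky * coords(i, 1) + kz * coords(i, 2);
            sre += q[i] * std::cos(ph);
            sim += q[i] * std::sin(ph);
          }
          recip += pref * std::exp(-k2 * inv4a2) / k2 * (sre * sre + sim * sim);
        }

    double self = 0;
    for (int i = 0; i < N; ++i) self += q[i] * q[i];
    self *= alpha / std::sqrt(M_PI);

    double intra = 0;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (molid[i] != molid[j]) continue;
        double dx = coords(j, 0) - coords(i, 0);
        double dy = coords(j, 1) - coords(i, 1);
        double dz = coords(j, 2) - coords(i, 2);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r > 1e-12) intra += q[i] * q[j] * std::erf(alpha * r) / r;
      }

    res.e_qq = kcoul * (real + recip - self - intra) / Z;
  }

  // ---------------- dipole/quadrupole direct sum -----------------------
  // Summed over whole image cells (a block out to the electrostatic
  // cutoff) rather than a spherical atom-based cutoff: charge-dipole and
  // dipole-dipole terms are conditionally convergent, and whole neutral
  // cells cancel the boundary fluctuations a sphere would leave.
  if (any_mp) {
    int nmax[3];
    image_range(M, coords, el_cut, nmax);
    double acc = 0;
    for (int n1 = -nmax[0]; n1 <= nmax[0]; ++n1)
      for (int n2 = -nmax[1]; n2 <= nmax[1]; ++n2)
        for (int n3 = -nmax[2]; n3 <= nmax[2]; ++n3) {
          const bool home = (n1 == 0 && n2 == 0 && n3 == 0);
          Vec3 t = mat_vec(M, n1, n2, n3);
          for (int i = 0; i < N; ++i) {
            const double qi = q[i];
            const double mi[3] = { dip(i, 0), dip(i, 1), dip(i, 2) };
            const double Ti[9] = { quad(i, 0), quad(i, 1), quad(i, 2),
                                   quad(i, 3), quad(i, 4), quad(i, 5),
                                   quad(i, 6), quad(i, 7), quad(i, 8) };
            bool i_mp = (mi[0] != 0 || mi[1] != 0 || mi[2] != 0 ||
                         Ti[0] != 0 || Ti[1] != 0 || Ti[2] != 0 ||
                         Ti[4] != 0 || Ti[5] != 0 || Ti[8] != 0);
            for (int j = 0; j < N; ++j) {
              if (home && (i == j || molid[i] == molid[j])) continue;
              const double qj = q[j];
              const double mj[3] = { dip(j, 0), dip(j, 1), dip(j, 2) };
              const double Tj[9] = { quad(j, 0), quad(j, 1), quad(j, 2),
                                     quad(j, 3), quad(j, 4), quad(j, 5),
                                     quad(j, 6), quad(j, 7), quad(j, 8) };
              bool j_mp = (mj[0] != 0 || mj[1] != 0 || mj[2] != 0 ||
                           Tj[0] != 0 || Tj[1] != 0 || Tj[2] != 0 ||
                           Tj[4] != 0 || Tj[5] != 0 || Tj[8] != 0);
              if (!i_mp && !j_mp) continue;
              double Rx = coords(j, 0) + t.x - coords(i, 0);
              double Ry = coords(j, 1) + t.y - coords(i, 1);
              double Rz = coords(j, 2) + t.z - coords(i, 2);
              double r2 = Rx * Rx + Ry * Ry + Rz * Rz;
              if (r2 < clash_floor * clash_floor) continue; // degenerate pair
              double r = std::sqrt(r2);
              double ir = 1.0 / r, ir2 = ir * ir;
              double ir3 = ir * ir2, ir5 = ir3 * ir2, ir7 = ir5 * ir2,
                     ir9 = ir7 * ir2;
              const double R[3] = { Rx, Ry, Rz };
              // source-i moments: potential, gradient, Hessian at j
              double mdR = mi[0] * Rx + mi[1] * Ry + mi[2] * Rz;
              double TiR[3];
              for (int a = 0; a < 3; ++a)
                TiR[a] = Ti[a] * Rx + Ti[a + 3] * Ry + Ti[a + 6] * Rz;
              double TRR = TiR[0] * Rx + TiR[1] * Ry + TiR[2] * Rz;

              double phi = mdR * ir3 + TRR * ir5; // rank>=1 potential only
              double grad[3], hess[9];
              for (int a = 0; a < 3; ++a) {
                grad[a] = -qi * R[a] * ir3                 // charge
                        + mi[a] * ir3 - 3.0 * mdR * R[a] * ir5
                        + 2.0 * TiR[a] * ir5 - 5.0 * TRR * R[a] * ir7;
              }
              for (int a = 0; a < 3; ++a)
                for (int b = 0; b < 3; ++b) {
                  double dab = (a == b) ? 1.0 : 0.0;
                  double h = qi * (3.0 * R[a] * R[b] * ir5 - dab * ir3);
                  h += -3.0 * (mi[a] * R[b] + mi[b] * R[a] + mdR * dab) * ir5
                       + 15.0 * mdR * R[a] * R[b] * ir7;
                  h += 2.0 * Ti[a + 3 * b] * ir5
                       - 10.0 * (TiR[a] * R[b] + TiR[b] * R[a]) * ir7
                       - 5.0 * TRR * dab * ir7
                       + 35.0 * TRR * R[a] * R[b] * ir9;
                  hess[a + 3 * b] = h;
                }
              double u = qj * phi;
              for (int a = 0; a < 3; ++a) u += mj[a] * grad[a];
              double qh = 0;
              for (int k = 0; k < 9; ++k) qh += Tj[k] * hess[k];
              u += qh / 3.0;
              acc += u;
            }
          }
        }
    res.e_multi = kcoul * 0.5 * acc / Z;
  }

  return res;
}

// [[Rcpp::export]]
List cpp_cell_energy(NumericMatrix coords, IntegerVector molid,
                     IntegerVector type, NumericMatrix Apar,
                     NumericMatrix Bpar, NumericMatrix Cpar,
                     NumericMatrix rwall, NumericMatrix uwall,
                     NumericVector q, NumericMatrix dip, NumericMatrix quad,
                     NumericMatrix cellM, List settings) {
  EnergyResult r = cell_energy_core(coords, molid, type, Apar, Bpar, Cpar,
                                    rwall, uwall, q, dip, quad, cellM,
                                    settings);
  return List::create(_["repdisp"] = r.repdisp + r.tail,
                      _["repdisp_tail"] = r.tail,
                      _["e_qq"] = r.e_qq,
                      _["e_multi"] = r.e_multi,
                      _["elec"] = r.e_qq + r.e_multi,
                      _["min_r"] = r.min_r,
                      _["clash"] = r.clash);
}

// Build the full cell contents from packed packing variables and evaluate.
// local coordinates must be centred on the molecular centroid; opsW holds
// one fractional rotation part per row (row-major 3x3), opsw the
// fractional translations.
// [[Rcpp::export]]
List cpp_param_energy(NumericVector cellpar, NumericVector centroid,
                      NumericVector quat, NumericMatrix local,
                      IntegerVector type, NumericVector q,
                      NumericMatrix dipl, NumericMatrix quadl,
                      NumericMatrix opsW, NumericMatrix opsw,
                      NumericMatrix Apar, NumericMatrix Bpar,
                      NumericMatrix Cpar, NumericMatrix rwall,
                      NumericMatrix uwall, List settings) {
  const double d2r = M_PI / 180.0;
  double a = cellpar[0], b = cellpar[1], c = cellpar[2];
  double ca = std::cos(cellpar[3] * d2r), cb = std::cos(cellpar[4] * d2r),
         cg = std::cos(cellpar[5] * d2r), sg = std::sin(cellpar[5] * d2r);
  double arg = 1 + 2 * ca * cb * cg - ca * ca - cb * cb - cg * cg;
  if (!(a > 0 && b > 0 && c > 0) || arg <= 1e-4 || sg <= 1e-6) {
    return List::create(_["valid"] = false,
                        _["e_latt"] = 1e6 + (1e-4 - arg) * 1e6);
  }
  double M[9];
  M[0] = a; M[1] = 0; M[2] = 0;
  M[3] = b * cg; M[4] = b * sg; M[5] = 0;
  M[6] = c * cb; M[7] = c * (ca - cb * cg) / sg;
  M[8] = c * std::sqrt(arg) / sg;

  NumericMatrix cellM(3, 3);
  for (int cc = 0; cc < 3; ++cc)
    for (int rr = 0; rr < 3; ++rr) cellM(rr, cc) = M[3 * cc + rr];

  double det = cell_volume3(M);
  double Minv[9];
  inv3(M, det, Minv);

  // rotation matrix from unit quaternion
  double qn = std::sqrt(quat[0] * quat[0] + quat[1] * quat[1] +
                        quat[2] * quat[2] + quat[3] * quat[3]);
  double w = quat[0] / qn, x = quat[1] / qn, y = quat[2] / qn,
         z = quat[3] / qn;
  double R0[9]; // column-major
  R0[0] = 1 - 2 * (y * y + z * z); R0[1] = 2 * (x * y + w * z);
  R0[2] = 2 * (x * z - w * y);
  R0[3] = 2 * (x * y - w * z); R0[4] = 1 - 2 * (x * x + z * z);
  R0[5] = 2 * (y * z + w * x);
  R0[6] = 2 * (x * z + w * y); R0[7] = 2 * (y * z - w * x);
  R0[8] = 1 - 2 * (x * x + y * y);

  const int n = local.nrow();
  const int Z = opsw.nrow();
  const int N = n * Z;
  NumericMatrix coords(N, 3), dip(N, 3), quad(N, 9);
  IntegerVector molid(N), typeN(N);
  NumericVector qN(N);

  // asymmetric-unit fractional coordinates
  std::vector<double> frac0(3 * n);
  for (int i = 0; i < n; ++i) {
    double cx = R0[0] * local(i, 0) + R0[3] * local(i, 1) + R0[6] * local(i, 2);
    double cy = R0[1] * local(i, 0) + R0[4] * local(i, 1) + R0[7] * local(i, 2);
    double cz = R0[2] * local(i, 0) + R0[5] * local(i, 1) + R0[8] * local(i, 2);
    // add centroid (fractional) after converting atom vector to fractional
    double f1 = Minv[0] * cx + Minv[3] * cy + Minv[6] * cz + centroid[0];
    double f2 = Minv[1] * cx + Minv[4] * cy + Minv[7] * cz + centroid[1];
    double f3 = Minv[2] * cx + Minv[5] * cy + Minv[8] * cz + centroid[2];
    frac0[3 * i] = f1; frac0[3 * i + 1] = f2; frac0[3 * i + 2] = f3;
  }

  for (int k = 0; k < Z; ++k) {
    double W[9]; // row-major
    for (int e = 0; e < 9; ++e) W[e] = opsW(k, e);
    // Cartesian operation Ck = M W Minv (columns act on vectors)
    double WMinv[9], Ck[9]; // column-major products
    for (int cc = 0; cc < 3; ++cc)
      for (int rr = 0; rr < 3; ++rr)
        WMinv[3 * cc + rr] = W[3 * rr + 0] * Minv[3 * cc + 0] +
                             W[3 * rr + 1] * Minv[3 * cc + 1] +
                             W[3 * rr + 2] * Minv[3 * cc + 2];
    for (int cc = 0; cc < 3; ++cc)
      for (int rr = 0; rr < 3; ++rr)
        Ck[3 * cc + rr] = M[3 * 0 + rr] * WMinv[3 * cc + 0] +
                          M[3 * 1 + rr] * WMinv[3 * cc + 1] +
                          M[3 * 2 + rr] * WMinv[3 * cc + 2];
    // total Cartesian transform applied to molecular frame
    double Rt[9];
    for (int cc = 0; cc < 3; ++cc)
      for (int rr = 0; rr < 3; ++rr)
        Rt[3 * cc + rr] = Ck[3 * 0 + rr] * R0[3 * cc + 0] +
                          Ck[3 * 1 + rr] * R0[3 * cc + 1] +
                          Ck[3 * 2 + rr] * R0[3 * cc + 2];

    // image fractional coords + wrap by centroid
    double cenf[3] = { 0, 0, 0 };
    std::vector<double> fr(3 * n);
    for (int i = 0; i < n; ++i) {
      for (int rr = 0; rr < 3; ++rr) {
        double v = W[3 * rr + 0] * frac0[3 * i + 0] +
                   W[3 * rr + 1] * frac0[3 * i + 1] +
                   W[3 * rr + 2] * frac0[3 * i + 2] + opsw(k, rr);
        fr[3 * i + rr] = v;
        cenf[rr] += v / n;
      }
    }
    double shift[3] = { std::floor(cenf[0]), std::floor(cenf[1]),
                        std::floor(cenf[2]) };
    for (int i = 0; i < n; ++i) {
      int idx = k * n + i;
      double f1 = fr[3 * i] - shift[0], f2 = fr[3 * i + 1] - shift[1],
             f3 = fr[3 * i + 2] - shift[2];
      coords(idx, 0) = M[0] * f1 + M[3] * f2 + M[6] * f3;
      coords(idx, 1) = M[1] * f1 + M[4] * f2 + M[7] * f3;
      coords(idx, 2) = M[2] * f1 + M[5] * f2 + M[8] * f3;
      molid[idx] = k + 1;
      typeN[idx] = type[i];
      qN[idx] = q[i];
      for (int rr = 0; rr < 3; ++rr)
        dip(idx, rr) = Rt[3 * 0 + rr] * dipl(i, 0) +
                       Rt[3 * 1 + rr] * dipl(i, 1) +
                       Rt[3 * 2 + rr] * dipl(i, 2);
      // quad' = Rt Q Rt^T; first Qt = Q Rt^T, then quad_img = Rt Qt
      double Qt[9];
      for (int cc = 0; cc < 3; ++cc)
        for (int rr = 0; rr < 3; ++rr)
          Qt[3 * cc + rr] = quadl(i, 0 + rr) * Rt[3 * 0 + cc] +
                            quadl(i, 3 + rr) * Rt[3 * 1 + cc] +
                            quadl(i, 6 + rr) * Rt[3 * 2 + cc];
      for (int cc = 0; cc < 3; ++cc)
        for (int rr = 0; rr < 3; ++rr)
          quad(idx, 3 * cc + rr) = Rt[3 * 0 + rr] * Qt[3 * cc + 0] +
                                   Rt[3 * 1 + rr] * Qt[3 * cc + 1] +
                                   Rt[3 * 2 + rr] * Qt[3 * cc + 2];
    }
  }

  EnergyResult r = cell_energy_core(coords, molid, typeN, Apar, Bpar, Cpar,
                                    rwall, uwall, qN, dip, quad, cellM,
                                    settings);
  double e_rd = r.repdisp + r.tail;
  return List::create(_["valid"] = true,
                      _["e_latt"] = e_rd + r.e_qq + r.e_multi,
                      _["repdisp"] = e_rd,
                      _["e_qq"] = r.e_qq,
                      _["e_multi"] = r.e_multi,
                      _["elec"] = r.e_qq + r.e_multi,
                      _["min_r"] = r.min_r,
                      _["clash"] = r.clash,
                      _["volume"] = std::fabs(det));
}

// Minimum intermolecular contact margin min(r - s*(vdw_i + vdw_j)) over
// all pairs within a 6 A search radius (any pair beyond that has a
// positive margin for vdW-scale radii).
// [[Rcpp::export]]
List cpp_min_contact(NumericMatrix coords, IntegerVector molid,
                     NumericVector radii, NumericMatrix cellM, double s) {
  double M[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) M[3 * c + r] = cellM(r, c);
  const int N = coords.nrow();
  const double rc = 6.0, rc2 = rc * rc;
  int nmax[3];
  image_range(M, coords, rc, nmax);
  double min_margin = R_PosInf, min_r = R_PosInf;
  for (int n1 = -nmax[0]; n1 <= nmax[0]; ++n1)
    for (int n2 = -nmax[1]; n2 <= nmax[1]; ++n2)
      for (int n3 = -nmax[2]; n3 <= nmax[2]; ++n3) {
        const bool home = (n1 == 0 && n2 == 0 && n3 == 0);
        Vec3 t = mat_vec(M, n1, n2, n3);
        for (int i = 0; i < N; ++i)
          for (int j = 0; j < N; ++j) {
            if (home && (i == j || molid[i] == molid[j])) continue;
            double dx = coords(j, 0) + t.x - coords(i, 0);
            double dy = coords(j, 1) + t.y - coords(i, 1);
            double dz = coords(j, 2) + t.z - coords(i, 2);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 > rc2) continue;
            double r = std::sqrt(r2);
            double margin = r - s * (radii[i] + radii[j]);
            if (r < min_r) min_r = r;
            if (margin < min_margin) min_margin = margin;
          }
      }
  return List::create(_["min_margin"] = min_margin, _["min_r"] = min_r);
}

// Atom-centred symmetry functions (radial G2 + angular G4) for the atoms
// listed in center_idx (1-based, indices into coords), with periodic
// neighbours. elem is 1-based element channel per atom.
// [[Rcpp::export]]
NumericMatrix cpp_acsf(NumericMatrix coords, IntegerVector elem, int nelem,
                       NumericMatrix cellM, IntegerVector center_idx,
                       double rcut, NumericVector radial_rs,
                       double radial_eta, double ang_eta,
                       NumericVector ang_zeta, NumericVector ang_lambda) {
  double M[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) M[3 * c + r] = cellM(r, c);
  const int N = coords.nrow();
  const int nrs = radial_rs.size();
  const int ncombo = ang_zeta.size() * ang_lambda.size();
  const int npair = nelem * (nelem + 1) / 2;
  const int D = nelem * nrs + npair * ncombo;
  const int NC = center_idx.size();
  NumericMatrix out(NC, D);
  int nmax[3];
  image_range(M, coords, rcut, nmax);
  const double rc2 = rcut * rcut;

  for (int ci = 0; ci < NC; ++ci) {
    const int c0 = center_idx[ci] - 1;
    std::vector<double> ndx, ndy, ndz, nr, nfc;
    std::vector<int> nel;
    for (int n1 = -nmax[0]; n1 <= nmax[0]; ++n1)
      for (int n2 = -nmax[1]; n2 <= nmax[1]; ++n2)
        for (int n3 = -nmax[2]; n3 <= nmax[2]; ++n3) {
          const bool home = (n1 == 0 && n2 == 0 && n3 == 0);
          Vec3 t = mat_vec(M, n1, n2, n3);
          for (int j = 0; j < N; ++j) {
            if (home && j == c0) continue;
            double dx = coords(j, 0) + t.x - coords(c0, 0);
            double dy = coords(j, 1) + t.y - coords(c0, 1);
            double dz = coords(j, 2) + t.z - coords(c0, 2);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 > rc2 || r2 < 1e-12) continue;
            double r = std::sqrt(r2);
            ndx.push_back(dx); ndy.push_back(dy); ndz.push_back(dz);
            nr.push_back(r);
            nfc.push_back(0.5 * (std::cos(M_PI * r / rcut) + 1.0));
            nel.push_back(elem[j] - 1);
          }
        }
    const int nn = (int)nr.size();
    // radial G2
    for (int j = 0; j < nn; ++j)
      for (int k = 0; k < nrs; ++k) {
        double d = nr[j] - radial_rs[k];
        out(ci, nel[j] * nrs + k) += std::exp(-radial_eta * d * d) * nfc[j];
      }
    // angular G4
    for (int p = 0; p < nn; ++p)
      for (int qn_ = p + 1; qn_ < nn; ++qn_) {
        double dxp = ndx[p] - ndx[qn_], dyp = ndy[p] - ndy[qn_],
               dzp = ndz[p] - ndz[qn_];
        double rjk2 = dxp * dxp + dyp * dyp + dzp * dzp;
        if (rjk2 > rc2) continue;
        double rjk = std::sqrt(rjk2);
        double fc3 = nfc[p] * nfc[qn_] *
                     0.5 * (std::cos(M_PI * rjk / rcut) + 1.0);
        double cosq = (ndx[p] * ndx[qn_] + ndy[p] * ndy[qn_] +
                       ndz[p] * ndz[qn_]) / (nr[p] * nr[qn_]);
        double expo = std::exp(-ang_eta * (nr[p] * nr[p] + nr[qn_] * nr[qn_] +
                                           rjk2));
        int e1 = nel[p], e2 = nel[qn_];
        if (e1 > e2) { int tmp = e1; e1 = e2; e2 = tmp; }
        int pidx = e1 * nelem - e1 * (e1 - 1) / 2 + (e2 - e1);
        int col0 = nelem * nrs + pidx * ncombo;
        int cidx = 0;
        for (int zi = 0; zi < ang_zeta.size(); ++zi)
          for (int li = 0; li < ang_lambda.size(); ++li) {
            double base = 1.0 + ang_lambda[li] * cosq;
            double v = 0.0;
            if (base > 0)
              v = std::pow(2.0, 1.0 - ang_zeta[zi]) *
                  std::pow(base, ang_zeta[zi]) * expo * fc3;
            out(ci, col0 + cidx) += v;
            ++cidx;
          }
      }
  }
  return out;
}
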