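// Energy, Metropolis and test-particle kernels for the coarse-grained
// sorption engine. All functions take flat per-particle arrays prepared by
// the R wrappers (.sim_args); particle indices arriving from R are 1-based
// and converted at the boundary. The Metropolis and test-insertion paths
// use a sub-cell neighbour list (cell edge ~ rc/2, offsets chosen by
// box-box minimum distance) updated incrementally on accepted moves; small
// or non-periodic boxes fall back to the plain O(N) particle loop, which
// yields identical energies up to summation order.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

// nearest-image wrap; floor(d/L + 0.5) keeps components in [-L/2, L/2)
inline double mi(double d, double L, int per) {
  if (per) d -= L * std::floor(d / L + 0.5);
  return d;
}

struct Sim {
  int n;
  std::vector<double> x, y, z;
  std::vector<double> seps, sig, aff;  // seps = sqrt(epsilon)
  std::vector<int> isw;
  double Lx, Ly, Lz;
  int prx, pry, prz;
  double rc, rc2, alpha;
  int cidx;      // coupled particle (0-based), -1 if none
  double clam;   // its lambda
  NumericMatrix bonds;    // i j k r0 (i, j 0-based after conversion)
  NumericMatrix tethers;  // i k ax ay az
  std::vector<std::vector<int>> bond_rows;
  std::vector<int> tether_row;

  // cell list
  bool use_cells = false;
  int ncx = 0, ncy = 0, ncz = 0;
  double ex = 0, ey = 0, ez = 0;
  std::vector<std::vector<int>> cell;
  std::vector<int> cell_of, slot_of;
  std::vector<std::array<int, 3>> offs;

  inline double dist2(int i, int j) const {
    double dx = mi(x[j] - x[i], Lx, prx);
    double dy = mi(y[j] - y[i], Ly, pry);
    double dz = mi(z[j] - z[i], Lz, prz);
    return dx * dx + dy * dy + dz * dz;
  }

  inline bool excluded(int i, int j) const {
    for (int r : bond_rows[i]) {
      if ((int)bonds(r, 0) == j || (int)bonds(r, 1) == j) return true;
    }
    return false;
  }

  // Lennard-Jones pair term; soft-core separation shift when one member is
  // the partially coupled particle (exact plain LJ at lambda = 1)
  inline double pair_e(int i, int j) const {
    double r2 = dist2(i, j);
    if (r2 >= rc2) return 0.0;
    double sij = 0.5 * (sig[i] + sig[j]);
    double s2 = sij * sij;
    double e = seps[i] * seps[j];
    if (isw[i] != isw[j]) e *= (isw[i] ? aff[j] : aff[i]);
    double lam = 1.0;
    if (i == cidx || j == cidx) {
      lam = clam;
      if (lam == 0.0) return 0.0;
      r2 += alpha * (1.0 - lam) * s2;
    }
    double s6 = s2 / r2;
    s6 = s6 * s6 * s6;
    return lam * 4.0 * e * (s6 * s6 - s6);
  }

  double bonded_energy_of(int i) const {
    double E = 0.0;
    for (int r : bond_rows[i]) {
      int a = (int)bonds(r, 0), b = (int)bonds(r, 1);
      int j = (a == i) ? b : a;
      double d = std::sqrt(dist2(i, j));
      double dr = d - bonds(r, 3);
      E += 0.5 * bonds(r, 2) * dr * dr;
    }
    int tr = tether_row[i];
    if (tr >= 0) {
      double dx = mi(x[i] - tethers(tr, 2), Lx, prx);
      double dy = mi(y[i] - tethers(tr, 3), Ly, pry);
      double dz = mi(z[i] - tethers(tr, 4), Lz, prz);
      E += 0.5 * tethers(tr, 1) * (dx * dx + dy * dy + dz * dz);
    }
    return E;
  }

  inline int clampc(double v, double e, int nc) const {
    int c = (int)(v / e);
    if (c >= nc) c = nc - 1;
    if (c < 0) c = 0;
    return c;
  }
  inline int cell_index(int cx, int cy, int cz) const {
    return (cz * ncy + cy) * ncx + cx;
  }
  inline int cell_at(int i) const {
    return cell_index(clampc(x[i], ex, ncx), clampc(y[i], ey, ncy),
                      clampc(z[i], ez, ncz));
  }

  void setup_cells() {
    use_cells = false;
    if (!(prx && pry && prz) || n == 0) return;
    double target = rc * 0.5;
    ncx = std::max(1, (int)std::floor(Lx / target));
    ncy = std::max(1, (int)std::floor(Ly / target));
    ncz = std::max(1, (int)std::floor(Lz / target));
    ex = Lx / ncx; ey = Ly / ncy; ez = Lz / ncz;
    int mox = (int)std::ceil(rc / ex) + 1;
    int moy = (int)std::ceil(rc / ey) + 1;
    int moz = (int)std::ceil(rc / ez) + 1;
    offs.clear();
    int mx = 0, my = 0, mz = 0;
    for (int ox = -mox; ox <= mox; ++ox) {
      for (int oy = -moy; oy <= moy; ++oy) {
        for (int oz = -moz; oz <= moz; ++oz) {
          double dx = std::max(0.0, (std::abs(ox) - 1.0)) * ex;
          double dy = std::max(0.0, (std::abs(oy) - 1.0)) * ey;
          double dz = std::max(0.0, (std::abs(oz) - 1.0)) * ez;
          if (dx * dx + dy * dy + dz * dz < rc2) {
            offs.push_back({ox, oy, oz});
            mx = std::max(mx, std::abs(ox));
            my = std::max(my, std::abs(oy));
            mz = std::max(mz, std::abs(oz));
          }
        }
      }
    }
    // a wrapped neighbourhood must not visit any cell twice
    if (ncx < 2 * mx + 1 || ncy < 2 * my + 1 || ncz < 2 * mz + 1) return;
    cell.assign((size_t)ncx * ncy * ncz, {});
    cell_of.assign(n, -1);
    slot_of.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_at(i);
      cell_of[i] = c;
      slot_of[i] = (int)cell[c].size();
      cell[c].push_back(i);
    }
    use_cells = true;
  }

  void cell_update(int i) {
    if (!use_cells) return;
    int c = cell_at(i);
    if (c == cell_of[i]) return;
    std::vector<int>& v = cell[cell_of[i]];
    int sfree = slot_of[i];
    v[sfree] = v.back();
    slot_of[v[sfree]] = sfree;
    v.pop_back();
    cell_of[i] = c;
    slot_of[i] = (int)cell[c].size();
    cell[c].push_back(i);
  }

  // full interaction energy of particle i (pair + its bonded terms)
  double particle_energy(int i) const {
    double E = 0.0;
    bool hb = !bond_rows[i].empty();
    if (use_cells) {
      int cx = clampc(x[i], ex, ncx), cy = clampc(y[i], ey, ncy),
          cz = clampc(z[i], ez, ncz);
      for (const std::array<int, 3>& o : offs) {
        int ax = cx + o[0]; if (ax < 0) ax += ncx; else if (ax >= ncx) ax -= ncx;
        int ay = cy + o[1]; if (ay < 0) ay += ncy; else if (ay >= ncy) ay -= ncy;
        int az = cz + o[2]; if (az < 0) az += ncz; else if (az >= ncz) az -= ncz;
        const std::vector<int>& v = cell[cell_index(ax, ay, az)];
        for (int j : v) {
          if (j == i) continue;
          if (hb && excluded(i, j)) continue;
          E += pair_e(i, j);
        }
      }
    } else {
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (hb && excluded(i, j)) continue;
        E += pair_e(i, j);
      }
    }
    return E + bonded_energy_of(i);
  }

  // interaction energy of a fully coupled test water at a point
  double ghost_energy(double gx, double gy, double gz, double eps_w,
                      double sig_w) const {
    double E = 0.0;
    if (use_cells) {
      int cx = clampc(gx, ex, ncx), cy = clampc(gy, ey, ncy),
          cz = clampc(gz, ez, ncz);
      for (const std::array<int, 3>& o : offs) {
        int ax = cx + o[0]; if (ax < 0) ax += ncx; else if (ax >= ncx) ax -= ncx;
        int ay = cy + o[1]; if (ay < 0) ay += ncy; else if (ay >= ncy) ay -= ncy;
        int az = cz + o[2]; if (az < 0) az += ncz; else if (az >= ncz) az -= ncz;
        for (int j : cell[cell_index(ax, ay, az)]) {
          E += ghost_pair(gx, gy, gz, j, eps_w, sig_w);
        }
      }
    } else {
      for (int j = 0; j < n; ++j) E += ghost_pair(gx, gy, gz, j, eps_w, sig_w);
    }
    return E;
  }

  inline double ghost_pair(double gx, double gy, double gz, int j,
                           double eps_w, double sig_w) const {
    double dx = mi(x[j] - gx, Lx, prx);
    double dy = mi(y[j] - gy, Ly, pry);
    double dz = mi(z[j] - gz, Lz, prz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return 0.0;
    double sij = 0.5 * (sig_w + sig[j]);
    double s2 = sij * sij;
    double e = std::sqrt(eps_w) * seps[j];
    if (!isw[j]) e *= aff[j];
    double s6 = s2 / r2;
    s6 = s6 * s6 * s6;
    return 4.0 * e * (s6 * s6 - s6);
  }
};

Sim make_sim(const NumericMatrix& pos, const NumericVector& eps,
             const NumericVector& sig, const NumericVector& aff,
             const IntegerVector& isw, const NumericVector& L,
             const IntegerVector& per, double rc,
             const NumericMatrix& bonds, const NumericMatrix& tethers,
             int cidx, double clam, double alpha) {
  Sim s;
  s.n = pos.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  s.seps.resize(s.n); s.sig.resize(s.n); s.aff.resize(s.n); s.isw.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.seps[i] = std::sqrt(eps[i]);
    s.sig[i] = sig[i]; s.aff[i] = aff[i]; s.isw[i] = isw[i];
  }
  s.Lx = L[0]; s.Ly = L[1]; s.Lz = L[2];
  s.prx = per[0]; s.pry = per[1]; s.prz = per[2];
  s.rc = rc;
  s.rc2 = rc * rc;
  s.alpha = alpha;
  s.cidx = cidx;  // already 0-based (or -1) from R wrapper
  s.clam = clam;
  NumericMatrix b = clone(bonds);
  for (int r = 0; r < b.nrow(); ++r) { b(r, 0) -= 1.0; b(r, 1) -= 1.0; }
  NumericMatrix t = clone(tethers);
  for (int r = 0; r < t.nrow(); ++r) t(r, 0) -= 1.0;
  s.bonds = b;
  s.tethers = t;
  s.bond_rows.assign(s.n, {});
  for (int r = 0; r < b.nrow(); ++r) {
    s.bond_rows[(int)b(r, 0)].push_back(r);
    s.bond_rows[(int)b(r, 1)].push_back(r);
  }
  s.tether_row.assign(s.n, -1);
  for (int r = 0; r < t.nrow(); ++r) s.tether_row[(int)t(r, 0)] = r;
  return s;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_energy_report(NumericMatrix pos, NumericVector eps,
                                NumericVector sig, NumericVector aff,
                                IntegerVector isw, NumericVector L,
                                IntegerVector per, double rc,
                                NumericMatrix bonds, NumericMatrix tethers,
                                int cidx, double clam, double alpha) {
  Sim s = make_sim(pos, eps, sig, aff, isw, L, per, rc, bonds, tethers,
                   cidx, clam, alpha);
  double pair = 0.0, coup = 0.0, bonded = 0.0;
  for (int i = 0; i < s.n; ++i) {
    for (int j = i + 1; j < s.n; ++j) {
      if (!s.bond_rows[i].empty() && s.excluded(i, j)) continue;
      double e = s.pair_e(i, j);
      if (i == s.cidx || j == s.cidx) coup += e; else pair += e;
    }
  }
  for (int r = 0; r < s.bonds.nrow(); ++r) {
    int i = (int)s.bonds(r, 0), j = (int)s.bonds(r, 1);
    double d = std::sqrt(s.dist2(i, j));
    double dr = d - s.bonds(r, 3);
    bonded += 0.5 * s.bonds(r, 2) * dr * dr;
  }
  for (int r = 0; r < s.tethers.nrow(); ++r) {
    int i = (int)s.tethers(r, 0);
    double dx = mi(s.x[i] - s.tethers(r, 2), s.Lx, s.prx);
    double dy = mi(s.y[i] - s.tethers(r, 3), s.Ly, s.pry);
    double dz = mi(s.z[i] - s.tethers(r, 4), s.Lz, s.prz);
    bonded += 0.5 * s.tethers(r, 1) * (dx * dx + dy * dy + dz * dz);
  }
  return NumericVector::create(pair, bonded, coup);
}

// [[Rcpp::export]]
double cpp_particle_energy(NumericMatrix pos, NumericVector eps,
                           NumericVector sig, NumericVector aff,
                           IntegerVector isw, NumericVector L,
                           IntegerVector per, double rc, NumericMatrix bonds,
                           NumericMatrix tethers, int cidx, double clam,
                           double alpha, int i1) {
  Sim s = make_sim(pos, eps, sig, aff, isw, L, per, rc, bonds, tethers,
                   cidx, clam, alpha);
  return s.particle_energy(i1 - 1);
}

// Metropolis single-particle displacement sweeps at fixed N, V, T.
// One sweep = n random particle picks; uses R's RNG so set.seed() in R
// makes runs reproducible. With probability pjump a picked free molecule
// (no bonds, no tether: waters and unbonded beads) attempts a relocation
// to a uniform random point instead of a local displacement (a symmetric
// proposal, so the standard acceptance rule applies); this mimics the fast
// diffusion of small molecules relative to matrix relaxation.
// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos, NumericVector eps, NumericVector sig,
               NumericVector aff, IntegerVector isw, NumericVector L,
               IntegerVector per, double rc, NumericMatrix bonds,
               NumericMatrix tethers, int cidx, double clam, double alpha,
               int n_sweeps, double beta, double max_disp, int save_every,
               double pjump) {
  Sim s = make_sim(pos, eps, sig, aff, isw, L, per, rc, bonds, tethers,
                   cidx, clam, alpha);
  s.setup_cells();
  List frames;
  long n_acc = 0, n_try = 0;
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int m = 0; m < s.n; ++m) {
      int i = (int)(unif_rand() * s.n);
      if (i >= s.n) i = s.n - 1;
      double e0 = s.particle_energy(i);
      double ox = s.x[i], oy = s.y[i], oz = s.z[i];
      double nx, ny, nz;
      bool free_mol = s.bond_rows[i].empty() && s.tether_row[i] < 0;
      if (free_mol && pjump > 0.0 && unif_rand() < pjump) {
        nx = unif_rand() * s.Lx;
        ny = unif_rand() * s.Ly;
        nz = unif_rand() * s.Lz;
      } else {
        nx = ox + (2.0 * unif_rand() - 1.0) * max_disp;
        ny = oy + (2.0 * unif_rand() - 1.0) * max_disp;
        nz = oz + (2.0 * unif_rand() - 1.0) * max_disp;
      }
      if (s.prx) nx -= s.Lx * std::floor(nx / s.Lx);
      if (s.pry) ny -= s.Ly * std::floor(ny / s.Ly);
      if (s.prz) nz -= s.Lz * std::floor(nz / s.Lz);
      s.x[i] = nx; s.y[i] = ny; s.z[i] = nz;
      s.cell_update(i);
      double e1 = s.particle_energy(i);
      double dE = e1 - e0;
      ++n_try;
      if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
        ++n_acc;
      } else {
        s.x[i] = ox; s.y[i] = oy; s.z[i] = oz;
        s.cell_update(i);
      }
    }
    if (save_every > 0 && sweep % save_every == 0) {
      NumericMatrix f(s.n, 3);
      for (int i = 0; i < s.n; ++i) {
        f(i, 0) = s.x[i]; f(i, 1) = s.y[i]; f(i, 2) = s.z[i];
      }
      frames.push_back(f);
    }
  }
  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    out(i, 0) = s.x[i]; out(i, 1) = s.y[i]; out(i, 2) = s.z[i];
  }
  double acc = n_try > 0 ? (double)n_acc / (double)n_try : NA_REAL;
  return List::create(_["positions"] = out, _["acceptance"] = acc,
                      _["frames"] = frames);
}

// ghost (test) insertion energies of a fully coupled water at uniform
// random positions; the configuration is never modified
// [[Rcpp::export]]
List cpp_insertion_energies(NumericMatrix pos, NumericVector eps,
                            NumericVector sig, NumericVector aff,
                            IntegerVector isw, NumericVector L,
                            IntegerVector per, double rc, int n_ins,
                            double eps_w, double sig_w) {
  Sim s = make_sim(pos, eps, sig, aff, isw, L, per, rc,
                   NumericMatrix(0, 4), NumericMatrix(0, 5), -1, 1.0, 0.5);
  s.setup_cells();
  NumericVector du(n_ins);
  NumericMatrix at(n_ins, 3);
  for (int t = 0; t < n_ins; ++t) {
    double gx = unif_rand() * L[0];
    double gy = unif_rand() * L[1];
    double gz = unif_rand() * L[2];
    at(t, 0) = gx; at(t, 1) = gy; at(t, 2) = gz;
    du[t] = s.ghost_energy(gx, gy, gz, eps_w, sig_w);
  }
  return List::create(_["du"] = du, _["positions"] = at);
}

// deletion energy change (U without - U with = -interaction energy) for
// every fully coupled water, in particle order
// [[Rcpp::export]]
NumericVector cpp_deletion_energies(NumericMatrix pos, NumericVector eps,
                                    NumericVector sig, NumericVector aff,
                                    IntegerVector isw, NumericVector L,
                                    IntegerVector per, double rc,
                                    NumericMatrix bonds, NumericMatrix tethers,
                                    int cidx, double clam, double alpha) {
  Sim s = make_sim(pos, eps, sig, aff, isw, L, per, rc, bonds, tethers,
                   cidx, clam, alpha);
  s.setup_cells();
  std::vector<double> out;
  for (int i = 0; i < s.n; ++i) {
    if (s.isw[i] && i != s.cidx) out.push_back(-s.particle_energy(i));
  }
  return wrap(out);
}

// smallest r_ij / sigma_ij between a trial point and all particles
// (overlap criterion for insertions)
// [[Rcpp::export]]
double cpp_min_sep_ratio(NumericMatrix pos, NumericVector sig, NumericVector L,
                         IntegerVector per, double px, double py, double pz,
                         double sig_w) {
  int n = pos.nrow();
  double best = R_PosInf;
  for (int j = 0; j < n; ++j) {
    double dx = mi(pos(j, 0) - px, L[0], per[0]);
    double dy = mi(pos(j, 1) - py, L[1], per[1]);
    double dz = mi(pos(j, 2) - pz, L[2], per[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ratio = r / (0.5 * (sig_w + sig[j]));
    if (ratio < best) best = ratio;
  }
  return best;
}

// Shrake-Rupley accessible area for particles in `subset` (1-based),
// using pre-expanded radii (r + probe) and unit sphere points
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix pos, NumericVector radii, NumericVector L,
                       IntegerVector per, NumericMatrix pts,
                       IntegerVector subset) {
  int ns = subset.size(), np = pts.nrow();
  NumericVector area(ns);
  for (int a = 0; a < ns; ++a) {
    int i = subset[a] - 1;
    double Ri = radii[i];
    // neighbours (nearest-image displacements relative to i)
    std::vector<double> bx, by, bz, br2;
    for (int si = 0; si < ns; ++si) {
      int j = subset[si] - 1;
      if (j == i) continue;
      double dx = mi(pos(j, 0) - pos(i, 0), L[0], per[0]);
      double dy = mi(pos(j, 1) - pos(i, 1), L[1], per[1]);
      double dz = mi(pos(j, 2) - pos(i, 2), L[2], per[2]);
      double Rj = radii[j];
      double lim = Ri + Rj;
      if (dx * dx + dy * dy + dz * dz < lim * lim) {
        bx.push_back(dx); by.push_back(dy); bz.push_back(dz);
        br2.push_back(Rj * Rj);
      }
    }
    int n_acc = 0;
    for (int p = 0; p < np; ++p) {
      double qx = Ri * pts(p, 0), qy = Ri * pts(p, 1), qz = Ri * pts(p, 2);
      bool buried = false;
      for (size_t b = 0; b < bx.size(); ++b) {
        double dx = qx - bx[b], dy = qy - by[b], dz = qz - bz[b];
        if (dx * dx + dy * dy + dz * dz < br2[b]) { buried = true; break; }
      }
      if (!buried) ++n_acc;
    }
    area[a] = 4.0 * M_PI * Ri * Ri * (double)n_acc / (double)np;
  }
  return area;
}

// minimum-image distance matrix between two position sets
// [[Rcpp::export]]
NumericMatrix cpp_dist_mi(NumericMatrix A, NumericMatrix B, NumericVector L,
                          IntegerVector per) {
  int na = A.nrow(), nb = B.nrow();
  NumericMatrix D(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = mi(B(j, 0) - A(i, 0), L[0], per[0]);
      double dy = mi(B(j, 1) - A(i, 1), L[1], per[1]);
      double dz = mi(B(j, 2) - A(i, 2), L[2], per[2]);
      D(i, j) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return D;
}
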