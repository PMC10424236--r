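// Energy and Metropolis Monte Carlo kernels for the coarse-grained DNA pair
// system. Units: nm, kJ/mol, elementary charges. Molecules are stored
// unwrapped (the centre-of-mass reaction coordinate must not be folded by
// the minimum image); ions are wrapped into [0, edge). All non-bonded
// interactions use the minimum-image convention in a cubic periodic box.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Params {
  double bond_k, bend_k, sigma, eps, lB, lD, kT, rcut, edge;
  double coul_pref;   // kT * lB
  double wca_rmin2;   // (2^(1/6) sigma)^2
  double shift;       // screened-kernel value at rcut, subtracted (cut & shift)
  bool screened;
};

inline double min_img(double d, double edge) {
  return d - edge * std::round(d / edge);
}

inline double pair_dist2(const std::vector<double>& x,
                         const std::vector<double>& y,
                         const std::vector<double>& z,
                         int i, int j, double edge) {
  double dx = min_img(x[i] - x[j], edge);
  double dy = min_img(y[i] - y[j], edge);
  double dz = min_img(z[i] - z[j], edge);
  return dx * dx + dy * dy + dz * dz;
}

inline double wca(double r2, const Params& p) {
  if (r2 >= p.wca_rmin2) return 0.0;
  double sr2 = p.sigma * p.sigma / r2;
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * p.eps * (sr6 * sr6 - sr6) + p.eps;
}

// screened Coulomb kernel (without charge product), cut & shifted at rcut
inline double coul_kernel(double r, const Params& p) {
  if (r >= p.rcut) return 0.0;
  double s = p.screened ? std::exp(-r / p.lD) / r : 1.0 / r;
  return s - p.shift;
}

// non-bonded energy between particles i and j; excl = true if 1-2 bonded
inline double nb_pair(const std::vector<double>& x,
                      const std::vector<double>& y,
                      const std::vector<double>& z,
                      const std::vector<double>& q,
                      int i, int j, bool excl, const Params& p) {
  double r2 = pair_dist2(x, y, z, i, j, p.edge);
  if (r2 < 1e-12) return 1e12;  // numeric guard: overlapping sites
  double e = excl ? 0.0 : wca(r2, p);
  double qq = q[i] * q[j];
  if (qq != 0.0) e += p.coul_pref * qq * coul_kernel(std::sqrt(r2), p);
  return e;
}

Params make_params(List ff, double edge) {
  Params p;
  p.bond_k = as<double>(ff["bond_k"]);
  p.bend_k = as<double>(ff["bend_k"]);
  p.sigma  = as<double>(ff["wca_sigma"]);
  p.eps    = as<double>(ff["wca_epsilon"]);
  p.lB     = as<double>(ff["bjerrum_length"]);
  p.lD     = as<double>(ff["debye_length"]);
  p.kT     = as<double>(ff["kT"]);
  p.edge   = edge;
  p.rcut   = edge / 2.0;
  p.coul_pref = p.kT * p.lB;
  p.screened = p.lD > 0;
  p.shift = (p.screened ? std::exp(-p.rcut / p.lD) : 1.0) / p.rcut;
  double rmin = std::pow(2.0, 1.0 / 6.0) * p.sigma;
  p.wca_rmin2 = rmin * rmin;
  return p;
}

struct Topology {
  std::vector<int> bi, bj;           // bonds, 0-based
  std::vector<double> br0;
  std::vector<int> ai, aj, ak;       // angles
  std::vector<double> ath0;
  std::vector<std::vector<int>> excl;        // 1-2 exclusion adjacency
  std::vector<std::vector<int>> bonds_of;    // bond ids touching particle
  std::vector<std::vector<int>> angles_of;   // angle ids touching particle
};

Topology make_topology(IntegerVector bi, IntegerVector bj, NumericVector br0,
                       IntegerVector ai, IntegerVector aj, IntegerVector ak,
                       NumericVector ath0, int n) {
  Topology t;
  t.bi.assign(bi.begin(), bi.end());
  t.bj.assign(bj.begin(), bj.end());
  t.br0.assign(br0.begin(), br0.end());
  t.ai.assign(ai.begin(), ai.end());
  t.aj.assign(aj.begin(), aj.end());
  t.ak.assign(ak.begin(), ak.end());
  t.ath0.assign(ath0.begin(), ath0.end());
  t.excl.resize(n);
  t.bonds_of.resize(n);
  t.angles_of.resize(n);
  for (size_t b = 0; b < t.bi.size(); ++b) {
    t.excl[t.bi[b]].push_back(t.bj[b]);
    t.excl[t.bj[b]].push_back(t.bi[b]);
    t.bonds_of[t.bi[b]].push_back((int)b);
    t.bonds_of[t.bj[b]].push_back((int)b);
  }
  for (size_t a = 0; a < t.ai.size(); ++a) {
    t.angles_of[t.ai[a]].push_back((int)a);
    t.angles_of[t.aj[a]].push_back((int)a);
    t.angles_of[t.ak[a]].push_back((int)a);
  }
  return t;
}

inline bool is_excl(const Topology& t, int i, int j) {
  for (int k : t.excl[i]) if (k == j) return true;
  return false;
}

double bond_energy(const std::vector<double>& x, const std::vector<double>& y,
                   const std::vector<double>& z, const Topology& t, int b,
                   const Params& p) {
  // bonded neighbours are always within the same unwrapped molecule
  double dx = x[t.bi[b]] - x[t.bj[b]];
  double dy = y[t.bi[b]] - y[t.bj[b]];
  double dz = z[t.bi[b]] - z[t.bj[b]];
  double d = std::sqrt(dx * dx + dy * dy + dz * dz) - t.br0[b];
  return 0.5 * p.bond_k * d * d;
}

double angle_energy(const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<double>& z, const Topology& t, int a,
                    const Params& p) {
  int i = t.ai[a], j = t.aj[a], k = t.ak[a];
  double ux = x[i] - x[j], uy = y[i] - y[j], uz = z[i] - z[j];
  double vx = x[k] - x[j], vy = y[k] - y[j], vz = z[k] - z[j];
  double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
  double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
  double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
  c = std::max(-1.0, std::min(1.0, c));
  double d = std::acos(c) - t.ath0[a];
  return 0.5 * p.bend_k * d * d;
}

// total non-bonded + bonded energy (double loop; used for the exported
// total_energy and as the reference inside the kernel tests)
double total_energy_impl(const std::vector<double>& x,
                         const std::vector<double>& y,
                         const std::vector<double>& z,
                         const std::vector<double>& q,
                         const Topology& t, const Params& p) {
  int n = (int)x.size();
  double e = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      e += nb_pair(x, y, z, q, i, j, is_excl(t, i, j), p);
  for (size_t b = 0; b < t.bi.size(); ++b) e += bond_energy(x, y, z, t, b, p);
  for (size_t a = 0; a < t.ai.size(); ++a) e += angle_energy(x, y, z, t, a, p);
  return e;
}

}  // namespace

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, NumericVector charge,
                        IntegerVector bi, IntegerVector bj, NumericVector br0,
                        IntegerVector ai, IntegerVector aj, IntegerVector ak,
                        NumericVector ath0, List ff, double edge) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), q(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    q[i] = charge[i];
  }
  Params p = make_params(ff, edge);
  Topology t = make_topology(bi, bj, br0, ai, aj, ak, ath0, n);
  double e = total_energy_impl(x, y, z, q, t, p);
  if (e >= 1e12) stop("overlapping point charges (r < 1e-6 nm)");
  return e;
}

namespace {

struct MCState {
  std::vector<double> x, y, z, q;
  int nA, nB, n;              // molecule A = [0, nA), B = [nA, nA+nB)
  double comA[3], comB[3];
  void update_coms() {
    for (int d = 0; d < 3; ++d) { comA[d] = 0; comB[d] = 0; }
    for (int i = 0; i < nA; ++i) { comA[0] += x[i]; comA[1] += y[i]; comA[2] += z[i]; }
    for (int i = nA; i < nA + nB; ++i) { comB[0] += x[i]; comB[1] += y[i]; comB[2] += z[i]; }
    for (int d = 0; d < 3; ++d) { comA[d] /= nA; comB[d] /= nB; }
  }
  double rc() const {
    double dx = comA[0] - comB[0], dy = comA[1] - comB[1], dz = comA[2] - comB[2];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }
};

inline double bias(double r, double c, double fk) {
  return 0.5 * fk * (r - c) * (r - c);
}

inline bool metro(double dE, double kT) {
  if (dE <= 0) return true;
  if (kT <= 0) return false;
  return unif_rand() < std::exp(-dE / kT);
}

// interaction of particle i with all others (non-bonded) plus its bonded terms
double particle_energy(const MCState& s, const Topology& t, const Params& p,
                       int i) {
  double e = 0.0;
  for (int j = 0; j < s.n; ++j)
    if (j != i) e += nb_pair(s.x, s.y, s.z, s.q, i, j, is_excl(t, i, j), p);
  for (int b : t.bonds_of[i]) e += bond_energy(s.x, s.y, s.z, t, b, p);
  for (int a : t.angles_of[i]) e += angle_energy(s.x, s.y, s.z, t, a, p);
  return e;
}

// cross energy between a molecule [lo, hi) and everything outside it
double cross_energy(const MCState& s, const Topology& t, const Params& p,
                    int lo, int hi) {
  double e = 0.0;
  for (int i = lo; i < hi; ++i)
    for (int j = 0; j < s.n; ++j)
      if (j < lo || j >= hi)
        e += nb_pair(s.x, s.y, s.z, s.q, i, j, is_excl(t, i, j), p);
  return e;
}

}  // namespace

// Run n_sweeps Metropolis sweeps. One sweep = one trial displacement per ion,
// then per molecule: one trial displacement per bead, one rigid COM
// translation, one rigid rotation about the COM. The harmonic umbrella bias
// 0.5*fk*(rc - center)^2 on the (unwrapped) COM separation enters every
// acceptance test. amps = c(d_ion, d_bead, d_trans, d_rot); when tune = TRUE
// the amplitudes are adjusted every 50 sweeps towards 30-50% acceptance.
// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix pos, NumericVector charge, int nA, int nB,
                IntegerVector bi, IntegerVector bj, NumericVector br0,
                IntegerVector ai, IntegerVector aj, IntegerVector ak,
                NumericVector ath0, List ff, double edge,
                double center, double fk,
                int n_sweeps, int sample_stride, int frame_stride,
                NumericVector amps, bool tune) {
  RNGScope rng;
  MCState s;
  s.n = pos.nrow();
  s.nA = nA; s.nB = nB;
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n); s.q.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.q[i] = charge[i];
  }
  s.update_coms();
  Params p = make_params(ff, edge);
  Topology t = make_topology(bi, bj, br0, ai, aj, ak, ath0, s.n);
  int n_ion = s.n - nA - nB;
  int ion0 = nA + nB;

  double d_ion = amps[0], d_bead = amps[1], d_trans = amps[2], d_rot = amps[3];
  // acceptance bookkeeping: [ion, bead, trans, rot]
  long acc[4] = {0, 0, 0, 0}, att[4] = {0, 0, 0, 0};
  long acc_blk[4] = {0, 0, 0, 0}, att_blk[4] = {0, 0, 0, 0};

  std::vector<double> rc_series;
  List frames;
  std::vector<NumericMatrix> frame_store;

  int mol_lo[2] = {0, nA}, mol_hi[2] = {nA, nA + nB};

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    // --- single-ion displacements -------------------------------------
    for (int i = ion0; i < s.n; ++i) {
      double ox = s.x[i], oy = s.y[i], oz = s.z[i];
      double e0 = particle_energy(s, t, p, i);
      s.x[i] = ox + d_ion * (2.0 * unif_rand() - 1.0);
      s.y[i] = oy + d_ion * (2.0 * unif_rand() - 1.0);
      s.z[i] = oz + d_ion * (2.0 * unif_rand() - 1.0);
      // wrap ions into the box
      s.x[i] -= edge * std::floor(s.x[i] / edge);
      s.y[i] -= edge * std::floor(s.y[i] / edge);
      s.z[i] -= edge * std::floor(s.z[i] / edge);
      double dE = particle_energy(s, t, p, i) - e0;
      ++att[0]; ++att_blk[0];
      if (metro(dE, p.kT)) { ++acc[0]; ++acc_blk[0]; }
      else { s.x[i] = ox; s.y[i] = oy; s.z[i] = oz; }
    }
    // --- molecule moves ------------------------------------------------
    for (int m = 0; m < 2; ++m) {
      int lo = mol_lo[m], hi = mol_hi[m], nm = hi - lo;
      double* com = (m == 0) ? s.comA : s.comB;
      // per-bead displacements (shift the COM by delta/nm)
      for (int i = lo; i < hi; ++i) {
        double ox = s.x[i], oy = s.y[i], oz = s.z[i];
        double r0c = s.rc();
        double e0 = particle_energy(s, t, p, i) + bias(r0c, center, fk);
        double dx = d_bead * (2.0 * unif_rand() - 1.0);
        double dy = d_bead * (2.0 * unif_rand() - 1.0);
        double dz = d_bead * (2.0 * unif_rand() - 1.0);
        s.x[i] += dx; s.y[i] += dy; s.z[i] += dz;
        com[0] += dx / nm; com[1] += dy / nm; com[2] += dz / nm;
        double dE = particle_energy(s, t, p, i) + bias(s.rc(), center, fk) - e0;
        ++att[1]; ++att_blk[1];
        if (metro(dE, p.kT)) { ++acc[1]; ++acc_blk[1]; }
        else {
          s.x[i] = ox; s.y[i] = oy; s.z[i] = oz;
          com[0] -= dx / nm; com[1] -= dy / nm; com[2] -= dz / nm;
        }
      }
      // rigid COM translation (intramolecular terms unchanged)
      {
        double r0c = s.rc();
        double e0 = cross_energy(s, t, p, lo, hi) + bias(r0c, center, fk);
        double dx = d_trans * (2.0 * unif_rand() - 1.0);
        double dy = d_trans * (2.0 * unif_rand() - 1.0);
        double dz = d_trans * (2.0 * unif_rand() - 1.0);
        for (int i = lo; i < hi; ++i) { s.x[i] += dx; s.y[i] += dy; s.z[i] += dz; }
        com[0] += dx; com[1] += dy; com[2] += dz;
        double dE = cross_energy(s, t, p, lo, hi) + bias(s.rc(), center, fk) - e0;
        ++att[2]; ++att_blk[2];
        if (metro(dE, p.kT)) { ++acc[2]; ++acc_blk[2]; }
        else {
          for (int i = lo; i < hi; ++i) { s.x[i] -= dx; s.y[i] -= dy; s.z[i] -= dz; }
          com[0] -= dx; com[1] -= dy; com[2] -= dz;
        }
      }
      // rigid rotation about the COM (COM and rc unchanged)
      if (nm > 1) {
        double e0 = cross_energy(s, t, p, lo, hi);
        double axx = norm_rand(), axy = norm_rand(), axz = norm_rand();
        double an = std::sqrt(axx * axx + axy * axy + axz * axz);
        if (an < 1e-12) { axx = 1; axy = 0; axz = 0; an = 1; }
        axx /= an; axy /= an; axz /= an;
        double th = d_rot * (2.0 * unif_rand() - 1.0);
        double ct = std::cos(th), st = std::sin(th);
        std::vector<double> sx(nm), sy(nm), sz(nm);
        for (int i = lo; i < hi; ++i) {
          int k = i - lo;
          sx[k] = s.x[i]; sy[k] = s.y[i]; sz[k] = s.z[i];
          double px = s.x[i] - com[0], py = s.y[i] - com[1], pz = s.z[i] - com[2];
          double dot = axx * px + axy * py + axz * pz;
          double cx = axy * pz - axz * py;
          double cy = axz * px - axx * pz;
          double cz = axx * py - axy * px;
          s.x[i] = com[0] + px * ct + cx * st + axx * dot * (1 - ct);
          s.y[i] = com[1] + py * ct + cy * st + axy * dot * (1 - ct);
          s.z[i] = com[2] + pz * ct + cz * st + axz * dot * (1 - ct);
        }
        double dE = cross_energy(s, t, p, lo, hi) - e0;
        ++att[3]; ++att_blk[3];
        if (metro(dE, p.kT)) { ++acc[3]; ++acc_blk[3]; }
        else {
          for (int i = lo; i < hi; ++i) {
            int k = i - lo;
            s.x[i] = sx[k]; s.y[i] = sy[k]; s.z[i] = sz[k];
          }
        }
      }
    }
    // --- amplitude tuning during equilibration -------------------------
    if (tune && sweep % 50 == 0) {
      double* d[4] = {&d_ion, &d_bead, &d_trans, &d_rot};
      double dmax[4] = {edge / 4, edge / 4, edge / 4, M_PI};
      for (int k = 0; k < 4; ++k) {
        if (att_blk[k] == 0) continue;
        double a = (double)acc_blk[k] / att_blk[k];
        if (a > 0.5) *d[k] = std::min(*d[k] * 1.2, dmax[k]);
        else if (a < 0.3) *d[k] = std::max(*d[k] * 0.8, 1e-5);
        acc_blk[k] = 0; att_blk[k] = 0;
      }
    }
    if (sample_stride > 0 && sweep % sample_stride == 0)
      rc_series.push_back(s.rc());
    if (frame_stride > 0 && sweep % frame_stride == 0) {
      NumericMatrix f(s.n, 3);
      for (int i = 0; i < s.n; ++i) {
        f(i, 0) = s.x[i]; f(i, 1) = s.y[i]; f(i, 2) = s.z[i];
      }
      frame_store.push_back(f);
    }
    if (sweep % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    out(i, 0) = s.x[i]; out(i, 1) = s.y[i]; out(i, 2) = s.z[i];
  }
  NumericVector acc_rate(4), amps_out(4);
  const char* nm[4] = {"ion", "bead", "translate", "rotate"};
  CharacterVector mn(4);
  for (int k = 0; k < 4; ++k) {
    acc_rate[k] = att[k] > 0 ? (double)acc[k] / att[k] : NA_REAL;
    mn[k] = nm[k];
  }
  acc_rate.names() = mn;
  amps_out[0] = d_ion; amps_out[1] = d_bead;
  amps_out[2] = d_trans; amps_out[3] = d_rot;
  List fl(frame_store.size());
  for (size_t i = 0; i < frame_store.size(); ++i) fl[i] = frame_store[i];
  return List::create(_["positions"] = out,
                      _["rc_series"] = NumericVector(rc_series.begin(), rc_series.end()),
                      _["frames"] = fl,
                      _["acceptance"] = acc_rate,
                      _["amps"] = amps_out);
}
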