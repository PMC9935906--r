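#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Coords {
  std::vector<double> x, y, z;
  explicit Coords(const NumericMatrix &m)
      : x(m.nrow()), y(m.nrow()), z(m.nrow()) {
    for (int i = 0; i < m.nrow(); ++i) {
      x[i] = m(i, 0); y[i] = m(i, 1); z[i] = m(i, 2);
    }
  }
  int n() const { return (int)x.size(); }
};

inline bool excluded_pair(int res_i, int res_j, int chain_i, int chain_j,
                          int resno_i, int resno_j) {
  if (res_i == res_j) return true;                       // intra-residue
  if (chain_i == chain_j && std::abs(resno_i - resno_j) <= 1) return true;
  return false;                                          // 1-2 bonded shell
}

// Split Lennard-Jones: plateaued attractive branch (-eps inside the
// contact distance, full 12-6 beyond, switched to zero over
// [switch_on, cutoff]) and a clamped repulsive branch active only
// inside the contact distance.
inline void lj_pair(double r, double eps, double rm, double cutoff,
                    double switch_on, double &atr, double &rep) {
  atr = 0.0; rep = 0.0;
  if (r >= cutoff) return;
  if (r < rm) {
    atr = -eps;
    double rr = r < 0.6 * rm ? 0.6 * rm : r;
    double s2 = (rm / rr) * (rm / rr);
    double s6 = s2 * s2 * s2;
    rep = eps * (s6 * s6 - 2.0 * s6 + 1.0);
  } else {
    double s2 = (rm / r) * (rm / r);
    double s6 = s2 * s2 * s2;
    double e = eps * (s6 * s6 - 2.0 * s6);
    if (r > switch_on) {
      double c2 = cutoff * cutoff, so2 = switch_on * switch_on, r2 = r * r;
      double sw = (c2 - r2) * (c2 - r2) * (c2 + 2.0 * r2 - 3.0 * so2) /
                  ((c2 - so2) * (c2 - so2) * (c2 - so2));
      e *= sw;
    }
    atr = e;
  }
}

}  // namespace

// Shrake-Rupley accessible surface area with a deterministic
// golden-section spiral point lattice. Radii are per-atom van der Waals
// radii; the probe radius is added to every atom.
// [[Rcpp::export(name = ".sasa_kernel")]]
NumericVector sasa_kernel(NumericMatrix xyz, NumericVector radius,
                          double probe, int n_points) {
  Coords c(xyz);
  const int n = c.n();
  NumericVector area(n);
  if (n == 0) return area;

  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zz = 1.0 - (2.0 * k + 1.0) / n_points;
    double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
    double phi = ga * k;
    px[k] = rr * std::cos(phi);
    py[k] = rr * std::sin(phi);
    pz[k] = zz;
  }

  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radius[i] + probe;

  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = c.x[i] - c.x[j], dy = c.y[i] - c.y[j], dz = c.z[i] - c.z[j];
      double lim = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double sx = c.x[i] + R[i] * px[k];
      double sy = c.y[i] + R[i] * py[k];
      double sz = c.z[i] + R[i] * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = sx - c.x[j], dy = sy - c.y[j], dz = sz - c.z[j];
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * acc / n_points;
  }
  return area;
}

// Total attractive/repulsive energies plus exact per-residue attribution
// (cross terms split half/half between the partner residues).
// [[Rcpp::export(name = ".pair_energy_kernel")]]
List pair_energy_kernel(NumericMatrix xyz, NumericVector eps, NumericVector rmin,
                        IntegerVector res, IntegerVector chain, IntegerVector resno,
                        int n_res, double cutoff, double switch_on) {
  Coords c(xyz);
  const int n = c.n();
  double atr_tot = 0.0, rep_tot = 0.0;
  NumericVector res_atr(n_res), res_rep(n_res);
  const double cut2 = cutoff * cutoff;
  const int *resp = res.begin(), *chp = chain.begin(), *rnp = resno.begin();
  const double *ep = eps.begin(), *rp = rmin.begin();
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = c.x[i] - c.x[j];
      if (dx * dx >= cut2) continue;
      double dy = c.y[i] - c.y[j], dz = c.z[i] - c.z[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= cut2) continue;
      if (excluded_pair(resp[i], resp[j], chp[i], chp[j], rnp[i], rnp[j]))
        continue;
      double r = std::sqrt(d2);
      double e = std::sqrt(ep[i] * ep[j]);
      double rm = rp[i] + rp[j];
      double a, p;
      lj_pair(r, e, rm, cutoff, switch_on, a, p);
      atr_tot += a; rep_tot += p;
      res_atr[resp[i]] += 0.5 * a; res_atr[resp[j]] += 0.5 * a;
      res_rep[resp[i]] += 0.5 * p; res_rep[resp[j]] += 0.5 * p;
    }
  }
  return List::create(_["attractive"] = atr_tot, _["repulsive"] = rep_tot,
                      _["res_attractive"] = res_atr, _["res_repulsive"] = res_rep);
}

namespace {

double subset_lj(const Coords &c, const double *ep, const double *rp,
                 const int *resp, const int *chp, const int *rnp,
                 const std::vector<int> &idx, double cutoff, double switch_on) {
  const double cut2 = cutoff * cutoff;
  const int n = c.n();
  double tot = 0.0;
  for (size_t a = 0; a < idx.size(); ++a) {
    int i = idx[a];
    for (int j = 0; j < n; ++j) {
      if (excluded_pair(resp[i], resp[j], chp[i], chp[j], rnp[i], rnp[j]))
        continue;
      double dx = c.x[i] - c.x[j], dy = c.y[i] - c.y[j], dz = c.z[i] - c.z[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= cut2) continue;
      double r = std::sqrt(d2);
      double e = std::sqrt(ep[i] * ep[j]);
      double rm = rp[i] + rp[j];
      double at, rep;
      lj_pair(r, e, rm, cutoff, switch_on, at, rep);
      tot += at + rep;
    }
  }
  return tot;
}

}  // namespace

// Greedy coordinate descent on chi1 angles. 'movable' is a list of
// lists(side = 0-based atom indices rotated by chi1, ca, cb, restr =
// 0-based indices into the restraint arrays). Harmonic pair restraints
// w * (d - d0)^2 tether the structure to the input coordinates.
// Candidate chi1 offsets are scanned each sweep; sweeps stop when the
// total objective improvement falls below conv_tol.
// [[Rcpp::export(name = ".relax_chi_kernel")]]
List relax_chi_kernel(NumericMatrix xyz_in, NumericVector eps, NumericVector rmin,
                      IntegerVector res, IntegerVector chain, IntegerVector resno,
                      List movable, NumericVector cand,
                      IntegerVector restr_i, IntegerVector restr_j,
                      NumericVector restr_d0, double restr_w,
                      double cutoff, double switch_on,
                      double conv_tol, int max_sweeps) {
  Coords c(xyz_in);
  const int n_mov = movable.size();
  const int *resp = res.begin(), *chp = chain.begin(), *rnp = resno.begin();
  const double *ep = eps.begin(), *rp = rmin.begin();

  std::vector<std::vector<int> > side(n_mov), restr(n_mov);
  std::vector<int> ca(n_mov), cb(n_mov);
  for (int m = 0; m < n_mov; ++m) {
    List mm = movable[m];
    IntegerVector s = mm["side"], rr = mm["restr"];
    side[m] = std::vector<int>(s.begin(), s.end());
    restr[m] = std::vector<int>(rr.begin(), rr.end());
    ca[m] = as<int>(mm["ca"]);
    cb[m] = as<int>(mm["cb"]);
  }

  auto restraint_obj = [&](int m) {
    double tot = 0.0;
    for (size_t k = 0; k < restr[m].size(); ++k) {
      int t = restr[m][k];
      int i = restr_i[t], j = restr_j[t];
      double dx = c.x[i] - c.x[j], dy = c.y[i] - c.y[j], dz = c.z[i] - c.z[j];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - restr_d0[t];
      tot += restr_w * d * d;
    }
    return tot;
  };
  auto local_obj = [&](int m) {
    return subset_lj(c, ep, rp, resp, chp, rnp, side[m], cutoff, switch_on) +
           restraint_obj(m);
  };
  auto rotate_side = [&](int m, const std::vector<double> &kx,
                         const std::vector<double> &ky,
                         const std::vector<double> &kz, double theta) {
    double ax = c.x[cb[m]] - c.x[ca[m]];
    double ay = c.y[cb[m]] - c.y[ca[m]];
    double az = c.z[cb[m]] - c.z[ca[m]];
    double al = std::sqrt(ax * ax + ay * ay + az * az);
    ax /= al; ay /= al; az /= al;
    double ox = c.x[cb[m]], oy = c.y[cb[m]], oz = c.z[cb[m]];
    double ct = std::cos(theta), st = std::sin(theta);
    for (size_t a = 0; a < side[m].size(); ++a) {
      int i = side[m][a];
      double vx = kx[a] - ox, vy = ky[a] - oy, vz = kz[a] - oz;
      double dot = vx * ax + vy * ay + vz * az;
      double cx = ay * vz - az * vy, cy = az * vx - ax * vz,
             cz = ax * vy - ay * vx;
      c.x[i] = ox + vx * ct + cx * st + ax * dot * (1 - ct);
      c.y[i] = oy + vy * ct + cy * st + ay * dot * (1 - ct);
      c.z[i] = oz + vz * ct + cz * st + az * dot * (1 - ct);
    }
  };

  int sweeps = 0;
  for (; sweeps < max_sweeps; ++sweeps) {
    double improved = 0.0;
    for (int m = 0; m < n_mov; ++m) {
      if (side[m].empty()) continue;
      double al2 = 0;
      {
        double ax = c.x[cb[m]] - c.x[ca[m]], ay = c.y[cb[m]] - c.y[ca[m]],
               az = c.z[cb[m]] - c.z[ca[m]];
        al2 = ax * ax + ay * ay + az * az;
      }
      if (al2 < 1e-18) continue;
      std::vector<double> kx, ky, kz;
      for (size_t a = 0; a < side[m].size(); ++a) {
        int i = side[m][a];
        kx.push_back(c.x[i]); ky.push_back(c.y[i]); kz.push_back(c.z[i]);
      }
      double base = local_obj(m);
      double best = base, best_theta = 0.0;
      for (int q = 0; q < cand.size(); ++q) {
        double theta = cand[q] * M_PI / 180.0;
        if (theta == 0.0) continue;
        rotate_side(m, kx, ky, kz, theta);
        double o = local_obj(m);
        if (o < best) { best = o; best_theta = theta; }
      }
      rotate_side(m, kx, ky, kz, best_theta);  // apply best (0 = restore)
      if (best_theta != 0.0) improved += base - best;
    }
    if (improved < conv_tol) { ++sweeps; break; }
  }
  NumericMatrix out(c.n(), 3);
  for (int i = 0; i < c.n(); ++i) {
    out(i, 0) = c.x[i]; out(i, 1) = c.y[i]; out(i, 2) = c.z[i];
  }
  return List::create(_["xyz"] = out, _["sweeps"] = sweeps);
}
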