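// Minimal Lennard-Jones fluid engine with Verlet neighbor lists.
//
// The engine is deliberately small: truncated-and-shifted LJ pair potential,
// velocity-Verlet integration, orthorhombic periodic box, single or dual
// (outer/inner) pair lists, velocity-rescaling thermostat and a Berendsen-type
// box rescaler.  It is instrumented to detect "missed" pair interactions:
// pairs whose minimum-image distance drops below the interaction cutoff r_c
// while they are absent from the pair list used for the force evaluation.
//
// Miss detection uses a shadow list built together with the outer list at a
// cutoff r_l + margin, with margin = safety * 2 * v_max * nstlist * dt.  Any
// pair that can travel from beyond the shadow cutoff to within r_c during one
// list lifetime would have to move faster than safety times the fastest
// particle pair at build time, so the scan over shadow pairs is exhaustive
// for all practical purposes (and exact for free flight).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Pair {
  int i, j;
};

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

inline std::int64_t pair_key(int i, int j) {
  return static_cast<std::int64_t>(i) * 1000000007LL + j;
}

// Brute-force O(N^2) minimum-image pair search within cutoff.
void build_pairs_brute(const std::vector<double>& x, const std::vector<double>& y,
                       const std::vector<double>& z, const double* box,
                       double cutoff, std::vector<Pair>& out) {
  out.clear();
  const int n = static_cast<int>(x.size());
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(x[i] - x[j], box[0]);
      double dy = min_image(y[i] - y[j], box[1]);
      double dz = min_image(z[i] - z[j], box[2]);
      if (dx * dx + dy * dy + dz * dz < c2) out.push_back({i, j});
    }
  }
}

// Cell-list pair search; falls back to brute force when the box holds fewer
// than three cells along any axis (where the half-neighbour stencil would
// double-count periodic images).
void build_pairs_cell(const std::vector<double>& x, const std::vector<double>& y,
                      const std::vector<double>& z, const double* box,
                      double cutoff, std::vector<Pair>& out) {
  const int n = static_cast<int>(x.size());
  int nc[3];
  for (int d = 0; d < 3; ++d) nc[d] = static_cast<int>(std::floor(box[d] / cutoff));
  if (nc[0] < 3 || nc[1] < 3 || nc[2] < 3) {
    build_pairs_brute(x, y, z, box, cutoff, out);
    return;
  }
  const int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), next(n, -1);
  auto cell_of = [&](double px, double py, double pz) {
    int cx = static_cast<int>(std::floor(px / box[0] * nc[0]));
    int cy = static_cast<int>(std::floor(py / box[1] * nc[1]));
    int cz = static_cast<int>(std::floor(pz / box[2] * nc[2]));
    if (cx >= nc[0]) cx = nc[0] - 1; if (cx < 0) cx = 0;
    if (cy >= nc[1]) cy = nc[1] - 1; if (cy < 0) cy = 0;
    if (cz >= nc[2]) cz = nc[2] - 1; if (cz < 0) cz = 0;
    return (cz * nc[1] + cy) * nc[0] + cx;
  };
  for (int i = 0; i < n; ++i) {
    int c = cell_of(x[i], y[i], z[i]);
    next[i] = head[c];
    head[c] = i;
  }
  // half stencil: self + 13 neighbours
  static const int stencil[14][3] = {
    {0, 0, 0}, {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
    {-1, -1, 1}, {0, -1, 1}, {1, -1, 1}, {-1, 0, 1}, {0, 0, 1},
    {1, 0, 1}, {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};
  const double c2 = cutoff * cutoff;
  out.clear();
  for (int cz = 0; cz < nc[2]; ++cz) {
    for (int cy = 0; cy < nc[1]; ++cy) {
      for (int cx = 0; cx < nc[0]; ++cx) {
        int c1 = (cz * nc[1] + cy) * nc[0] + cx;
        for (int s = 0; s < 14; ++s) {
          int ox = (cx + stencil[s][0] + nc[0]) % nc[0];
          int oy = (cy + stencil[s][1] + nc[1]) % nc[1];
          int oz = (cz + stencil[s][2] + nc[2]) % nc[2];
          int c2i = (oz * nc[1] + oy) * nc[0] + ox;
          bool same = (s == 0);
          for (int i = head[c1]; i != -1; i = next[i]) {
            for (int j = same ? next[i] : head[c2i]; j != -1; j = next[j]) {
              double dx = min_image(x[i] - x[j], box[0]);
              double dy = min_image(y[i] - y[j], box[1]);
              double dz = min_image(z[i] - z[j], box[2]);
              if (dx * dx + dy * dy + dz * dz < c2) {
                if (i < j) out.push_back({i, j}); else out.push_back({j, i});
              }
            }
          }
        }
      }
    }
  }
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_build_pairs(NumericMatrix pos, NumericVector box, double cutoff,
                              bool brute) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double b[3] = {box[0], box[1], box[2]};
  std::vector<Pair> pr;
  if (brute) build_pairs_brute(x, y, z, b, cutoff, pr);
  else build_pairs_cell(x, y, z, b, cutoff, pr);
  IntegerMatrix out(static_cast<int>(pr.size()), 2);
  for (size_t k = 0; k < pr.size(); ++k) {
    out(k, 0) = pr[k].i + 1;  // 1-based for R
    out(k, 1) = pr[k].j + 1;
  }
  return out;
}

namespace {

// Truncated-and-shifted LJ force/energy/virial over a pair list.
// Returns potential energy; fills forces and the full virial tensor
// W_ab = sum_pairs r_ab * f_ab.
double eval_forces(const std::vector<double>& x, const std::vector<double>& y,
                   const std::vector<double>& z, const double* box,
                   const std::vector<Pair>& pairs, double eps, double sigma,
                   double rc, std::vector<double>& fx, std::vector<double>& fy,
                   std::vector<double>& fz, double* virial /* 9 */) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  for (int k = 0; k < 9; ++k) virial[k] = 0.0;
  const double rc2 = rc * rc;
  const double s2 = sigma * sigma;
  double sr2c = s2 / rc2, sr6c = sr2c * sr2c * sr2c;
  const double ushift = 4.0 * eps * (sr6c * sr6c - sr6c);
  double epot = 0.0;
  for (const Pair& p : pairs) {
    double dx = min_image(x[p.i] - x[p.j], box[0]);
    double dy = min_image(y[p.i] - y[p.j], box[1]);
    double dz = min_image(z[p.i] - z[p.j], box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
    epot += 4.0 * eps * (sr12 - sr6) - ushift;
    double fr = 24.0 * eps * (2.0 * sr12 - sr6) / r2;  // f / r along r
    double fxx = fr * dx, fyy = fr * dy, fzz = fr * dz;
    fx[p.i] += fxx; fy[p.i] += fyy; fz[p.i] += fzz;
    fx[p.j] -= fxx; fy[p.j] -= fyy; fz[p.j] -= fzz;
    virial[0] += dx * fxx; virial[1] += dx * fyy; virial[2] += dx * fzz;
    virial[3] += dy * fxx; virial[4] += dy * fyy; virial[5] += dy * fzz;
    virial[6] += dz * fxx; virial[7] += dz * fyy; virial[8] += dz * fzz;
  }
  return epot;
}

} // namespace

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericVector box, IntegerMatrix pairs,
                double eps, double sigma, double rc) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double b[3] = {box[0], box[1], box[2]};
  std::vector<Pair> pr(pairs.nrow());
  for (int k = 0; k < pairs.nrow(); ++k) pr[k] = {pairs(k, 0) - 1, pairs(k, 1) - 1};
  double virial[9];
  double epot = eval_forces(x, y, z, b, pr, eps, sigma, rc, fx, fy, fz, virial);
  NumericMatrix f(n, 3), W(3, 3);
  for (int i = 0; i < n; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; f(i, 2) = fz[i]; }
  for (int a = 0; a < 3; ++a)
    for (int c = 0; c < 3; ++c) W(a, c) = virial[a * 3 + c];
  return List::create(_["forces"] = f, _["energy"] = epot, _["virial"] = W);
}

// [[Rcpp::export]]
IntegerMatrix cpp_missing_pairs(NumericMatrix pos, NumericVector box,
                                IntegerMatrix pairs, double rc) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double b[3] = {box[0], box[1], box[2]};
  std::unordered_set<std::int64_t> listed;
  for (int k = 0; k < pairs.nrow(); ++k)
    listed.insert(pair_key(pairs(k, 0) - 1, pairs(k, 1) - 1));
  std::vector<Pair> within;
  build_pairs_brute(x, y, z, b, rc, within);
  std::vector<Pair> missing;
  for (const Pair& p : within)
    if (!listed.count(pair_key(p.i, p.j))) missing.push_back(p);
  IntegerMatrix out(static_cast<int>(missing.size()), 2);
  for (size_t k = 0; k < missing.size(); ++k) {
    out(k, 0) = missing[k].i + 1;
    out(k, 1) = missing[k].j + 1;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos0, NumericMatrix vel0, NumericVector box0,
                NumericVector mass, double eps, double sigma, double rc,
                double rl, int nstlist, bool dual, double r_inner,
                int nstlist_inner, double dt, int n_steps,
                int thermo_mode, double thermo_T, int thermo_interval,
                int baro_mode, double baro_tau, double baro_target,
                double baro_kappa, int baro_interval,
                double kB, double pfac, bool forces_on, bool count_misses,
                double miss_safety) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<double> fx(n), fy(n), fz(n), m(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
    m[i] = mass[i];
  }
  double box[3] = {box0[0], box0[1], box0[2]};

  const int nrec = n_steps + 1;
  NumericMatrix pdiag(nrec, 3), kdiag(nrec, 3), wdiag(nrec, 3), boxrec(nrec, 3);
  NumericVector epot_rec(nrec), ekin_rec(nrec), psca(nrec);
  IntegerVector steprec(nrec);

  std::vector<Pair> outer, shadow, active, candidates;
  std::vector<int> cand_state;  // 1 if already counted unique this lifetime
  std::unordered_set<std::int64_t> outer_keys, inner_keys;

  std::vector<int> miss_build_step;
  std::vector<int> miss_unique, miss_events;
  int cur_unique = 0, cur_events = 0, cur_build = 0;

  double virial[9];
  double epot = 0.0;

  auto wrap_all = [&]() {
    for (int i = 0; i < n; ++i) {
      x[i] -= box[0] * std::floor(x[i] / box[0]);
      y[i] -= box[1] * std::floor(y[i] / box[1]);
      z[i] -= box[2] * std::floor(z[i] / box[2]);
    }
  };

  auto vmax = [&]() {
    double v2m = 0.0;
    for (int i = 0; i < n; ++i) {
      double v2 = vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      if (v2 > v2m) v2m = v2;
    }
    return std::sqrt(v2m);
  };

  auto rebuild_candidates = [&]() {
    // pairs absent from the active (force) list that could reach r_c:
    // shadow pairs beyond r_l at outer build, plus (dual mode) outer pairs
    // currently outside the inner list.
    candidates.clear();
    for (const Pair& p : shadow)
      if (!outer_keys.count(pair_key(p.i, p.j))) candidates.push_back(p);
    if (dual) {
      for (const Pair& p : outer)
        if (!inner_keys.count(pair_key(p.i, p.j))) candidates.push_back(p);
    }
  };

  std::unordered_set<std::int64_t> unique_seen;

  auto build_outer = [&](int step) {
    build_pairs_cell(x, y, z, box, rl, outer);
    outer_keys.clear();
    for (const Pair& p : outer) outer_keys.insert(pair_key(p.i, p.j));
    if (count_misses) {
      double margin = miss_safety * 2.0 * vmax() * nstlist * dt;
      double rshadow = rl + margin;
      double halfmin = 0.499 * std::min(box[0], std::min(box[1], box[2]));
      if (rshadow > halfmin) rshadow = halfmin;
      build_pairs_cell(x, y, z, box, rshadow, shadow);
      unique_seen.clear();
      cur_unique = 0; cur_events = 0; cur_build = step;
    }
  };

  auto build_inner = [&]() {
    active.clear();
    inner_keys.clear();
    if (r_inner >= rl) {  // degenerate dual list: keep the full outer pool
      active = outer;
      inner_keys = outer_keys;
      return;
    }
    const double ri2 = r_inner * r_inner;
    for (const Pair& p : outer) {
      double dx = min_image(x[p.i] - x[p.j], box[0]);
      double dy = min_image(y[p.i] - y[p.j], box[1]);
      double dz = min_image(z[p.i] - z[p.j], box[2]);
      if (dx * dx + dy * dy + dz * dz < ri2) {
        active.push_back(p);
        inner_keys.insert(pair_key(p.i, p.j));
      }
    }
  };

  auto flush_misses = [&]() {
    if (!count_misses) return;
    miss_build_step.push_back(cur_build);
    miss_unique.push_back(cur_unique);
    miss_events.push_back(cur_events);
  };

  auto scan_misses = [&]() {
    if (!count_misses) return;
    const double rc2 = rc * rc;
    for (const Pair& p : candidates) {
      double dx = min_image(x[p.i] - x[p.j], box[0]);
      double dy = min_image(y[p.i] - y[p.j], box[1]);
      double dz = min_image(z[p.i] - z[p.j], box[2]);
      if (dx * dx + dy * dy + dz * dz < rc2) {
        ++cur_events;
        std::int64_t key = pair_key(p.i, p.j);
        if (!unique_seen.count(key)) { unique_seen.insert(key); ++cur_unique; }
      }
    }
  };

  auto record = [&](int idx, int step) {
    double kxx = 0, kyy = 0, kzz = 0, ekin = 0;
    for (int i = 0; i < n; ++i) {
      kxx += m[i] * vx[i] * vx[i];
      kyy += m[i] * vy[i] * vy[i];
      kzz += m[i] * vz[i] * vz[i];
    }
    ekin = 0.5 * (kxx + kyy + kzz);
    double V = box[0] * box[1] * box[2];
    double pxx = (kxx + virial[0]) / V * pfac;
    double pyy = (kyy + virial[4]) / V * pfac;
    double pzz = (kzz + virial[8]) / V * pfac;
    steprec[idx] = step;
    pdiag(idx, 0) = pxx; pdiag(idx, 1) = pyy; pdiag(idx, 2) = pzz;
    kdiag(idx, 0) = kxx / V * pfac; kdiag(idx, 1) = kyy / V * pfac;
    kdiag(idx, 2) = kzz / V * pfac;
    wdiag(idx, 0) = virial[0] / V * pfac; wdiag(idx, 1) = virial[4] / V * pfac;
    wdiag(idx, 2) = virial[8] / V * pfac;
    boxrec(idx, 0) = box[0]; boxrec(idx, 1) = box[1]; boxrec(idx, 2) = box[2];
    epot_rec[idx] = epot; ekin_rec[idx] = ekin;
    psca[idx] = (pxx + pyy + pzz) / 3.0;
  };

  // initial build + force evaluation at step 0
  wrap_all();
  if (2.0 * rl >= std::min(box[0], std::min(box[1], box[2])))
    stop("box lengths must exceed 2*r_l for minimum-image validity");
  build_outer(0);
  if (dual) build_inner();
  const std::vector<Pair>& force_list = dual ? active : outer;
  rebuild_candidates();
  if (forces_on)
    epot = eval_forces(x, y, z, box, force_list, eps, sigma, rc, fx, fy, fz, virial);
  else {
    std::fill(fx.begin(), fx.end(), 0.0); std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int k = 0; k < 9; ++k) virial[k] = 0.0;
    epot = 0.0;
  }
  record(0, 0);

  const int ndof = 3 * n - 3;

  for (int t = 1; t <= n_steps; ++t) {
    // velocity Verlet
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / m[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
      x[i] += dt * vx[i]; y[i] += dt * vy[i]; z[i] += dt * vz[i];
    }
    wrap_all();

    if (t % nstlist == 0) {
      flush_misses();
      build_outer(t);
      if (dual) build_inner();
      rebuild_candidates();
    } else if (dual && t % nstlist_inner == 0) {
      build_inner();
      rebuild_candidates();
      scan_misses();  // fresh inner list cannot miss, but shadow-only pairs can
    } else {
      scan_misses();
    }

    if (forces_on)
      epot = eval_forces(x, y, z, box, dual ? active : outer, eps, sigma, rc,
                         fx, fy, fz, virial);
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / m[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
    }

    record(t, t);

    if (!std::isfinite(epot_rec[t]) || !std::isfinite(ekin_rec[t]))
      stop("simulation diverged (non-finite energy) at step %d", t);

    if (thermo_mode == 1 && t % thermo_interval == 0) {
      double ek = ekin_rec[t];
      double Tinst = 2.0 * ek / (ndof * kB);
      if (Tinst > 0) {
        double lam = std::sqrt(thermo_T / Tinst);
        for (int i = 0; i < n; ++i) { vx[i] *= lam; vy[i] *= lam; vz[i] *= lam; }
      }
    }

    if (baro_mode != 0 && t % baro_interval == 0) {
      double dtc = baro_interval * dt;
      double mu[3];
      double pxx = pdiag(t, 0), pyy = pdiag(t, 1), pzz = pdiag(t, 2);
      auto mu_of = [&](double P) {
        return std::cbrt(1.0 - dtc * baro_kappa / baro_tau * (baro_target - P));
      };
      if (baro_mode == 1) {  // isotropic
        double mall = mu_of((pxx + pyy + pzz) / 3.0);
        mu[0] = mu[1] = mu[2] = mall;
      } else if (baro_mode == 2) {  // semi-isotropic: (x,y) joint, z separate
        double mxy = mu_of(0.5 * (pxx + pyy));
        mu[0] = mu[1] = mxy;
        mu[2] = mu_of(pzz);
      } else {  // anisotropic
        mu[0] = mu_of(pxx); mu[1] = mu_of(pyy); mu[2] = mu_of(pzz);
      }
      for (int d = 0; d < 3; ++d) box[d] *= mu[d];
      for (int i = 0; i < n; ++i) { x[i] *= mu[0]; y[i] *= mu[1]; z[i] *= mu[2]; }
      if (2.0 * rl >= std::min(box[0], std::min(box[1], box[2])))
        stop("barostat shrank the box below 2*r_l at step %d", t);
      boxrec(t, 0) = box[0]; boxrec(t, 1) = box[1]; boxrec(t, 2) = box[2];
    }
  }
  flush_misses();

  NumericMatrix posF(n, 3), velF(n, 3);
  for (int i = 0; i < n; ++i) {
    posF(i, 0) = x[i]; posF(i, 1) = y[i]; posF(i, 2) = z[i];
    velF(i, 0) = vx[i]; velF(i, 1) = vy[i]; velF(i, 2) = vz[i];
  }
  return List::create(
      _["step"] = steprec, _["pdiag"] = pdiag, _["kdiag"] = kdiag,
      _["wdiag"] = wdiag, _["p_scalar"] = psca, _["epot"] = epot_rec,
      _["ekin"] = ekin_rec, _["box"] = boxrec,
      _["miss_build_step"] = wrap(miss_build_step),
      _["miss_unique"] = wrap(miss_unique), _["miss_events"] = wrap(miss_events),
      _["pos"] = posF, _["vel"] = velF,
      _["box_final"] = NumericVector::create(box[0], box[1], box[2]));
}
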