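#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Lattice layout: R column-major array, idx = i + nx*(j + ny*k), 0-based.
// Entity ids: 0 = medium, >=1 indexed into entity_type / target_vol /
// vol_lambda / frozen (position id). Types: 0 medium, 1 alpha, 2 beta,
// 3 delta, 4 capillary.

namespace {

struct Offsets {
  std::vector<int> di, dj, dk;
};

// Full neighbor set for the boundary-energy term. Order 1: the 6 face
// neighbors; order 2: 18 neighbors (faces + edges, corners excluded).
Offsets energy_offsets(int order) {
  Offsets o;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (order == 1 && m > 1) continue;
        if (order == 2 && m > 2) continue;
        o.di.push_back(di); o.dj.push_back(dj); o.dk.push_back(dk);
      }
  return o;
}

// Half set (each unordered pair counted once) for total-energy sums.
Offsets half_offsets(int order) {
  Offsets full = energy_offsets(order), h;
  for (size_t t = 0; t < full.di.size(); ++t) {
    int di = full.di[t], dj = full.dj[t], dk = full.dk[t];
    if (dk > 0 || (dk == 0 && dj > 0) || (dk == 0 && dj == 0 && di > 0)) {
      h.di.push_back(di); h.dj.push_back(dj); h.dk.push_back(dk);
    }
  }
  return h;
}

inline int type_of(const int *et, int id) { return id == 0 ? 0 : et[id - 1]; }

} // namespace

// [[Rcpp::export]]
NumericVector cpm_entity_volumes_cpp(IntegerVector lattice, int n_entities) {
  NumericVector vol(n_entities);
  for (R_xlen_t s = 0; s < lattice.size(); ++s) {
    int id = lattice[s];
    if (id > 0 && id <= n_entities) vol[id - 1] += 1.0;
  }
  return vol;
}

// [[Rcpp::export]]
double cpm_total_energy_cpp(IntegerVector lattice, IntegerVector dims,
                            IntegerVector entity_type, NumericVector target_vol,
                            NumericVector vol_lambda, LogicalVector frozen,
                            NumericMatrix J, int neighbor_order) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *lat = INTEGER(lattice);
  const int *et = INTEGER(entity_type);
  Offsets off = half_offsets(neighbor_order);
  const int noff = (int)off.di.size();
  double H = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int idx = i + nx * (j + ny * k);
        const int id1 = lat[idx];
        const int t1 = type_of(et, id1);
        for (int t = 0; t < noff; ++t) {
          const int i2 = i + off.di[t], j2 = j + off.dj[t], k2 = k + off.dk[t];
          if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
            continue; // free boundary: sites outside contribute nothing
          const int id2 = lat[i2 + nx * (j2 + ny * k2)];
          if (id2 != id1) H += J(t1, type_of(et, id2));
        }
      }
  const int n_ent = entity_type.size();
  NumericVector vol = cpm_entity_volumes_cpp(lattice, n_ent);
  for (int e = 0; e < n_ent; ++e) {
    if (frozen[e] || target_vol[e] < 0) continue;
    const double d = vol[e] - target_vol[e];
    H += vol_lambda[e] * d * d;
  }
  return H;
}

namespace {

// Energy change of copying entity `new_id` into `site_idx`.
double delta_H(const int *lat, int nx, int ny, int nz, int si, int sj, int sk,
               int new_id, const int *et, const double *tv, const double *vl,
               const int *frz, const double *vol, const Offsets &off,
               const NumericMatrix &J) {
  const int idx = si + nx * (sj + ny * sk);
  const int old_id = lat[idx];
  const int t_old = type_of(et, old_id), t_new = type_of(et, new_id);
  double before = 0.0, after = 0.0;
  const int noff = (int)off.di.size();
  for (int t = 0; t < noff; ++t) {
    const int i2 = si + off.di[t], j2 = sj + off.dj[t], k2 = sk + off.dk[t];
    if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
      continue;
    const int id2 = lat[i2 + nx * (j2 + ny * k2)];
    const int t2 = type_of(et, id2);
    if (id2 != old_id) before += J(t_old, t2);
    if (id2 != new_id) after += J(t_new, t2);
  }
  double dH = after - before;
  if (old_id > 0 && tv[old_id - 1] >= 0 && !frz[old_id - 1]) {
    const double d = vol[old_id - 1] - tv[old_id - 1];
    dH += vl[old_id - 1] * ((d - 1.0) * (d - 1.0) - d * d);
  }
  if (new_id > 0 && tv[new_id - 1] >= 0 && !frz[new_id - 1]) {
    const double d = vol[new_id - 1] - tv[new_id - 1];
    dH += vl[new_id - 1] * ((d + 1.0) * (d + 1.0) - d * d);
  }
  return dH;
}

} // namespace

// Single copy attempt at a caller-chosen (site, neighbor) pair; randomness is
// used only for the Metropolis acceptance draw. Returns the updated lattice
// and volumes so the caller keeps R copy semantics.
// [[Rcpp::export]]
List cpm_attempt_copy_cpp(IntegerVector lattice, IntegerVector dims,
                          IntegerVector entity_type, NumericVector target_vol,
                          NumericVector vol_lambda, LogicalVector frozen,
                          NumericMatrix J, int neighbor_order, double temperature,
                          IntegerVector site, IntegerVector neighbor,
                          NumericVector volumes) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lat = clone(lattice);
  NumericVector vol = clone(volumes);
  const int *et = INTEGER(entity_type);
  const int si = site[0], sj = site[1], sk = site[2];
  const int ni = neighbor[0], nj = neighbor[1], nk = neighbor[2];
  const int sidx = si + nx * (sj + ny * sk);
  const int nidx = ni + nx * (nj + ny * nk);
  const int old_id = lat[sidx], new_id = lat[nidx];
  bool accepted = false;
  double dH = NA_REAL;
  bool frozen_block =
      (old_id > 0 && frozen[old_id - 1]) || (new_id > 0 && frozen[new_id - 1]);
  if (!frozen_block && old_id != new_id) {
    Offsets off = energy_offsets(neighbor_order);
    dH = delta_H(INTEGER(lat), nx, ny, nz, si, sj, sk, new_id, et,
                 REAL(target_vol), REAL(vol_lambda), LOGICAL(frozen),
                 REAL(vol), off, J);
    accepted = (dH <= 0.0) || (unif_rand() < std::exp(-dH / temperature));
    if (accepted) {
      lat[sidx] = new_id;
      if (old_id > 0) vol[old_id - 1] -= 1.0;
      if (new_id > 0) vol[new_id - 1] += 1.0;
    }
  } else if (!frozen_block && old_id == new_id) {
    dH = 0.0;
    accepted = true; // no-op copy of an identical id
  }
  return List::create(_["accepted"] = accepted, _["delta_H"] = dH,
                      _["frozen_rejected"] = frozen_block,
                      _["lattice"] = lat, _["volumes"] = vol);
}

// Metropolis evolution: one Monte Carlo step = as many copy attempts as
// lattice sites. Incremental energy bookkeeping is cross-checked against a
// full recomputation at checkpoints.
// [[Rcpp::export]]
List cpm_evolve_cpp(IntegerVector lattice, IntegerVector dims,
                    IntegerVector entity_type, NumericVector target_vol,
                    NumericVector vol_lambda, LogicalVector frozen,
                    NumericMatrix J, int neighbor_order, double temperature,
                    int n_mcs, int checkpoint_every) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n_sites = (R_xlen_t)nx * ny * nz;
  IntegerVector lat = clone(lattice);
  int *latp = INTEGER(lat);
  const int *et = INTEGER(entity_type);
  const double *tv = REAL(target_vol), *vl = REAL(vol_lambda);
  const int *frz = LOGICAL(frozen);
  const int n_ent = entity_type.size();
  NumericVector volR = cpm_entity_volumes_cpp(lat, n_ent);
  double *vol = REAL(volR);
  Offsets off = energy_offsets(neighbor_order);

  double H = cpm_total_energy_cpp(lat, dims, entity_type, target_vol,
                                  vol_lambda, frozen, J, neighbor_order);
  NumericVector H_trace(n_mcs);
  std::vector<double> H_incr, H_full;
  double n_attempt = 0.0, n_accept = 0.0;
  static const int ndi[6] = {1, -1, 0, 0, 0, 0};
  static const int ndj[6] = {0, 0, 1, -1, 0, 0};
  static const int ndk[6] = {0, 0, 0, 0, 1, -1};

  for (int mcs = 1; mcs <= n_mcs; ++mcs) {
    for (R_xlen_t a = 0; a < n_sites; ++a) {
      R_xlen_t idx = (R_xlen_t)(unif_rand() * n_sites);
      if (idx >= n_sites) idx = n_sites - 1;
      int d = (int)(unif_rand() * 6.0);
      if (d >= 6) d = 5;
      const int si = (int)(idx % nx);
      const int sj = (int)((idx / nx) % ny);
      const int sk = (int)(idx / ((R_xlen_t)nx * ny));
      const int ni = si + ndi[d], nj = sj + ndj[d], nk = sk + ndk[d];
      n_attempt += 1.0;
      if (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0 || nk >= nz)
        continue;
      const int new_id = latp[ni + nx * ((R_xlen_t)nj + (R_xlen_t)ny * nk)];
      const int old_id = latp[idx];
      if (new_id == old_id) continue;
      if ((old_id > 0 && frz[old_id - 1]) || (new_id > 0 && frz[new_id - 1]))
        continue;
      const double dH = delta_H(latp, nx, ny, nz, si, sj, sk, new_id, et, tv,
                                vl, frz, vol, off, J);
      if (dH <= 0.0 || unif_rand() < std::exp(-dH / temperature)) {
        latp[idx] = new_id;
        if (old_id > 0) vol[old_id - 1] -= 1.0;
        if (new_id > 0) vol[new_id - 1] += 1.0;
        H += dH;
        n_accept += 1.0;
      }
    }
    H_trace[mcs - 1] = H;
    if (checkpoint_every > 0 &&
        (mcs % checkpoint_every == 0 || mcs == n_mcs)) {
      H_incr.push_back(H);
      H_full.push_back(cpm_total_energy_cpp(lat, dims, entity_type, target_vol,
                                            vol_lambda, frozen, J,
                                            neighbor_order));
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["lattice"] = lat, _["volumes"] = volR,
                      _["H_trace"] = H_trace,
                      _["H_incremental"] = wrap(H_incr),
                      _["H_recomputed"] = wrap(H_full),
                      _["acceptance_rate"] =
                          n_attempt > 0 ? n_accept / n_attempt : NA_REAL);
}
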