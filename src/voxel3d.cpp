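#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// 3D grids come in as R arrays with dim = c(nz, ny, nx); the 0-based linear
// index is i = z + nz*(y + ny*x).  All neighbourhood work honours the array
// bounds; nothing here knows about physical voxel size (callers convert to
// micrometres).

namespace {

struct Nbhd {
  std::vector<int> dz, dy, dx;
  explicit Nbhd(int conn) {
    for (int x = -1; x <= 1; ++x)
      for (int y = -1; y <= 1; ++y)
        for (int z = -1; z <= 1; ++z) {
          int m = std::abs(x) + std::abs(y) + std::abs(z);
          if (m == 0) continue;
          if (conn == 6 && m != 1) continue;
          dz.push_back(z); dy.push_back(y); dx.push_back(x);
        }
  }
  int size() const { return static_cast<int>(dz.size()); }
};

inline void decode(int i, int nz, int ny, int &z, int &y, int &x) {
  z = i % nz;
  int r = i / nz;
  y = r % ny;
  x = r / ny;
}

}  // namespace

// Connected-component labelling of a binary 3D grid.  Components are
// numbered 1..n in order of their first voxel in linear scan order, which
// makes the labelling deterministic.
// [[Rcpp::export]]
IntegerVector cc_label3d_cpp(LogicalVector mask, IntegerVector dims,
                             int connectivity = 26) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  Nbhd nb(connectivity);
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int j = stack.back(); stack.pop_back();
      int z, y, x; decode(j, nz, ny, z, y, x);
      for (int t = 0; t < nb.size(); ++t) {
        int zz = z + nb.dz[t], yy = y + nb.dy[t], xx = x + nb.dx[t];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int k = zz + nz * (yy + ny * xx);
        if (mask[k] && !lab[k]) { lab[k] = cur; stack.push_back(k); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Regional maxima with a noise-tolerance (prominence) h, in the spirit of
// the classic find-maxima flood: candidates are visited in descending
// intensity; from each one a flood over voxels >= v - h is run and the
// candidate is kept only if the flood never reaches a strictly higher voxel.
// Voxels claimed by an accepted maximum cannot seed further maxima.  Only
// candidates with intensity >= floor are considered (detection limit).
// Returns 1-based linear indices, ordered by descending intensity.
// [[Rcpp::export]]
IntegerVector find_maxima3d_cpp(NumericVector img, LogicalVector mask,
                                IntegerVector dims, double h,
                                double floor_level) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  Nbhd nb(26);

  std::vector<int> cand;
  cand.reserve(1024);
  for (int i = 0; i < n; ++i)
    if (mask[i] && img[i] >= floor_level) cand.push_back(i);
  std::stable_sort(cand.begin(), cand.end(), [&](int a, int b) {
    if (img[a] != img[b]) return img[a] > img[b];
    return a < b;
  });

  std::vector<char> claimed(n, 0);
  std::vector<int> stamp(n, -1);
  std::vector<int> flood;
  std::vector<int> accepted;

  for (size_t ci = 0; ci < cand.size(); ++ci) {
    int c = cand[ci];
    if (claimed[c]) continue;
    const double vc = img[c];
    bool dominated = false;
    flood.clear();
    flood.push_back(c);
    stamp[c] = c;
    for (size_t qi = 0; qi < flood.size() && !dominated; ++qi) {
      int j = flood[qi];
      int z, y, x; decode(j, nz, ny, z, y, x);
      for (int t = 0; t < nb.size(); ++t) {
        int zz = z + nb.dz[t], yy = y + nb.dy[t], xx = x + nb.dx[t];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int k = zz + nz * (yy + ny * xx);
        if (!mask[k]) continue;
        if (img[k] > vc) { dominated = true; break; }
        if (img[k] >= vc - h && stamp[k] != c) {
          stamp[k] = c;
          flood.push_back(k);
        }
      }
    }
    if (!dominated) {
      accepted.push_back(c);
      for (size_t qi = 0; qi < flood.size(); ++qi) claimed[flood[qi]] = 1;
    } else {
      claimed[c] = 1;
    }
  }

  IntegerVector out(accepted.size());
  for (size_t i = 0; i < accepted.size(); ++i) out[i] = accepted[i] + 1;
  return out;
}

// Union of per-seed 26-connected regions grown over voxels >= the seed's own
// threshold.  seeds are 1-based linear indices.
// [[Rcpp::export]]
LogicalVector grow_seeds3d_cpp(NumericVector img, LogicalVector mask,
                               IntegerVector dims, IntegerVector seeds,
                               NumericVector thresholds) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  Nbhd nb(26);
  LogicalVector grown(n, false);
  std::vector<int> stamp(n, -1);
  std::vector<int> stack;

  for (int s = 0; s < seeds.size(); ++s) {
    int seed = seeds[s] - 1;
    double thr = thresholds[s];
    if (!mask[seed] || img[seed] < thr) continue;
    stack.clear();
    stack.push_back(seed);
    stamp[seed] = s;
    grown[seed] = true;
    while (!stack.empty()) {
      int j = stack.back(); stack.pop_back();
      int z, y, x; decode(j, nz, ny, z, y, x);
      for (int t = 0; t < nb.size(); ++t) {
        int zz = z + nb.dz[t], yy = y + nb.dy[t], xx = x + nb.dx[t];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int k = zz + nz * (yy + ny * xx);
        if (!mask[k] || stamp[k] == s || img[k] < thr) continue;
        stamp[k] = s;
        grown[k] = true;
        stack.push_back(k);
      }
    }
  }
  grown.attr("dim") = dims;
  return grown;
}

namespace {

struct PQItem {
  double value;
  long order;
  int idx;
  int label;
};

struct PQLess {
  bool operator()(const PQItem &a, const PQItem &b) const {
    if (a.value != b.value) return a.value < b.value;  // max-heap on value
    return a.order > b.order;                          // FIFO on ties
  }
};

}  // namespace

// Marker-based watershed by priority flooding: seeds are pushed with their
// intensity and the region is flooded in order of descending intensity, so
// each voxel joins the catchment basin of the seed that reaches it along the
// highest-intensity path.  Returns a label grid (0 outside `region`).
// [[Rcpp::export]]
IntegerVector marker_watershed3d_cpp(NumericVector img, LogicalVector region,
                                     IntegerVector dims, IntegerVector seeds) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  Nbhd nb(26);
  IntegerVector lab(n, 0);
  std::priority_queue<PQItem, std::vector<PQItem>, PQLess> pq;
  long counter = 0;

  for (int s = 0; s < seeds.size(); ++s) {
    int seed = seeds[s] - 1;
    if (!region[seed] || lab[seed]) continue;
    lab[seed] = s + 1;
    pq.push(PQItem{img[seed], counter++, seed, s + 1});
  }
  while (!pq.empty()) {
    PQItem it = pq.top(); pq.pop();
    int z, y, x; decode(it.idx, nz, ny, z, y, x);
    for (int t = 0; t < nb.size(); ++t) {
      int zz = z + nb.dz[t], yy = y + nb.dy[t], xx = x + nb.dx[t];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int k = zz + nz * (yy + ny * xx);
      if (!region[k] || lab[k]) continue;
      lab[k] = it.label;
      pq.push(PQItem{img[k], counter++, k, it.label});
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// One full sequential ICM sweep for a Gaussian-emission Potts model on the
// 6-neighbourhood; labels are 1..K inside the mask and 0 outside.  Updated
// labels are used immediately within the sweep (standard ICM), which is
// deterministic.  Returns the new labels and the number of changed voxels.
// [[Rcpp::export]]
List icm_sweep3d_cpp(NumericVector img, IntegerVector labels,
                     IntegerVector dims, int K, NumericVector mu,
                     NumericVector sigma, double beta) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  Nbhd nb(6);
  IntegerVector lab = clone(labels);
  std::vector<double> logsig(K), inv2var(K);
  for (int k = 0; k < K; ++k) {
    double s = std::max(sigma[k], 1e-12);
    logsig[k] = std::log(s);
    inv2var[k] = 1.0 / (2.0 * s * s);
  }
  int changed = 0;
  std::vector<int> cnt(K);
  for (int i = 0; i < n; ++i) {
    if (lab[i] == 0) continue;
    std::fill(cnt.begin(), cnt.end(), 0);
    int z, y, x; decode(i, nz, ny, z, y, x);
    for (int t = 0; t < nb.size(); ++t) {
      int zz = z + nb.dz[t], yy = y + nb.dy[t], xx = x + nb.dx[t];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int k = zz + nz * (yy + ny * xx);
      if (lab[k] > 0) cnt[lab[k] - 1]++;
    }
    int best = 0;
    double bestcost = R_PosInf;
    for (int k = 0; k < K; ++k) {
      double d = img[i] - mu[k];
      double cost = d * d * inv2var[k] + logsig[k] - beta * cnt[k];
      if (cost < bestcost) { bestcost = cost; best = k; }
    }
    if (best + 1 != lab[i]) { lab[i] = best + 1; ++changed; }
  }
  lab.attr("dim") = dims;
  return List::create(_["labels"] = lab, _["changed"] = changed);
}

// Gibbs sampling of a K-state Potts model on the 6-neighbourhood, sequential
// scan, `sweeps` full passes.  Uses R's RNG so set.seed() controls the draw.
// labels: 1..K inside the mask, 0 outside (fixed).
// [[Rcpp::export]]
IntegerVector gibbs_potts3d_cpp(IntegerVector labels, IntegerVector dims,
                                int K, double beta, int sweeps) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  Nbhd nb(6);
  IntegerVector lab = clone(labels);
  std::vector<int> cnt(K);
  std::vector<double> w(K);
  for (int sw = 0; sw < sweeps; ++sw) {
    for (int i = 0; i < n; ++i) {
      if (lab[i] == 0) continue;
      std::fill(cnt.begin(), cnt.end(), 0);
      int z, y, x; decode(i, nz, ny, z, y, x);
      for (int t = 0; t < nb.size(); ++t) {
        int zz = z + nb.dz[t], yy = y + nb.dy[t], xx = x + nb.dx[t];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int k = zz + nz * (yy + ny * xx);
        if (lab[k] > 0) cnt[lab[k] - 1]++;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { w[k] = std::exp(beta * cnt[k]); tot += w[k]; }
      double u = unif_rand() * tot;
      int pick = K - 1;
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        acc += w[k];
        if (u <= acc) { pick = k; break; }
      }
      lab[i] = pick + 1;
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
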