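// Low-level voxel-grid primitives: 26-connectivity component labeling,
// boundary-contact extraction, exact Euclidean distance transform, and
// geodesic (Dijkstra) path lengths restricted to a voxel set.
// All linear indices crossing the R boundary are 1-based, column-major,
// axis order (x, y, z) with z the beam axis.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_map>
#include <limits>
#include <cmath>
using namespace Rcpp;

static inline void idx2xyz(R_xlen_t idx, int nx, int ny, int &x, int &y, int &z) {
  x = (int)(idx % nx);
  y = (int)((idx / nx) % ny);
  z = (int)(idx / ((R_xlen_t)nx * ny));
}

// 26-neighbour offsets (dx, dy, dz), excluding (0,0,0)
static void neighbour_offsets(std::vector<std::array<int,3>> &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dx || dy || dz) off.push_back({dx, dy, dz});
}

// Label 26-connected components of a logical mask. Returns integer vector
// (same length), 0 = background, components numbered 1..n in first-voxel
// (raster) order, which makes labeling deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_mask(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> off;
  neighbour_offsets(off);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x, y, z; idx2xyz(cur, nx, ny, x, y, z);
      for (const auto &d : off) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// For every component voxel 26-adjacent to a nonzero label (boundary) voxel,
// emit one row (component id, boundary id, 1-based voxel index). Rows are
// deduplicated and ordered by (component, boundary, voxel).
// [[Rcpp::export]]
DataFrame cpp_component_contacts(IntegerVector complab, IntegerVector labels,
                                 IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (complab.size() != n || labels.size() != n) stop("length mismatch");
  std::vector<std::array<int,3>> off;
  neighbour_offsets(off);
  std::vector<int> comp_out, bnd_out;
  std::vector<double> vox_out;
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = complab[i];
    if (c == 0) continue;
    int x, y, z; idx2xyz(i, nx, ny, x, y, z);
    // collect distinct boundary ids touched from this voxel
    std::vector<int> seen;
    for (const auto &d : off) {
      int xx = x + d[0], yy = y + d[1], zz = z + d[2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
      int b = labels[j];
      if (b == 0) continue;
      bool dup = false;
      for (int s : seen) if (s == b) { dup = true; break; }
      if (!dup) {
        seen.push_back(b);
        comp_out.push_back(c);
        bnd_out.push_back(b);
        vox_out.push_back((double)(i + 1));
      }
    }
  }
  return DataFrame::create(_["component"] = comp_out,
                           _["boundary"] = bnd_out,
                           _["voxel"] = vox_out);
}

// ---- exact Euclidean distance transform (squared), separable lower
// envelope (Felzenszwalb & Huttenlocher) ------------------------------
// `f` uses a large finite sentinel for "no seed" so the envelope stays
// well-defined (the classic FH caveat with true infinities).
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0; zz[0] = -INF; zz[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= zz[k] && k > 0) { --k; } else break;
    }
    if (s <= zz[k]) { v[k] = q; zz[k + 1] = INF; }
    else { ++k; v[k] = q; zz[k] = s; zz[k + 1] = INF; }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (in voxel units) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims) {
  static const double INF = 1e18;   // finite sentinel, see dt1d
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = g[base + x]; if (f[x] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nx);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      bool any = false;
      for (int y = 0; y < ny; ++y) { f[y] = g[base + (R_xlen_t)y * nx]; if (f[y] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, ny);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      bool any = false;
      for (int z = 0; z < nz; ++z) { f[z] = g[base + (R_xlen_t)z * nx * ny]; if (f[z] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nz);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nx * ny] = d[z];
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// ---- geodesics within a voxel set -----------------------------------
// Dijkstra over the 26-neighbour graph restricted to `voxels` (1-based
// linear indices), Euclidean step weights (1, sqrt2, sqrt3 voxels).
struct Geo {
  int nx, ny, nz;
  std::unordered_map<R_xlen_t, int> loc;        // linear idx -> local id
  std::vector<R_xlen_t> vox;                    // local id -> linear idx
  std::vector<std::array<int,3>> off;
  std::vector<double> w;
  Geo(NumericVector voxels, IntegerVector dims) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    vox.reserve(voxels.size());
    for (R_xlen_t k = 0; k < voxels.size(); ++k) {
      R_xlen_t i = (R_xlen_t)voxels[k] - 1;
      loc[i] = (int)vox.size();
      vox.push_back(i);
    }
    neighbour_offsets(off);
    w.resize(off.size());
    for (size_t a = 0; a < off.size(); ++a)
      w[a] = std::sqrt((double)(off[a][0]*off[a][0] + off[a][1]*off[a][1] + off[a][2]*off[a][2]));
  }
  // single/multi-source Dijkstra; returns distances to all member voxels
  std::vector<double> run(const std::vector<int> &sources) const {
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<double> dist(vox.size(), INF);
    typedef std::pair<double, int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
    for (int s : sources) { dist[s] = 0.0; pq.push({0.0, s}); }
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      double dcur = top.first; int u = top.second;
      if (dcur > dist[u]) continue;
      int x, y, z; idx2xyz(vox[u], nx, ny, x, y, z);
      for (size_t a = 0; a < off.size(); ++a) {
        int xx = x + off[a][0], yy = y + off[a][1], zz = z + off[a][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        auto it = loc.find(j);
        if (it == loc.end()) continue;
        double nd = dcur + w[a];
        if (nd < dist[it->second]) { dist[it->second] = nd; pq.push({nd, it->second}); }
      }
    }
    return dist;
  }
};

static std::vector<int> local_ids(const Geo &g, NumericVector v) {
  std::vector<int> out;
  for (R_xlen_t k = 0; k < v.size(); ++k) {
    auto it = g.loc.find((R_xlen_t)v[k] - 1);
    if (it == g.loc.end()) stop("source/target voxel not in the voxel set");
    out.push_back(it->second);
  }
  return out;
}

// Minimal geodesic length (voxel units) between any src and any dst voxel.
// Returns Inf if disconnected within the set.
// [[Rcpp::export]]
double cpp_geodesic_min(NumericVector voxels, IntegerVector dims,
                        NumericVector src, NumericVector dst) {
  Geo g(voxels, dims);
  std::vector<int> s = local_ids(g, src), t = local_ids(g, dst);
  std::vector<double> dist = g.run(s);
  double best = std::numeric_limits<double>::infinity();
  for (int q : t) best = std::min(best, dist[q]);
  return best;
}

// Maximal over (src, dst) pairs of the shortest-path length: the longest
// geodesic placement available between the two contact sets.
// [[Rcpp::export]]
double cpp_geodesic_max(NumericVector voxels, IntegerVector dims,
                        NumericVector src, NumericVector dst) {
  Geo g(voxels, dims);
  std::vector<int> s = local_ids(g, src), t = local_ids(g, dst);
  double best = -1.0;
  for (int a : s) {
    std::vector<double> dist = g.run(std::vector<int>{a});
    for (int q : t)
      if (std::isfinite(dist[q]) && dist[q] > best) best = dist[q];
  }
  return best;
}

// Separable Gaussian smoothing (reflecting edges); sigma in voxels.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dims, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("length mismatch");
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double &v : k) v /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  auto pass = [&](int axis) {
    int nn[3] = {nx, ny, nz};
    R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
    int m = nn[axis];
    for (R_xlen_t i = 0; i < n; ++i) {
      int x, y, z; idx2xyz(i, nx, ny, x, y, z);
      int c[3] = {x, y, z};
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int p = c[axis] + t;
        if (p < 0) p = -p - 1;          // reflect
        if (p >= m) p = 2 * m - p - 1;
        acc += k[t + r] * a[i + ((R_xlen_t)p - c[axis]) * stride[axis]];
      }
      b[i] = acc;
    }
    a.swap(b);
  };
  pass(0); pass(1); pass(2);
  return NumericVector(a.begin(), a.end());
}
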