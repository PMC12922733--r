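#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian convolution on a 3D array, sigma given per axis in
// voxel units. Kernels are truncated at 5 sigma (tail mass < 1e-6) and
// renormalised at the array edges so constant regions stay constant.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector arr, IntegerVector dim,
                             NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(arr.begin(), arr.end());
  std::vector<double> out(buf.size());
  const int n[3] = {nx, ny, nz};
  const long strides[3] = {1, (long)nx, (long)nx * ny};

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int rad = (int)std::ceil(5.0 * s);
    std::vector<double> k(2 * rad + 1);
    for (int i = -rad; i <= rad; ++i)
      k[i + rad] = std::exp(-0.5 * (double)i * i / (s * s));
    const long stride = strides[axis];
    const int len = n[axis];
    // iterate over all lines along `axis`
    long nlines = (long)nx * ny * nz / len;
    const int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
    for (long l = 0; l < nlines; ++l) {
      long i1 = l % n[a1], i2 = l / n[a1];
      long base = i1 * strides[a1] + i2 * strides[a2];
      for (int i = 0; i < len; ++i) {
        double acc = 0, wsum = 0;
        int lo = std::max(0, i - rad), hi = std::min(len - 1, i + rad);
        for (int j = lo; j <= hi; ++j) {
          double w = k[j - i + rad];
          acc += w * buf[base + (long)j * stride];
          wsum += w;
        }
        out[base + (long)i * stride] = acc / wsum;
      }
    }
    std::swap(buf, out);
  }
  NumericVector res(buf.begin(), buf.end());
  res.attr("dim") = dim;
  return res;
}

// Connected components of the nonzero voxels of an integer array.
// connectivity: 6 or 26. If same_value_only, voxels join only when they
// carry equal values (used to check that each cell label is one component).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector vol, IntegerVector dim,
                                   int connectivity, bool same_value_only) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long ntot = (long)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  lab.attr("dim") = dim;
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::vector<long> stack;
  for (long v = 0; v < ntot; ++v) {
    if (vol[v] == 0 || lab[v] != 0) continue;
    ++cur;
    lab[v] = cur;
    stack.push_back(v);
    while (!stack.empty()) {
      long u = stack.back(); stack.pop_back();
      int ux = u % nx, uy = (u / nx) % ny, uz = u / ((long)nx * ny);
      for (auto &o : offs) {
        int x = ux + o[0], y = uy + o[1], z = uz + o[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        long w = x + (long)nx * (y + (long)ny * z);
        if (vol[w] == 0 || lab[w] != 0) continue;
        if (same_value_only && vol[w] != vol[u]) continue;
        lab[w] = cur;
        stack.push_back(w);
      }
    }
  }
  return lab;
}

struct QItem {
  double pri;
  long age;   // FIFO tie-break for equal priorities
  long idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.pri != b.pri) return a.pri > b.pri;
    return a.age > b.age;
  }
};

// Meyer-style seeded watershed flooding of an intensity landscape,
// 6-connectivity. seeds: integer labels (0 = unseeded). Every voxel ends up
// with the label of the seed whose flood reaches it first (lowest
// intensity path first).
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector intensity, IntegerVector seeds,
                            IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long ntot = (long)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  lab.attr("dim") = dim;
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long age = 0;
  for (long v = 0; v < ntot; ++v) {
    if (seeds[v] != 0) {
      lab[v] = seeds[v];
      pq.push({intensity[v], age++, v});
    }
  }
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    long u = pq.top().idx; pq.pop();
    int ux = u % nx, uy = (u / nx) % ny, uz = u / ((long)nx * ny);
    for (int d = 0; d < 6; ++d) {
      int x = ux + dxs[d], y = uy + dys[d], z = uz + dzs[d];
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      long w = x + (long)nx * (y + (long)ny * z);
      if (lab[w] != 0) continue;
      lab[w] = lab[u];
      pq.push({intensity[w], age++, w});
    }
  }
  return lab;
}

static inline double trilinear(const NumericVector &vol, int nx, int ny,
                               int nz, double cx, double cy, double cz,
                               bool *oob) {
  if (cx < -0.5 || cy < -0.5 || cz < -0.5 ||
      cx > nx - 0.5 || cy > ny - 0.5 || cz > nz - 0.5) {
    *oob = true;
    return 0.0;
  }
  int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
      z0 = (int)std::floor(cz);
  double fx = cx - x0, fy = cy - y0, fz = cz - z0;
  double acc = 0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        int x = x0 + dx, y = y0 + dy, z = z0 + dz;
        double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                   (dz ? fz : 1 - fz);
        if (w == 0) continue;
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
          continue;  // clamp contribution to 0 outside
        acc += w * vol[x + (long)nx * (y + (long)ny * z)];
      }
  return acc;
}

// For each point, sample the volume by trilinear interpolation along its
// unit normal at positions -band, -band+step, ..., +band and aggregate by
// max (use_max) or mean. Returns values plus the count of points whose own
// position falls outside the stack.
// [[Rcpp::export]]
List cpp_sample_normal(NumericVector vol, IntegerVector dim, NumericVector vs,
                       NumericVector origin, NumericMatrix pts,
                       NumericMatrix normals, double band, double step,
                       bool use_max) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = pts.nrow();
  NumericVector out(np);
  int n_oob = 0;
  int nsteps = (step > 0) ? (int)std::ceil(band / step) : 0;
  for (int p = 0; p < np; ++p) {
    double best = use_max ? R_NegInf : 0.0;
    int cnt = 0;
    bool centre_oob = false;
    for (int s = -nsteps; s <= nsteps; ++s) {
      double t = (nsteps > 0) ? band * (double)s / nsteps : 0.0;
      double x = pts(p, 0) + t * normals(p, 0);
      double y = pts(p, 1) + t * normals(p, 1);
      double z = pts(p, 2) + t * normals(p, 2);
      double cx = (x - origin[0]) / vs[0] - 0.5;
      double cy = (y - origin[1]) / vs[1] - 0.5;
      double cz = (z - origin[2]) / vs[2] - 0.5;
      bool oob = false;
      double val = trilinear(vol, nx, ny, nz, cx, cy, cz, &oob);
      // flag only vertices clearly outside: smoothing can push edge
      // vertices marginally past the outermost voxel centre
      if (s == 0 && (cx < -1.5 || cy < -1.5 || cz < -1.5 ||
                     cx > nx + 0.5 || cy > ny + 0.5 || cz > nz + 0.5))
        centre_oob = true;
      (void)oob;
      if (use_max) {
        if (val > best) best = val;
      } else {
        best += val;
        ++cnt;
      }
    }
    if (!use_max && cnt > 0) best /= cnt;
    if (centre_oob) ++n_oob;
    out[p] = best;
  }
  return List::create(_["value"] = out, _["n_out_of_bounds"] = n_oob);
}

// Add isotropic 3D Gaussian spots (physical-unit sigma) into a volume.
// Support truncated at 4 sigma.
// [[Rcpp::export]]
NumericVector cpp_render_spots(NumericVector vol, IntegerVector dim,
                               NumericVector vs, NumericVector origin,
                               NumericMatrix centers, double sigma,
                               double amplitude) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  out.attr("dim") = dim;
  if (centers.nrow() == 0 || amplitude == 0) return out;
  const double r = 4.0 * sigma;
  for (int p = 0; p < centers.nrow(); ++p) {
    double cx = centers(p, 0), cy = centers(p, 1), cz = centers(p, 2);
    int x0 = std::max(0, (int)std::floor((cx - r - origin[0]) / vs[0] - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + r - origin[0]) / vs[0] - 0.5));
    int y0 = std::max(0, (int)std::floor((cy - r - origin[1]) / vs[1] - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + r - origin[1]) / vs[1] - 0.5));
    int z0 = std::max(0, (int)std::floor((cz - r - origin[2]) / vs[2] - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + r - origin[2]) / vs[2] - 0.5));
    const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    for (int z = z0; z <= z1; ++z) {
      double pz = origin[2] + (z + 0.5) * vs[2] - cz;
      for (int y = y0; y <= y1; ++y) {
        double py = origin[1] + (y + 0.5) * vs[1] - cy;
        double d2yz = py * py + pz * pz;
        long base = (long)nx * (y + (long)ny * z);
        for (int x = x0; x <= x1; ++x) {
          double px = origin[0] + (x + 0.5) * vs[0] - cx;
          double d2 = px * px + d2yz;
          out[base + x] += amplitude * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  return out;
}
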