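#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Linear index helpers for 3-D arrays in R (column-major) layout.
static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Offsets for 6- or 26-connectivity.
static void neighbour_offsets(int connectivity,
                              std::vector<int> &dx, std::vector<int> &dy,
                              std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int nn = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && nn > 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Connected-component labelling of a binary 3-D mask. Components are numbered
// 1..k in order of their smallest linear index (deterministic).
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim,
                           int connectivity = 26) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  int nextlab = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++nextlab;
    lab[i] = nextlab;
    q.push(i);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int z = cur / (nx * ny);
      int rem = cur - z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int j = idx3(xx, yy, zz, nx, ny);
        if (mask[j] && lab[j] == 0) { lab[j] = nextlab; q.push(j); }
      }
    }
  }
  return lab;
}

// Binary erosion with the 3-D cross (face-connected) structuring element,
// radius r applied as r iterated radius-1 erosions (Minkowski additivity of
// the cross element makes this equal to one erosion of radius r).
// [[Rcpp::export]]
LogicalVector binary_erode_cpp(LogicalVector mask, IntegerVector dim,
                               int radius = 1) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> cur(n), nxt(n);
  for (int i = 0; i < n; ++i) cur[i] = mask[i] ? 1 : 0;
  for (int r = 0; r < radius; ++r) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          char keep = cur[i];
          if (keep) {
            // voxels on the grid border erode away (background outside)
            if (x == 0 || x == nx - 1 || y == 0 || y == ny - 1 ||
                z == 0 || z == nz - 1) keep = 0;
            else if (!cur[i - 1] || !cur[i + 1] ||
                     !cur[i - nx] || !cur[i + nx] ||
                     !cur[i - nx * ny] || !cur[i + nx * ny]) keep = 0;
          }
          nxt[i] = keep;
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cur[i] != 0;
  return out;
}

// The 13 unique 3-D directions (half of the 26 neighbours).
static void unique_directions(std::vector<int> &dx, std::vector<int> &dy,
                              std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (c > 0 || (c == 0 && b > 0) || (c == 0 && b == 0 && a > 0)) {
          dx.push_back(a); dy.push_back(b); dz.push_back(c);
        }
      }
}

// Gray-level co-occurrence counts, symmetric, distance 1, accumulated over
// the 13 unique 3-D directions. img holds bin numbers 1..ng (0 outside mask).
// [[Rcpp::export]]
NumericMatrix glcm_count_cpp(IntegerVector img, LogicalVector mask,
                             IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix P(ng, ng);
  std::vector<int> dx, dy, dz;
  unique_directions(dx, dy, dz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        int gi = img[i];
        for (size_t k = 0; k < dx.size(); ++k) {
          int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (!mask[j]) continue;
          int gj = img[j];
          P(gi - 1, gj - 1) += 1.0;
          P(gj - 1, gi - 1) += 1.0;
        }
      }
  return P;
}

// Gray-level run-length counts accumulated over the 13 unique directions.
// Returns an ng x maxRunLength matrix.
// [[Rcpp::export]]
NumericMatrix glrlm_count_cpp(IntegerVector img, LogicalVector mask,
                              IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxdim = std::max(nx, std::max(ny, nz));
  NumericMatrix R(ng, maxdim);
  std::vector<int> dx, dy, dz;
  unique_directions(dx, dy, dz);
  for (size_t k = 0; k < dx.size(); ++k) {
    int ax = dx[k], ay = dy[k], az = dz[k];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          if (!mask[i]) continue;
          int g = img[i];
          // run starts here iff predecessor along (ax,ay,az) is absent/different
          int px = x - ax, py = y - ay, pz = z - az;
          bool starts = true;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz) {
            int pi = idx3(px, py, pz, nx, ny);
            if (mask[pi] && img[pi] == g) starts = false;
          }
          if (!starts) continue;
          int len = 1;
          int cx = x + ax, cy = y + ay, cz = z + az;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 &&
                 cz < nz) {
            int ci = idx3(cx, cy, cz, nx, ny);
            if (!mask[ci] || img[ci] != g) break;
            ++len; cx += ax; cy += ay; cz += az;
          }
          R(g - 1, len - 1) += 1.0;
        }
  }
  return R;
}

// Gray-level size-zone counts: zones are 26-connected components of equal
// gray level inside the mask. Returns a list(sizes ng x nzones sparse as
// matrix ng x maxZoneSize would be huge) -> returns two integer vectors:
// zone gray level and zone size.
// [[Rcpp::export]]
List glszm_zones_cpp(IntegerVector img, LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<int> lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(26, dx, dy, dz);
  std::vector<int> zg, zs;
  std::queue<int> q;
  int nextlab = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    int g = img[i];
    ++nextlab;
    lab[i] = nextlab;
    int sz = 0;
    q.push(i);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      ++sz;
      int z = cur / (nx * ny);
      int rem = cur - z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int j = idx3(xx, yy, zz, nx, ny);
        if (mask[j] && lab[j] == 0 && img[j] == g) { lab[j] = nextlab; q.push(j); }
      }
    }
    zg.push_back(g);
    zs.push_back(sz);
  }
  return List::create(_["gray"] = wrap(zg), _["size"] = wrap(zs));
}

// Neighbouring gray-tone difference counts: per gray level i the number of
// mask voxels n_i with at least one in-mask 26-neighbour and the summed
// absolute difference s_i between the voxel level and the mean level of its
// in-mask neighbours.
// [[Rcpp::export]]
NumericMatrix ngtdm_count_cpp(IntegerVector img, LogicalVector mask,
                              IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2); // col 0: n_i, col 1: s_i
  std::vector<int> dx, dy, dz;
  neighbour_offsets(26, dx, dy, dz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        double sum = 0.0; int cnt = 0;
        for (size_t k = 0; k < dx.size(); ++k) {
          int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (!mask[j]) continue;
          sum += img[j]; ++cnt;
        }
        if (cnt == 0) continue;
        int g = img[i];
        out(g - 1, 0) += 1.0;
        out(g - 1, 1) += std::fabs((double)g - sum / cnt);
      }
  return out;
}

// Gray-level dependence counts: dependence of a voxel = number of 26-
// neighbours in the mask whose level differs by at most alpha. Returns an
// ng x (27) matrix (dependence 0..26 -> column dep+1).
// [[Rcpp::export]]
NumericMatrix gldm_count_cpp(IntegerVector img, LogicalVector mask,
                             IntegerVector dim, int ng, int alpha = 0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix D(ng, 27);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(26, dx, dy, dz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        int g = img[i];
        int dep = 0;
        for (size_t k = 0; k < dx.size(); ++k) {
          int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (!mask[j]) continue;
          if (std::abs(img[j] - g) <= alpha) ++dep;
        }
        D(g - 1, dep) += 1.0;
      }
  return D;
}

// Separable 1-D convolution of a 3-D volume along one axis (0,1,2).
// Kernel is centred (odd length). mode 0 = replicate border, 1 = periodic.
// Lines along the axis are gathered into a padded buffer so the inner loop
// is branch-free.
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis, int mode = 0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  int kl = kernel.size();
  int half = kl / 2;
  NumericVector out(n);
  int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  long stride = (axis == 0) ? 1 : (axis == 1) ? nx : (long)nx * ny;
  const double *src = REAL(vol);
  double *dst = REAL(out);
  const double *ker = REAL(kernel);
  std::vector<double> buf(len + 2 * half);
  // iterate over all lines perpendicular to the axis
  int d1 = (axis == 0) ? ny : nx;
  int d2 = (axis == 2) ? ny : nz;
  long s1 = (axis == 0) ? nx : 1;
  long s2 = (axis == 2) ? nx : (long)nx * ny;
  for (int b = 0; b < d2; ++b)
    for (int a = 0; a < d1; ++a) {
      long base = a * s1 + b * s2;
      for (int i = 0; i < len; ++i) buf[half + i] = src[base + i * stride];
      for (int i = 0; i < half; ++i) {
        if (mode == 1) {
          buf[i] = buf[len + i];                 // periodic
          buf[half + len + i] = buf[half + i];
        } else {
          buf[i] = buf[half];                    // replicate
          buf[half + len + i] = buf[half + len - 1];
        }
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        const double *bp = &buf[i];
        for (int k = 0; k < kl; ++k) acc += ker[k] * bp[k];
        dst[base + i * stride] = acc;
      }
    }
  return out;
}
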