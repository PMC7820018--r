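// Gray-level matrix counting on 3D discretized ROIs.
//
// All functions take a flattened (column-major, R order) integer level
// array where 0 marks voxels outside the ROI and 1..ngray are discretized
// gray levels, plus the grid dimensions. Feature formulas live in R; only
// the raw counts are computed here.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, const int *d) {
  return x + d[0] * (y + d[1] * z);
}

static inline bool inside(int x, int y, int z, const int *d) {
  return x >= 0 && y >= 0 && z >= 0 && x < d[0] && y < d[1] && z < d[2];
}

// 13 unique 3D direction vectors (one per +/- pair of the 26 neighbors).
static const int DIRS13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// [[Rcpp::export]]
IntegerMatrix cpp_directions13() {
  IntegerMatrix m(13, 3);
  for (int i = 0; i < 13; ++i)
    for (int j = 0; j < 3; ++j) m(i, j) = DIRS13[i][j];
  return m;
}

// Per-direction co-occurrence counts at distance 1 (not yet symmetrized).
// Returns ngray x ngray x 13 counts.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dims, int ngray) {
  const int *d = INTEGER(dims);
  NumericVector out(ngray * ngray * 13);
  for (int a = 0; a < 13; ++a) {
    const int dx = DIRS13[a][0], dy = DIRS13[a][1], dz = DIRS13[a][2];
    double *slab = REAL(out) + (R_xlen_t)a * ngray * ngray;
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          int li = levels[idx3(x, y, z, d)];
          if (li == 0) continue;
          int X = x + dx, Y = y + dy, Z = z + dz;
          if (!inside(X, Y, Z, d)) continue;
          int lj = levels[idx3(X, Y, Z, d)];
          if (lj == 0) continue;
          slab[(li - 1) + ngray * (lj - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ngray, ngray, 13);
  return out;
}

// Per-direction run-length counts. Returns a list of 13 ngray x maxrun
// matrices (maxrun = longest grid diagonal in voxels).
// [[Rcpp::export]]
List cpp_glrlm(IntegerVector levels, IntegerVector dims, int ngray) {
  const int *d = INTEGER(dims);
  int maxrun = std::max(d[0], std::max(d[1], d[2]));
  List out(13);
  for (int a = 0; a < 13; ++a) {
    const int dx = DIRS13[a][0], dy = DIRS13[a][1], dz = DIRS13[a][2];
    NumericMatrix P(ngray, maxrun);
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          int li = levels[idx3(x, y, z, d)];
          if (li == 0) continue;
          // run start: predecessor out of grid, outside ROI, or other level
          int px = x - dx, py = y - dy, pz = z - dz;
          if (inside(px, py, pz, d) && levels[idx3(px, py, pz, d)] == li)
            continue;
          int len = 1, X = x + dx, Y = y + dy, Z = z + dz;
          while (inside(X, Y, Z, d) && levels[idx3(X, Y, Z, d)] == li) {
            ++len; X += dx; Y += dy; Z += dz;
          }
          P(li - 1, len - 1) += 1.0;
        }
    out[a] = P;
  }
  return out;
}

// Size-zone counts: zones are 26-connected components of equal level.
// Returns ngray x maxzone counts (maxzone = largest zone found).
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector levels, IntegerVector dims, int ngray) {
  const int *d = INTEGER(dims);
  const R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int, int> > zones;  // (level, size)
  int maxzone = 1;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (levels[s] == 0 || seen[s]) continue;
    int lev = levels[s], size = 0;
    stack.clear();
    stack.push_back((int)s);
    seen[s] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++size;
      int cz = cur / (d[0] * d[1]);
      int rem = cur % (d[0] * d[1]);
      int cy = rem / d[0], cx = rem % d[0];
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = cx + dx, Y = cy + dy, Z = cz + dz;
            if (!inside(X, Y, Z, d)) continue;
            int ni = idx3(X, Y, Z, d);
            if (!seen[ni] && levels[ni] == lev) {
              seen[ni] = 1;
              stack.push_back(ni);
            }
          }
    }
    zones.push_back(std::make_pair(lev, size));
    if (size > maxzone) maxzone = size;
  }
  NumericMatrix P(ngray, maxzone);
  for (size_t i = 0; i < zones.size(); ++i)
    P(zones[i].first - 1, zones[i].second - 1) += 1.0;
  return P;
}

// Dependence counts: dependence size = 1 + number of 26-neighbors whose
// level differs from the center by at most alpha. Returns ngray x 27.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dims, int ngray,
                       int alpha) {
  const int *d = INTEGER(dims);
  NumericMatrix P(ngray, 27);
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int li = levels[idx3(x, y, z, d)];
        if (li == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (!inside(X, Y, Z, d)) continue;
              int lj = levels[idx3(X, Y, Z, d)];
              if (lj != 0 && std::abs(lj - li) <= alpha) ++dep;
            }
        P(li - 1, dep) += 1.0;  // column dep+1 <=> dependence size 1+dep
      }
  return P;
}

// Neighboring gray-tone difference sums: for each level i, n_i = voxel
// count and s_i = sum over those voxels of |level - mean level of valid
// 26-neighbors| (voxels with no in-ROI neighbor contribute count but 0).
// Returns ngray x 2 (n_i, s_i).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ngray) {
  const int *d = INTEGER(dims);
  NumericMatrix out(ngray, 2);
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int li = levels[idx3(x, y, z, d)];
        if (li == 0) continue;
        double sum = 0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (!inside(X, Y, Z, d)) continue;
              int lj = levels[idx3(X, Y, Z, d)];
              if (lj != 0) { sum += lj; ++cnt; }
            }
        out(li - 1, 0) += 1.0;
        if (cnt > 0) out(li - 1, 1) += std::abs(li - sum / cnt);
      }
  return out;
}

// 26-connected component labels of the nonzero voxels (labels 1..ncomp,
// 0 outside). Used for largest-component ROI extraction.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims) {
  const int *d = INTEGER(dims);
  const R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back((int)s);
    lab[s] = next;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cz = cur / (d[0] * d[1]);
      int rem = cur % (d[0] * d[1]);
      int cy = rem / d[0], cx = rem % d[0];
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = cx + dx, Y = cy + dy, Z = cz + dz;
            if (!inside(X, Y, Z, d)) continue;
            int ni = idx3(X, Y, Z, d);
            if (mask[ni] != 0 && lab[ni] == 0) {
              lab[ni] = next;
              stack.push_back(ni);
            }
          }
    }
  }
  return lab;
}
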