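#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All builders take a 3D integer array `lev` (dim attribute required) holding
// 0-based quantized gray levels inside the VOI and NA outside, plus the number
// of quantization levels. Connectivity is the full 26-neighborhood; the 13
// direction offsets below are the unique offsets up to sign.

static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int d1, int d2) {
  return x + d1 * (y + d2 * z);
}

// Symmetric co-occurrence counts summed over the 13 offsets; each unordered
// neighbor pair contributes to both (i,j) and (j,i).
// [[Rcpp::export(name = ".cppGlcm")]]
NumericMatrix cppGlcm(IntegerVector lev, int nlev) {
  const int* L = lev.begin();
  IntegerVector dims = lev.attr("dim");
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericMatrix out(nlev, nlev);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        int a = L[idx3(x, y, z, d1, d2)];
        if (a == NA_INTEGER) continue;
        for (int d = 0; d < 13; ++d) {
          int xx = x + DIR13[d][0], yy = y + DIR13[d][1], zz = z + DIR13[d][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= d1 || yy >= d2 || zz >= d3)
            continue;
          int b = L[idx3(xx, yy, zz, d1, d2)];
          if (b == NA_INTEGER) continue;
          out(a, b) += 1.0;
          out(b, a) += 1.0;
        }
      }
  return out;
}

// Dependence matrix: for each voxel the number of 26-neighbors inside the VOI
// whose level differs by at most alpha; column j holds dependence count j-1.
// [[Rcpp::export(name = ".cppGldm")]]
NumericMatrix cppGldm(IntegerVector lev, int nlev, int alpha) {
  const int* L = lev.begin();
  IntegerVector dims = lev.attr("dim");
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericMatrix out(nlev, 27);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        int a = L[idx3(x, y, z, d1, d2)];
        if (a == NA_INTEGER) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 ||
                  xx >= d1 || yy >= d2 || zz >= d3) continue;
              int b = L[idx3(xx, yy, zz, d1, d2)];
              if (b == NA_INTEGER) continue;
              if (abs(a - b) <= alpha) ++dep;
            }
        out(a, dep) += 1.0;
      }
  return out;
}

// Run-length matrix: maximal runs of equal level along each of the 13
// directions, counts merged into a single matrix. A run starts at a voxel
// whose predecessor along the direction is outside the VOI or differs in
// level, and extends while level is constant.
// [[Rcpp::export(name = ".cppGlrlm")]]
NumericMatrix cppGlrlm(IntegerVector lev, int nlev) {
  const int* L = lev.begin();
  IntegerVector dims = lev.attr("dim");
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int lmax = std::max(d1, std::max(d2, d3));
  NumericMatrix out(nlev, lmax);
  for (int d = 0; d < 13; ++d) {
    int ox = DIR13[d][0], oy = DIR13[d][1], oz = DIR13[d][2];
    for (int z = 0; z < d3; ++z)
      for (int y = 0; y < d2; ++y)
        for (int x = 0; x < d1; ++x) {
          int a = L[idx3(x, y, z, d1, d2)];
          if (a == NA_INTEGER) continue;
          int px = x - ox, py = y - oy, pz = z - oz;
          bool prevSame = px >= 0 && py >= 0 && pz >= 0 &&
            px < d1 && py < d2 && pz < d3 &&
            L[idx3(px, py, pz, d1, d2)] != NA_INTEGER &&
            L[idx3(px, py, pz, d1, d2)] == a;
          if (prevSame) continue; // not a run start
          int len = 1;
          int xx = x + ox, yy = y + oy, zz = z + oz;
          while (xx >= 0 && yy >= 0 && zz >= 0 &&
                 xx < d1 && yy < d2 && zz < d3 &&
                 L[idx3(xx, yy, zz, d1, d2)] != NA_INTEGER &&
                 L[idx3(xx, yy, zz, d1, d2)] == a) {
            ++len;
            xx += ox; yy += oy; zz += oz;
          }
          out(a, len - 1) += 1.0;
        }
  }
  return out;
}

// Size-zone matrix: zones are 26-connected components of equal level.
// Returns a two-column matrix (0-based level, zone size), one row per zone.
// [[Rcpp::export(name = ".cppGlszmZones")]]
IntegerMatrix cppGlszmZones(IntegerVector lev) {
  const int* L = lev.begin();
  IntegerVector dims = lev.attr("dim");
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int n = d1 * d2 * d3;
  std::vector<char> seen(n, 0);
  std::vector<int> zoneLevel, zoneSize, stack;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || L[start] == NA_INTEGER) continue;
    int a = L[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int x = cur % d1, y = (cur / d1) % d2, z = cur / (d1 * d2);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 ||
                xx >= d1 || yy >= d2 || zz >= d3) continue;
            int nb = idx3(xx, yy, zz, d1, d2);
            if (seen[nb] || L[nb] == NA_INTEGER || L[nb] != a) continue;
            seen[nb] = 1;
            stack.push_back(nb);
          }
    }
    zoneLevel.push_back(a);
    zoneSize.push_back(size);
  }
  int nz = (int) zoneLevel.size();
  IntegerMatrix out(nz, 2);
  for (int i = 0; i < nz; ++i) {
    out(i, 0) = zoneLevel[i];
    out(i, 1) = zoneSize[i];
  }
  return out;
}

// Neighborhood gray-tone difference: per level, the count n_i of VOI voxels
// of that level having at least one in-VOI 26-neighbor, and the sum s_i of
// |level - mean neighbor level| over those voxels.
// [[Rcpp::export(name = ".cppNgtdm")]]
NumericMatrix cppNgtdm(IntegerVector lev, int nlev) {
  const int* L = lev.begin();
  IntegerVector dims = lev.attr("dim");
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericMatrix out(nlev, 2); // columns: n_i, s_i
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        int a = L[idx3(x, y, z, d1, d2)];
        if (a == NA_INTEGER) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 ||
                  xx >= d1 || yy >= d2 || zz >= d3) continue;
              int b = L[idx3(xx, yy, zz, d1, d2)];
              if (b == NA_INTEGER) continue;
              sum += b;
              ++cnt;
            }
        if (cnt == 0) continue; // isolated voxel: excluded
        out(a, 0) += 1.0;
        out(a, 1) += std::abs((double) a - sum / cnt);
      }
  return out;
}
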