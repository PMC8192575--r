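#include <Rcpp.h>
#include <vector>
#include <cstring>

using namespace Rcpp;

// Topology-preserving 3-D thinning with 26-connected foreground and
// 6-connected background. Each full iteration visits the six border
// directions (U, D, N, S, E, W); border voxels are deleted sequentially
// only when they are simple points (Bertrand & Malandain characterisation:
// one 26-component of foreground in N26* and one 6-component of background
// in N18 touching a face neighbour) and not line endpoints. Sequential
// rechecking inside a subiteration keeps deletions mutually safe.

namespace {

// offsets of the 27 cells of the 3x3x3 neighbourhood, center last index 13
inline int cellIndex(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// Fill nb[27] with the neighbourhood of voxel (x,y,z); out of bounds = 0.
inline void neighbourhood(const std::vector<unsigned char>& img,
                          int nx, int ny, int nz,
                          int x, int y, int z, unsigned char* nb) {
  int c = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++c) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          nb[c] = 0;
        else
          nb[c] = img[(size_t)zz * nx * ny + (size_t)yy * nx + xx];
      }
}

// number of foreground voxels among the 26 neighbours
inline int fgNeighbourCount(const unsigned char* nb) {
  int cnt = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++cnt;
  return cnt;
}

// count 26-connected components of foreground within the 26 neighbours
int fgComponents26(const unsigned char* nb) {
  unsigned char lab[27];
  std::memset(lab, 0, 27);
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || lab[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    lab[s] = 1;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2)
              continue;
            int q = xx + 3 * yy + 9 * zz;
            if (q == 13 || q == cur || !nb[q] || lab[q]) continue;
            lab[q] = 1;
            stack[top++] = q;
          }
    }
  }
  return ncomp;
}

// count 6-connected components of BACKGROUND within the 18-neighbourhood
// that contain at least one of the six face neighbours of the center
int bgComponents6(const unsigned char* nb) {
  // N18: neighbours that are not corners of the cube
  auto inN18 = [](int q) {
    int x = q % 3 - 1, y = (q / 3) % 3 - 1, z = q / 9 - 1;
    if (q == 13) return false;
    return (std::abs(x) + std::abs(y) + std::abs(z)) <= 2;
  };
  static const int faces[6] = {4, 10, 12, 14, 16, 22};
  unsigned char lab[27];
  std::memset(lab, 0, 27);
  int ncomp = 0;
  int stack[27];
  for (int fi = 0; fi < 6; ++fi) {
    int s = faces[fi];
    if (nb[s] || lab[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    lab[s] = 1;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int xx = cx + d6[k][0], yy = cy + d6[k][1], zz = cz + d6[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        int q = xx + 3 * yy + 9 * zz;
        if (q == 13 || nb[q] || lab[q] || !inN18(q)) continue;
        lab[q] = 1;
        stack[top++] = q;
      }
    }
  }
  return ncomp;
}

inline bool isSimple(const unsigned char* nb) {
  return fgComponents26(nb) == 1 && bgComponents6(nb) == 1;
}

inline bool isEndpoint(const unsigned char* nb) {
  return fgNeighbourCount(nb) == 1;
}

} // namespace

// [[Rcpp::export(name = ".thin_cpp")]]
IntegerVector thin_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<unsigned char> img(n);
  for (size_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;

  // face-neighbour offsets for the six border directions
  const int dirs[6][3] = {
    {0, 0, 1}, {0, 0, -1}, {0, 1, 0}, {0, -1, 0}, {1, 0, 0}, {-1, 0, 0}
  };

  unsigned char nb[27];
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            size_t idx = (size_t)z * nx * ny + (size_t)y * nx + x;
            if (!img[idx]) continue;
            int xx = x + dirs[d][0], yy = y + dirs[d][1], zz = z + dirs[d][2];
            bool border = (xx < 0 || yy < 0 || zz < 0 ||
                           xx >= nx || yy >= ny || zz >= nz) ||
                          !img[(size_t)zz * nx * ny + (size_t)yy * nx + xx];
            if (!border) continue;
            neighbourhood(img, nx, ny, nz, x, y, z, nb);
            if (isEndpoint(nb)) continue;
            if (!isSimple(nb)) continue;
            cand.push_back((int)idx);
          }
      // sequential deletion with recheck: earlier deletions can make a
      // candidate non-simple or an endpoint
      for (size_t c = 0; c < cand.size(); ++c) {
        int idx = cand[c];
        int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
        neighbourhood(img, nx, ny, nz, x, y, z, nb);
        if (isEndpoint(nb) || !isSimple(nb)) continue;
        img[(size_t)idx] = 0;
        changed = true;
      }
    }
  }

  IntegerVector out(mask.size());
  for (size_t i = 0; i < n; ++i) out[i] = img[i];
  out.attr("dim") = dims;
  return out;
}
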