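// Texture-matrix kernels: connected-zone labeling (GLSZM), run scans
// (GLRLM) and co-occurrence counts (GLCM) on a 3-D quantized image where
// 0 marks background and 1..G the ROI gray levels.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// The 13 unique 3-D directions (half of the 26-neighborhood).
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Zones: connected components of equal-level ROI voxels under 6- or
// 26-connectivity. Returns a 2-column matrix (gray level, zone size).
// [[Rcpp::export]]
IntegerMatrix cpp_label_zones(IntegerVector levels, IntegerVector dims,
                              int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }

  std::vector<int> visited(n, 0);
  std::vector<int> zlevel, zsize;
  std::vector<int> stack;
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        int i0 = lin(x0, y0, z0, nx, ny);
        int g = levels[i0];
        if (g == 0 || visited[i0]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(i0);
        visited[i0] = 1;
        while (!stack.empty()) {
          int i = stack.back(); stack.pop_back();
          ++size;
          int x = i % nx, y = (i / nx) % ny, zz = i / (nx * ny);
          for (size_t k = 0; k < offx.size(); ++k) {
            int xn = x + offx[k], yn = y + offy[k], zn = zz + offz[k];
            if (xn < 0 || xn >= nx || yn < 0 || yn >= ny ||
                zn < 0 || zn >= nz) continue;
            int j = lin(xn, yn, zn, nx, ny);
            if (!visited[j] && levels[j] == g) {
              visited[j] = 1;
              stack.push_back(j);
            }
          }
        }
        zlevel.push_back(g);
        zsize.push_back(size);
      }

  IntegerMatrix out(zlevel.size(), 2);
  for (size_t k = 0; k < zlevel.size(); ++k) {
    out(k, 0) = zlevel[k];
    out(k, 1) = zsize[k];
  }
  colnames(out) = CharacterVector::create("level", "size");
  return out;
}

// GLRLM: maximal collinear runs of equal-level ROI voxels, counted per
// direction and summed over the 13 unique directions. Returns a G x Jmax
// count matrix (Jmax = longest run observed, at least 1).
// [[Rcpp::export]]
IntegerMatrix cpp_glrlm(IntegerVector levels, IntegerVector dims, int G) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int jcap = std::max(std::max(nx, ny), nz);
  IntegerMatrix counts(G, jcap);
  int jmax = 1;

  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int g = levels[lin(x, y, z, nx, ny)];
          if (g == 0) continue;
          // run start: predecessor along -d is outside, background, or a
          // different level
          int xp = x - dx, yp = y - dy, zp = z - dz;
          bool start = (xp < 0 || xp >= nx || yp < 0 || yp >= ny ||
                        zp < 0 || zp >= nz) ||
                       levels[lin(xp, yp, zp, nx, ny)] != g;
          if (!start) continue;
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (xn >= 0 && xn < nx && yn >= 0 && yn < ny &&
                 zn >= 0 && zn < nz &&
                 levels[lin(xn, yn, zn, nx, ny)] == g) {
            ++len;
            xn += dx; yn += dy; zn += dz;
          }
          counts(g - 1, len - 1) += 1;
          if (len > jmax) jmax = len;
        }
  }
  return counts(Range(0, G - 1), Range(0, jmax - 1));
}

// GLCM: distance-1 co-occurrences over the 13 unique directions, counted
// once per ordered pair then symmetrized. Returns a G x G count matrix.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dims, int G) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix counts(G, G);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int g = levels[lin(x, y, z, nx, ny)];
          if (g == 0) continue;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          if (xn < 0 || xn >= nx || yn < 0 || yn >= ny ||
              zn < 0 || zn >= nz) continue;
          int h = levels[lin(xn, yn, zn, nx, ny)];
          if (h == 0) continue;
          counts(g - 1, h - 1) += 1.0;
          counts(h - 1, g - 1) += 1.0;
        }
  }
  return counts;
}
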