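#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

// Voxel utilities for 3-D binary morphology: connected-component labeling,
// topology-preserving thinning, and an IIR filter kernel used by the
// zero-phase low-pass. Arrays are passed as flat integer vectors in R's
// column-major order with dims (nx, ny, nz).

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// Connected components (6- or 26-connectivity), BFS flood fill.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector arr, IntegerVector dims,
                                   int connectivity) {
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int start = 0; start < n; ++start) {
    if (arr[start] == 0 || lab[start] != 0) continue;
    lab[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int z = v / (nx * ny), r = v % (nx * ny), y = r / nx, x = r % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (connectivity == 6 && man != 1) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int w = idx3(xx, yy, zz, nx, ny);
            if (arr[w] != 0 && lab[w] == 0) { lab[w] = next; q.push(w); }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Simple-point test (Malandain & Bertrand): a foreground voxel is simple iff
//  (a) the foreground of its 26-neighborhood forms exactly one 26-connected
//      component, and
//  (b) the background of its 18-neighborhood forms exactly one 6-connected
//      component containing a face neighbor of the center.
// nb[27] holds the 3x3x3 neighborhood (center at offset (1,1,1)).

static const int OFF = 13; // center index in 3x3x3

static inline int nb_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

static int fg_components26(const int nb[27]) {
  int comp[27]; std::memset(comp, 0, sizeof(comp));
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == OFF || nb[s] == 0 || comp[s] != 0) continue;
    comp[s] = ++ncomp;
    int top = 0; stack[top++] = s;
    while (top > 0) {
      int v = stack[--top];
      int vz = v / 9, vr = v % 9, vy = vr / 3, vx = vr % 3;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = vx + dx, yy = vy + dy, zz = vz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2)
              continue;
            int w = xx + 3 * (yy + 3 * zz);
            if (w == OFF || w == v) continue;
            if (nb[w] != 0 && comp[w] == 0) { comp[w] = ncomp; stack[top++] = w; }
          }
    }
  }
  return ncomp;
}

static int bg_components6_in18(const int nb[27]) {
  // membership of the 18-neighborhood: chebyshev 1 but not a corner
  bool in18[27]; bool face[27];
  for (int s = 0; s < 27; ++s) {
    int z = s / 9, r = s % 9, y = r / 3, x = r % 3;
    int ax = std::abs(x - 1), ay = std::abs(y - 1), az = std::abs(z - 1);
    int man = ax + ay + az;
    in18[s] = (s != OFF) && (man >= 1) && (man <= 2);
    face[s] = (man == 1);
  }
  int comp[27]; std::memset(comp, 0, sizeof(comp));
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || !face[s] || nb[s] != 0 || comp[s] != 0) continue;
    // grow a background component seeded at a face neighbor
    ++ncomp;
    comp[s] = ncomp;
    int top = 0; stack[top++] = s;
    while (top > 0) {
      int v = stack[--top];
      int vz = v / 9, vr = v % 9, vy = vr / 3, vx = vr % 3;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int xx = vx + d6[k][0], yy = vy + d6[k][1], zz = vz + d6[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        int w = xx + 3 * (yy + 3 * zz);
        if (!in18[w] || nb[w] != 0 || comp[w] != 0) continue;
        comp[w] = ncomp; stack[top++] = w;
      }
    }
  }
  return ncomp;
}

static inline void fill_neighborhood(const std::vector<int>& a, int x, int y,
                                     int z, int nx, int ny, int nz, int nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        int v = 0;
        if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
          v = a[idx3(xx, yy, zz, nx, ny)];
        nb[nb_index(dx, dy, dz)] = v;
      }
}

static inline bool is_simple(const int nb[27]) {
  return fg_components26(nb) == 1 && bg_components6_in18(nb) == 1;
}

static inline int n_fg_neighbors26(const int nb[27]) {
  int c = 0;
  for (int s = 0; s < 27; ++s) if (s != OFF && nb[s] != 0) ++c;
  return c;
}

// ---------------------------------------------------------------------------
// Sequential thinning with six directional sub-iterations per pass. A voxel
// is deleted only if it is a border voxel in the current direction, is not a
// curve endpoint (>1 foreground 26-neighbor) and is still simple at the time
// of deletion, so the number of connected components never changes.
// [[Rcpp::export]]
IntegerVector thin3d_cpp(IntegerVector arr, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<int> a(n);
  for (int i = 0; i < n; ++i) a[i] = arr[i] != 0 ? 1 : 0;
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  int nb[27];
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int v = idx3(x, y, z, nx, ny);
            if (!a[v]) continue;
            int xx = x + dirs[d][0], yy = y + dirs[d][1], zz = z + dirs[d][2];
            int bgn = 1;
            if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
              bgn = a[idx3(xx, yy, zz, nx, ny)] == 0;
            if (!bgn) continue;
            fill_neighborhood(a, x, y, z, nx, ny, nz, nb);
            if (n_fg_neighbors26(nb) <= 1) continue; // endpoint
            if (is_simple(nb)) cand.push_back(v);
          }
      for (size_t k = 0; k < cand.size(); ++k) {
        int v = cand[k];
        int z = v / (nx * ny), r = v % (nx * ny), y = r / nx, x = r % nx;
        fill_neighborhood(a, x, y, z, nx, ny, nz, nb);
        if (n_fg_neighbors26(nb) <= 1) continue;
        if (!is_simple(nb)) continue;
        a[v] = 0;
        changed = true;
      }
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = a[i];
  return out;
}

// ---------------------------------------------------------------------------
// Direct-form II transposed IIR filter with initial state zi (a[0] == 1).
// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  const int nord = std::max(b.size(), a.size()) - 1;
  std::vector<double> bb(nord + 1, 0.0), aa(nord + 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  std::vector<double> z(nord, 0.0);
  for (int i = 0; i < zi.size() && i < nord; ++i) z[i] = zi[i];
  const int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nord > 0 ? z[0] : 0.0);
    for (int j = 0; j < nord - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nord > 0) z[nord - 1] = bb[nord] * xi - aa[nord] * yi;
    y[i] = yi;
  }
  return y;
}
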