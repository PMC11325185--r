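#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// CRC-32 (IEEE 802.3, reflected), as used by the PNG chunk format.
static uint32_t crc_table[256];
static bool crc_table_ready = false;

static void make_crc_table() {
  for (uint32_t n = 0; n < 256; ++n) {
    uint32_t c = n;
    for (int k = 0; k < 8; ++k)
      c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
    crc_table[n] = c;
  }
  crc_table_ready = true;
}

// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  if (!crc_table_ready) make_crc_table();
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = crc_table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return static_cast<double>(c ^ 0xFFFFFFFFu);
}

// Connected-component labelling of a binary mask. connectivity = 4 or 8.
// Labels are assigned in raster-scan order of first encounter, from 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  int nnb = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher lower envelope).
static void edt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                  std::vector<int> &v, std::vector<double> &z) {
  const double INF = 1e20;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance of each foreground pixel to the nearest
// background pixel inside the image (image border is not background).
// An all-foreground image yields a large finite value everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix d(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along columns (vertical)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    edt1d(f, out, nr, v, z);
    for (int r = 0; r < nr; ++r) d(r, c) = out[r];
  }
  // pass along rows (horizontal)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    edt1d(f, out, nc, v, z);
    for (int c = 0; c < nc; ++c) d(r, c) = out[c];
  }
  return d;
}

// Label regional maxima plateaus of x within mask (8-connectivity).
// A plateau is a connected set of equal values none of whose in-mask
// neighbours is strictly greater. Returns 0 elsewhere, labels from 1.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_maxima(NumericMatrix x, LogicalMatrix mask) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  IntegerMatrix seen(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::fill(seen.begin(), seen.end(), 0);
  const int dr[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::vector<int> stack, plateau;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || seen(r, c)) continue;
      double val = x(r, c);
      bool is_max = true;
      stack.clear(); plateau.clear();
      stack.push_back(r + c * nr);
      seen(r, c) = 1;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        plateau.push_back(idx);
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!mask(r2, c2)) continue;
          double v2 = x(r2, c2);
          if (v2 > val) is_max = false;
          else if (v2 == val && !seen(r2, c2)) {
            seen(r2, c2) = 1;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
      if (is_max) {
        ++next;
        for (size_t i = 0; i < plateau.size(); ++i) {
          int rr = plateau[i] % nr, cc = plateau[i] / nr;
          lab(rr, cc) = next;
        }
      }
    }
  }
  return lab;
}

struct FloodEntry {
  double elev;
  long order;
  int idx;
};
struct FloodCmp {
  bool operator()(const FloodEntry &a, const FloodEntry &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;                      // FIFO among equals
  }
};

// Seeded watershed by priority flooding of `elev` restricted to mask.
// seeds: initial label matrix (0 = unlabelled). Growth is 4-connected; a
// pixel reachable from two labels becomes a watershed line (returned as 0).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix elev, IntegerMatrix seeds, LogicalMatrix mask) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  const int LINE = -1;
  for (int i = 0; i < nr * nc; ++i) lab[i] = seeds[i];
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCmp> pq;
  long counter = 0;
  const int dr[] = {-1, 1, 0, 0}, dc[] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c) && lab(r, c) > 0)
        pq.push({elev(r, c), counter++, r + c * nr});
  while (!pq.empty()) {
    FloodEntry e = pq.top(); pq.pop();
    int r = e.idx % nr, c = e.idx / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || lab(r2, c2) != 0) continue;
      // distinct positive labels among the 4-neighbours of the candidate
      int found = 0; bool conflict = false;
      for (int k2 = 0; k2 < 4; ++k2) {
        int r3 = r2 + dr[k2], c3 = c2 + dc[k2];
        if (r3 < 0 || r3 >= nr || c3 < 0 || c3 >= nc) continue;
        int l3 = lab(r3, c3);
        if (l3 > 0) {
          if (found == 0) found = l3;
          else if (found != l3) { conflict = true; break; }
        }
      }
      if (conflict) {
        lab(r2, c2) = LINE;
      } else if (found > 0) {
        lab(r2, c2) = found;
        pq.push({elev(r2, c2), counter++, r2 + c2 * nr});
      }
    }
  }
  for (int i = 0; i < nr * nc; ++i) if (lab[i] == LINE) lab[i] = 0;
  return lab;
}
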