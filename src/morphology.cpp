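// Morphological primitives for the phase-contrast segmentation chain.
// Images are R numeric matrices (column-major); conn is 4 or 8.

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline void neighbours(int r, int c, int nr, int nc, int conn,
                              std::vector<int> &out) {
  out.clear();
  static const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int n = (conn == 8) ? 8 : 4;
  for (int k = 0; k < n; ++k) {
    int rr = r + dr8[k], cc = c + dc8[k];
    if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) out.push_back(rr + cc * nr);
  }
}

// Connected-component labelling of a logical mask, raster-order label ids.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix &mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> nb;
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      if (!mask[i] || lab[i] != 0) continue;
      lab[i] = ++next;
      q.push(i);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        neighbours(p % nr, p / nr, nr, nc, conn, nb);
        for (int j : nb) {
          if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
        }
      }
    }
  }
  return lab;
}

// Grayscale reconstruction by dilation (Vincent's hybrid algorithm).
// marker <= mask elementwise is assumed; result is the reconstruction.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(const NumericMatrix &marker,
                                       const NumericMatrix &mask, int conn) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix f = clone(marker);
  std::vector<int> nb;
  // forward raster scan
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      double m = f[i];
      neighbours(r, c, nr, nc, conn, nb);
      for (int j : nb) {
        // scan-order predecessors only (column-major raster)
        if (j < i && f[j] > m) m = f[j];
      }
      f[i] = std::min(m, mask[i]);
    }
  }
  // backward raster scan + queue seeding
  std::queue<int> q;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      int i = r + c * nr;
      double m = f[i];
      neighbours(r, c, nr, nc, conn, nb);
      bool enqueue = false;
      for (int j : nb) {
        if (j > i && f[j] > m) m = f[j];
      }
      f[i] = std::min(m, mask[i]);
      for (int j : nb) {
        if (j > i && f[j] < f[i] && f[j] < mask[j]) enqueue = true;
      }
      if (enqueue) q.push(i);
    }
  }
  while (!q.empty()) {
    int p = q.front(); q.pop();
    neighbours(p % nr, p / nr, nr, nc, conn, nb);
    for (int j : nb) {
      if (f[j] < f[p] && mask[j] != f[j]) {
        f[j] = std::min(f[p], mask[j]);
        q.push(j);
      }
    }
  }
  return f;
}

// Regional minima: connected plateaus with no lower neighbour, labelled in
// raster order of first discovery.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_minima(const NumericMatrix &img, int conn) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> visited(nr * nc, 0), plateau;
  std::vector<int> nb;
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      if (visited[i]) continue;
      double v = img[i];
      bool is_min = true;
      plateau.clear();
      visited[i] = 1;
      q.push(i);
      plateau.push_back(i);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        neighbours(p % nr, p / nr, nr, nc, conn, nb);
        for (int j : nb) {
          if (img[j] < v) is_min = false;
          else if (img[j] == v && !visited[j]) {
            visited[j] = 1;
            q.push(j);
            plateau.push_back(j);
          }
        }
      }
      if (is_min) {
        ++next;
        for (int p : plateau) lab[p] = next;
      }
    }
  }
  return lab;
}

struct FloodNode {
  double value;
  long long order;
  int index;
};
struct FloodCmp {
  bool operator()(const FloodNode &a, const FloodNode &b) const {
    if (a.value != b.value) return a.value > b.value;  // min-heap on value
    return a.order > b.order;                          // FIFO on ties
  }
};

// Marker-controlled watershed by priority flooding of `landscape`, restricted
// to `mask`. Every masked pixel reachable from a marker inherits the label of
// the basin that floods it first; unreachable masked pixels stay 0.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(const NumericMatrix &landscape,
                                   const IntegerMatrix &markers,
                                   const LogicalMatrix &mask, int conn) {
  int nr = landscape.nrow(), nc = landscape.ncol();
  IntegerMatrix out(nr, nc);
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCmp> pq;
  long long counter = 0;
  std::vector<int> nb;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      if (mask[i] && markers[i] > 0) {
        out[i] = markers[i];
        pq.push({landscape[i], counter++, i});
      }
    }
  }
  while (!pq.empty()) {
    FloodNode nd = pq.top(); pq.pop();
    int p = nd.index;
    neighbours(p % nr, p / nr, nr, nc, conn, nb);
    for (int j : nb) {
      if (mask[j] && out[j] == 0) {
        out[j] = out[p];
        pq.push({landscape[j], counter++, j});
      }
    }
  }
  return out;
}
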