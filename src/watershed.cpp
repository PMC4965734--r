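#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling of a binary mask. connectivity = 4 or 8.
// Components are numbered 1..K in column-major scan order (deterministic).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  const int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1}, dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int* dx = connectivity == 8 ? dx8 : dx4;
  const int* dy = connectivity == 8 ? dy8 : dy4;
  const int nd = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(x * h + y);
      lab(y, x) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int px = p / h, py = p % h;
        for (int d = 0; d < nd; ++d) {
          const int qx = px + dx[d], qy = py + dy[d];
          if (qx < 0 || qx >= w || qy < 0 || qy >= h) continue;
          if (mask(qy, qx) && lab(qy, qx) == 0) {
            lab(qy, qx) = next;
            stack.push_back(qx * h + qy);
          }
        }
      }
    }
  }
  return lab;
}

struct QEntry {
  double elev;
  long order;
  int idx;
  bool operator<(const QEntry& o) const { // min-heap via std::priority_queue
    if (elev != o.elev) return elev > o.elev;
    return order > o.order; // FIFO among equal elevations
  }
};

// Meyer's flooding watershed of an elevation map. Basin markers are the
// connected (4-connectivity) plateaus of the global minimum elevation; a
// pixel reached by floods from more than one basin becomes a ridge pixel.
// Ridge pixels are then assigned to the adjacent basin whose neighboring
// pixels have the lower mean elevation (ties to the lower basin id), in
// synchronized rounds until all pixels are owned.
// Returns basins (ridges = 0) and labels (every pixel > 0).
// [[Rcpp::export]]
List cpp_watershed(const NumericMatrix& elev) {
  const int h = elev.nrow(), w = elev.ncol();
  const R_xlen_t npx = (R_xlen_t)h * w;
  double mn = elev(0, 0);
  for (R_xlen_t i = 0; i < npx; ++i) mn = std::min(mn, elev[i]);
  LogicalMatrix minmask(h, w);
  for (R_xlen_t i = 0; i < npx; ++i) minmask[i] = (elev[i] == mn);
  IntegerMatrix lab = cpp_label_components(minmask, 4);
  IntegerMatrix basins(h, w); // 0 = unassigned, -1 = ridge (internally)
  for (R_xlen_t i = 0; i < npx; ++i) basins[i] = lab[i];

  const int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  std::priority_queue<QEntry> pq;
  long order = 0;
  std::vector<unsigned char> queued((size_t)npx, 0);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      if (basins(y, x) == 0) continue;
      for (int d = 0; d < 4; ++d) {
        const int qx = x + dx4[d], qy = y + dy4[d];
        if (qx < 0 || qx >= w || qy < 0 || qy >= h) continue;
        const R_xlen_t qi = (R_xlen_t)qx * h + qy;
        if (basins[qi] == 0 && !queued[qi]) {
          queued[qi] = 1;
          pq.push({elev(qy, qx), order++, (int)qi});
        }
      }
    }
  while (!pq.empty()) {
    const QEntry e = pq.top();
    pq.pop();
    const int px = e.idx / h, py = e.idx % h;
    if (basins(py, px) != 0) continue;
    int found = 0;
    for (int d = 0; d < 4; ++d) {
      const int qx = px + dx4[d], qy = py + dy4[d];
      if (qx < 0 || qx >= w || qy < 0 || qy >= h) continue;
      const int l = basins(qy, qx);
      if (l > 0) {
        if (found == 0) found = l;
        else if (found != l) { found = -1; break; }
      }
    }
    basins(py, px) = (found == -1) ? -1 : found; // found > 0 here otherwise
    if (found > 0) {
      for (int d = 0; d < 4; ++d) {
        const int qx = px + dx4[d], qy = py + dy4[d];
        if (qx < 0 || qx >= w || qy < 0 || qy >= h) continue;
        const R_xlen_t qi = (R_xlen_t)qx * h + qy;
        if (basins[qi] == 0 && !queued[qi]) {
          queued[qi] = 1;
          pq.push({elev(qy, qx), order++, (int)qi});
        }
      }
    }
  }

  IntegerMatrix ridge_basins(h, w);
  for (R_xlen_t i = 0; i < npx; ++i) ridge_basins[i] = basins[i] > 0 ? basins[i] : 0;

  // assign ridge / leftover pixels to an adjacent basin (8-neighborhood):
  // lowest mean elevation of same-labelled neighbors wins; ties to lower id
  IntegerMatrix labels = clone(ridge_basins);
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1}, dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  bool progress = true;
  while (progress) {
    progress = false;
    std::vector<std::pair<R_xlen_t, int>> updates;
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        if (labels(y, x) != 0) continue;
        double best_mean = 0.0;
        int best_lab = 0;
        // collect candidate labels among 8-neighbors
        for (int d = 0; d < 8; ++d) {
          const int qx = x + dx8[d], qy = y + dy8[d];
          if (qx < 0 || qx >= w || qy < 0 || qy >= h) continue;
          const int l = labels(qy, qx);
          if (l <= 0) continue;
          double s = 0.0;
          int cnt = 0;
          for (int d2 = 0; d2 < 8; ++d2) {
            const int rx = x + dx8[d2], ry = y + dy8[d2];
            if (rx < 0 || rx >= w || ry < 0 || ry >= h) continue;
            if (labels(ry, rx) == l) { s += elev(ry, rx); ++cnt; }
          }
          const double mean = s / cnt;
          if (best_lab == 0 || mean < best_mean ||
              (mean == best_mean && l < best_lab)) {
            best_mean = mean;
            best_lab = l;
          }
        }
        if (best_lab > 0) updates.emplace_back((R_xlen_t)x * h + y, best_lab);
      }
    for (auto& u : updates) {
      labels[u.first] = u.second;
      progress = true;
    }
  }
  return List::create(_["basins"] = ridge_basins, _["labels"] = labels);
}
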