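// Marker-based watershed on a distance map.
//
// Markers are the regional maxima of the distance transform: 8-connected
// plateaus of pixels that are >= all neighbours. Flooding assigns every
// foreground pixel to a marker in order of decreasing distance value
// (priority flood, 4-connected, deterministic tie-break by insertion order).
// Regions are then merged hierarchically: a pair of touching regions whose
// separating ridge is shallow — prominence min(peak_a, peak_b) - saddle
// below `tolerance` — is one object (this absorbs the sub-pixel fluctuation
// of the discrete distance transform along the ridge of an elongated ear),
// and a pair whose peaks lie closer than `min_sep` is also one object (two
// maxima inside one ear). Merges are applied smallest-prominence first;
// ties break toward the lower label.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix ws_maxima_cpp(NumericMatrix dm) {
  const int H = dm.nrow(), W = dm.ncol();
  LogicalMatrix cand(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (dm(i, j) <= 0) continue;
      bool ok = true;
      for (int dj = -1; dj <= 1 && ok; ++dj)
        for (int di = -1; di <= 1 && ok; ++di) {
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (dm(ii, jj) > dm(i, j)) ok = false;
        }
      cand(i, j) = ok;
    }
  IntegerMatrix marker(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (!cand(i, j) || marker(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      marker(i, j) = next;
      while (!stack.empty()) {
        const int y = stack.back().first, x = stack.back().second;
        stack.pop_back();
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            const int ny = y + dy, nx = x + dx;
            if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
            if (cand(ny, nx) && marker(ny, nx) == 0) {
              marker(ny, nx) = next;
              stack.push_back(std::make_pair(ny, nx));
            }
          }
      }
    }
  return marker;
}

struct FloodItem {
  double d;
  long order;
  int y, x, label;
};
struct FloodCmp {
  bool operator()(const FloodItem& a, const FloodItem& b) const {
    if (a.d != b.d) return a.d < b.d;      // max-heap on distance
    return a.order > b.order;              // FIFO among equals
  }
};

// [[Rcpp::export]]
IntegerMatrix ws_flood_cpp(NumericMatrix dm, IntegerMatrix marker) {
  const int H = dm.nrow(), W = dm.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<FloodItem, std::vector<FloodItem>, FloodCmp> pq;
  long order = 0;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      if (marker(i, j) > 0) {
        lab(i, j) = marker(i, j);
        pq.push(FloodItem{dm(i, j), order++, i, j, marker(i, j)});
      }
  const int dy[4] = { -1, 1, 0, 0 }, dx[4] = { 0, 0, -1, 1 };
  while (!pq.empty()) {
    const FloodItem it = pq.top();
    pq.pop();
    for (int d = 0; d < 4; ++d) {
      const int ny = it.y + dy[d], nx = it.x + dx[d];
      if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
      if (dm(ny, nx) <= 0 || lab(ny, nx) != 0) continue;
      lab(ny, nx) = it.label;
      pq.push(FloodItem{dm(ny, nx), order++, ny, nx, it.label});
    }
  }
  return lab;
}

// Hierarchical merging of flooded regions, one pair per pass:
// prominence < tolerance, or peak-to-peak distance < min_sep.
// [[Rcpp::export]]
IntegerMatrix ws_merge_cpp(NumericMatrix dm, IntegerMatrix lab0,
                           double tolerance, double min_sep) {
  const int H = dm.nrow(), W = dm.ncol();
  IntegerMatrix lab = clone(lab0);
  int K = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) > K) K = lab(i, j);
  if (K < 2) return lab;

  for (;;) {
    std::vector<double> peak(K + 1, -1.0);
    std::vector<int> py(K + 1, 0), px(K + 1, 0);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const int l = lab(i, j);
        if (l > 0 && dm(i, j) > peak[l]) {
          peak[l] = dm(i, j);
          py[l] = i; px[l] = j;
        }
      }
    std::map<std::pair<int, int>, double> saddle;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const int a = lab(i, j);
        if (a <= 0) continue;
        const int dy[2] = { 1, 0 }, dx[2] = { 0, 1 };
        for (int d = 0; d < 2; ++d) {
          const int ni = i + dy[d], nj = j + dx[d];
          if (ni >= H || nj >= W) continue;
          const int b = lab(ni, nj);
          if (b <= 0 || b == a) continue;
          const std::pair<int, int> key(std::min(a, b), std::max(a, b));
          const double s = std::min(dm(i, j), dm(ni, nj));
          std::map<std::pair<int, int>, double>::iterator it = saddle.find(key);
          if (it == saddle.end()) saddle[key] = s;
          else if (s > it->second) it->second = s;
        }
      }
    // pick the shallowest qualifying pair
    double best_score = R_PosInf;
    int ba = 0, bb = 0;
    for (std::map<std::pair<int, int>, double>::iterator it = saddle.begin();
         it != saddle.end(); ++it) {
      const int a = it->first.first, b = it->first.second;
      const double prom = std::min(peak[a], peak[b]) - it->second;
      const double dyp = py[a] - py[b], dxp = px[a] - px[b];
      const double pdist = std::sqrt(dyp * dyp + dxp * dxp);
      if (prom < tolerance || pdist < min_sep) {
        if (prom < best_score) {
          best_score = prom;
          ba = a; bb = b;
        }
      }
    }
    if (ba == 0) break;
    // keep the label with the higher peak (ties: lower label)
    int keep = ba, drop = bb;
    if (peak[bb] > peak[ba]) { keep = bb; drop = ba; }
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        if (lab(i, j) == drop) lab(i, j) = keep;
  }
  return lab;
}
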