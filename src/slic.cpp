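#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Localized k-means assignment/update rounds of SLIC. Labels are 0-based
// here; the R wrapper shifts to 1-based. centers: K x 5 matrix (l,a,b,x,y)
// with x = column, y = row, 0-based. Each center only competes for pixels
// within a 2S x 2S window around it, so a pixel keeps label -1 (unassigned)
// only in the degenerate case of no covering window; a final sweep assigns
// such pixels to the nearest center globally.
// [[Rcpp::export]]
List slic_iterate_cpp(NumericMatrix L, NumericMatrix A, NumericMatrix B,
                      NumericMatrix centers0, double S, double m,
                      int max_iter) {
  const int H = L.nrow(), W = L.ncol();
  const int K = centers0.nrow();
  NumericMatrix centers = clone(centers0);
  std::vector<int> label(H * W, -1);
  std::vector<double> dist(H * W);
  const double invS2 = (m / S) * (m / S);
  const int win = (int)(2.0 * S + 0.5);

  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(label.begin(), label.end(), -1);
    for (int k = 0; k < K; ++k) {
      const double cl = centers(k, 0), ca = centers(k, 1), cb = centers(k, 2);
      const double cx = centers(k, 3), cy = centers(k, 4);
      const int x0 = std::max(0, (int)std::floor(cx) - win);
      const int x1 = std::min(W - 1, (int)std::ceil(cx) + win);
      const int y0 = std::max(0, (int)std::floor(cy) - win);
      const int y1 = std::min(H - 1, (int)std::ceil(cy) + win);
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          const double dl = L(y, x) - cl, da = A(y, x) - ca, db = B(y, x) - cb;
          const double dx = x - cx, dy = y - cy;
          const double d = dl * dl + da * da + db * db +
                           invS2 * (dx * dx + dy * dy);
          const int idx = y + x * H;
          if (d < dist[idx]) {  // strict: ties keep the lower center index
            dist[idx] = d;
            label[idx] = k;
          }
        }
      }
    }
    // pixels missed by every window -> nearest center globally
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        const int idx = y + x * H;
        if (label[idx] >= 0) continue;
        double best = R_PosInf;
        int bk = 0;
        for (int k = 0; k < K; ++k) {
          const double dl = L(y, x) - centers(k, 0);
          const double da = A(y, x) - centers(k, 1);
          const double db = B(y, x) - centers(k, 2);
          const double dx = x - centers(k, 3), dy = y - centers(k, 4);
          const double d = dl * dl + da * da + db * db +
                           invS2 * (dx * dx + dy * dy);
          if (d < best) { best = d; bk = k; }
        }
        label[idx] = bk;
      }
    }
    // update centers to the mean of their pixels
    std::vector<double> acc(K * 5, 0.0);
    std::vector<int> cnt(K, 0);
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        const int k = label[y + x * H];
        acc[k * 5 + 0] += L(y, x);
        acc[k * 5 + 1] += A(y, x);
        acc[k * 5 + 2] += B(y, x);
        acc[k * 5 + 3] += x;
        acc[k * 5 + 4] += y;
        cnt[k]++;
      }
    }
    for (int k = 0; k < K; ++k) {
      if (cnt[k] == 0) continue;  // empty cluster keeps its old center
      for (int c = 0; c < 5; ++c) centers(k, c) = acc[k * 5 + c] / cnt[k];
    }
  }

  IntegerMatrix lab(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      lab(y, x) = label[y + x * H];
  return List::create(_["labels"] = lab, _["centers"] = centers);
}

// 4-connected component labelling of an integer label map. Components are
// numbered 1..C in row-major order of their first pixel (deterministic).
// [[Rcpp::export]]
IntegerMatrix connected_components_cpp(IntegerMatrix labels) {
  const int H = labels.nrow(), W = labels.ncol();
  IntegerMatrix comp(H, W);
  std::fill(comp.begin(), comp.end(), 0);
  int next = 0;
  std::deque<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (comp(i, j) != 0) continue;
      const int lab = labels(i, j);
      ++next;
      comp(i, j) = next;
      q.clear();
      q.push_back(std::make_pair(i, j));
      while (!q.empty()) {
        const int y = q.front().first, x = q.front().second;
        q.pop_front();
        const int dy[4] = { -1, 1, 0, 0 };
        const int dx[4] = { 0, 0, -1, 1 };
        for (int d = 0; d < 4; ++d) {
          const int ny = y + dy[d], nx = x + dx[d];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (comp(ny, nx) == 0 && labels(ny, nx) == lab) {
            comp(ny, nx) = next;
            q.push_back(std::make_pair(ny, nx));
          }
        }
      }
    }
  }
  return comp;
}
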