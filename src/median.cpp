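#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Half-sample symmetric reflection into [0, n): ... 2 1 0 | 0 1 2 ...
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int window) {
  const int H = img.nrow(), W = img.ncol();
  const int r = window / 2;
  const int wsz = window * window;
  NumericMatrix out(H, W);
  std::vector<double> buf(wsz);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int k = 0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = reflect(j + dj, W);
        for (int di = -r; di <= r; ++di) {
          buf[k++] = img(reflect(i + di, H), jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + wsz / 2, buf.begin() + wsz);
      out(i, j) = buf[wsz / 2];
    }
  }
  return out;
}
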