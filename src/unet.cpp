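// Encoder-decoder segmentation network (VGG-style encoder, U-Net decoder).
// Dense layers only at the level a desk CPU needs: im2col 3x3 convolutions,
// 2x2 max-pooling with argmax, nearest-neighbour upsampling with skip
// concatenation, sigmoid head, binary cross-entropy. Forward and backward
// passes are exact; the optimizer (Adam) lives on the R side.
//
// Weight layout (R builds the list in this exact order):
//   encoder stages s=1..4 with {2,2,3,3} convs (first conv of a stage maps
//   prev->w_s), bottleneck conv (w_4 -> B), decoder stages s=4..1 with 2
//   convs each (first maps prev+w_s -> w_s), final 1x1 conv (w_1 -> 1).
// Each element: list(W = (k*k*cin) x cout matrix, b = length-cout vector).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <array>
using namespace Rcpp;
using namespace arma;

static const int CONVS_PER_STAGE[4] = {2, 2, 3, 3};
static const int DEC_CONVS = 2;
static const double BCE_EPS = 1e-7;

static void im2col(const cube& X, int k, mat& out) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices, r = k / 2;
  out.zeros(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    int col = c * k * k;
    for (int dx = -r; dx <= r; ++dx) {
      for (int dy = -r; dy <= r; ++dy, ++col) {
        const int y0 = std::max(0, -dy), y1 = H - 1 - std::max(0, dy);
        const int x0 = std::max(0, -dx), x1 = W - 1 - std::max(0, dx);
        if (y0 > y1 || x0 > x1) continue;
        mat view(out.colptr(col), H, W, false, true);
        view.submat(y0, x0, y1, x1) =
            S.submat(y0 + dy, x0 + dx, y1 + dy, x1 + dx);
      }
    }
  }
}

static void col2im(const mat& dXc, int H, int W, int C, int k, cube& dX) {
  const int r = k / 2;
  dX.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    mat& S = dX.slice(c);
    int col = c * k * k;
    for (int dx = -r; dx <= r; ++dx) {
      for (int dy = -r; dy <= r; ++dy, ++col) {
        const int y0 = std::max(0, -dy), y1 = H - 1 - std::max(0, dy);
        const int x0 = std::max(0, -dx), x1 = W - 1 - std::max(0, dx);
        if (y0 > y1 || x0 > x1) continue;
        const mat view(const_cast<double*>(dXc.colptr(col)), H, W, false, true);
        S.submat(y0 + dy, x0 + dx, y1 + dy, x1 + dx) +=
            view.submat(y0, x0, y1, x1);
      }
    }
  }
}

static cube conv_fwd(const cube& X, const mat& Wm, const rowvec& b, int k,
                     bool relu, mat& Xc) {
  im2col(X, k, Xc);
  mat Ym = Xc * Wm;
  Ym.each_row() += b;
  if (relu) Ym.clamp(0.0, datum::inf);
  return cube(Ym.memptr(), X.n_rows, X.n_cols, Wm.n_cols);
}

// dY is consumed through the relu mask of the stored (post-activation)
// output; returns dX when need_dx.
static cube conv_bwd(const cube& dYc, const cube& Yout, bool relu,
                     const mat& Xc, const mat& Wm, int k, int Cin,
                     mat& dW, rowvec& db, bool need_dx) {
  const int H = dYc.n_rows, W = dYc.n_cols, Cout = dYc.n_slices;
  mat dYm(const_cast<double*>(dYc.memptr()), H * W, Cout);  // copies
  if (relu) {
    const mat Ym(const_cast<double*>(Yout.memptr()), H * W, Cout, false, true);
    dYm.elem(find(Ym <= 0)).zeros();
  }
  dW = Xc.t() * dYm;
  db = sum(dYm, 0);
  cube dX;
  if (need_dx) {
    mat dXc = dYm * Wm.t();
    col2im(dXc, H, W, Cin, k, dX);
  }
  return dX;
}

static cube pool_fwd(const cube& X, ucube& amax) {
  const int h = X.n_rows / 2, w = X.n_cols / 2, C = X.n_slices;
  cube Y(h, w, C);
  amax.set_size(h, w, C);
  for (int c = 0; c < C; ++c) {
    for (int x = 0; x < w; ++x) {
      for (int y = 0; y < h; ++y) {
        double best = -datum::inf;
        int bi = 0;
        for (int dx = 0; dx < 2; ++dx) {
          for (int dy = 0; dy < 2; ++dy) {
            const double v = X(2 * y + dy, 2 * x + dx, c);
            if (v > best) { best = v; bi = dy + 2 * dx; }
          }
        }
        Y(y, x, c) = best;
        amax(y, x, c) = bi;
      }
    }
  }
  return Y;
}

static cube pool_bwd(const cube& dY, const ucube& amax, int H, int W) {
  const int h = dY.n_rows, w = dY.n_cols, C = dY.n_slices;
  cube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        const int bi = amax(y, x, c);
        dX(2 * y + bi % 2, 2 * x + bi / 2, c) += dY(y, x, c);
      }
  return dX;
}

static cube up_fwd(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube Y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < 2 * W; ++x)
      for (int y = 0; y < 2 * H; ++y)
        Y(y, x, c) = X(y / 2, x / 2, c);
  return Y;
}

static cube up_bwd(const cube& dY) {
  const int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  cube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < 2 * W; ++x)
      for (int y = 0; y < 2 * H; ++y)
        dX(y / 2, x / 2, c) += dY(y, x, c);
  return dX;
}

struct Net {
  std::vector<mat> W;
  std::vector<rowvec> b;
};

static Net parse_weights(List weights) {
  Net net;
  for (int i = 0; i < weights.size(); ++i) {
    List l = weights[i];
    net.W.push_back(as<mat>(l["W"]));
    vec bv = as<vec>(l["b"]);
    net.b.push_back(rowvec(bv.t()));
  }
  return net;
}

// One sample: forward always; if t != nullptr also backward, accumulating
// parameter gradients into gW/gb and loss/accuracy into *loss / *acc.
static mat pass_one(const Net& net, const cube& x, const mat* t,
                    std::vector<mat>* gW, std::vector<rowvec>* gb,
                    double* loss, double* acc) {
  const int nl = net.W.size();
  std::vector<mat> Xc(nl);
  std::vector<cube> Out(nl);
  std::vector<int> cin(nl), kk(nl);
  std::vector<cube> skip(4);
  std::vector<ucube> amax(4);
  std::vector<std::array<int, 2> > pdims(4);
  std::vector<int> upch(4);

  int li = 0;
  cube cur = x;
  for (int s = 0; s < 4; ++s) {
    for (int c = 0; c < CONVS_PER_STAGE[s]; ++c) {
      cin[li] = cur.n_slices; kk[li] = 3;
      cur = conv_fwd(cur, net.W[li], net.b[li], 3, true, Xc[li]);
      Out[li] = cur; ++li;
    }
    skip[s] = cur;
    pdims[s][0] = cur.n_rows; pdims[s][1] = cur.n_cols;
    cur = pool_fwd(cur, amax[s]);
  }
  cin[li] = cur.n_slices; kk[li] = 3;
  cur = conv_fwd(cur, net.W[li], net.b[li], 3, true, Xc[li]);  // bottleneck
  Out[li] = cur; ++li;
  for (int s = 3; s >= 0; --s) {
    cube up = up_fwd(cur);
    upch[s] = up.n_slices;
    cur = join_slices(up, skip[s]);
    for (int c = 0; c < DEC_CONVS; ++c) {
      cin[li] = cur.n_slices; kk[li] = 3;
      cur = conv_fwd(cur, net.W[li], net.b[li], 3, true, Xc[li]);
      Out[li] = cur; ++li;
    }
  }
  cin[li] = cur.n_slices; kk[li] = 1;
  cur = conv_fwd(cur, net.W[li], net.b[li], 1, false, Xc[li]);  // logits
  Out[li] = cur; ++li;

  mat z = cur.slice(0);
  mat p = 1.0 / (1.0 + exp(-z));

  if (t == nullptr) return p;

  const double n = p.n_elem;
  mat pc = clamp(p, BCE_EPS, 1.0 - BCE_EPS);
  *loss += accu(-(*t) % log(pc) - (1.0 - *t) % log(1.0 - pc)) / n;
  *acc += accu(conv_to<mat>::from(p >= 0.5) == *t) / n;

  // backward
  mat dz = (p - *t) / n;
  cube d(z.n_rows, z.n_cols, 1);
  d.slice(0) = dz;
  mat dWl; rowvec dbl;
  --li;
  d = conv_bwd(d, Out[li], false, Xc[li], net.W[li], 1, cin[li], dWl, dbl, true);
  (*gW)[li] += dWl; (*gb)[li] += dbl;
  std::vector<cube> dskip(4);
  for (int s = 0; s < 4; ++s) {  // decoder stages in reverse creation order
    for (int c = 0; c < DEC_CONVS; ++c) {
      --li;
      d = conv_bwd(d, Out[li], true, Xc[li], net.W[li], 3, cin[li], dWl, dbl, true);
      (*gW)[li] += dWl; (*gb)[li] += dbl;
    }
    dskip[s] = d.slices(upch[s], d.n_slices - 1);
    d = up_bwd(d.slices(0, upch[s] - 1));
  }
  --li;  // bottleneck
  d = conv_bwd(d, Out[li], true, Xc[li], net.W[li], 3, cin[li], dWl, dbl, true);
  (*gW)[li] += dWl; (*gb)[li] += dbl;
  for (int s = 3; s >= 0; --s) {
    d = pool_bwd(d, amax[s], pdims[s][0], pdims[s][1]);
    d += dskip[s];
    for (int c = 0; c < CONVS_PER_STAGE[s]; ++c) {
      --li;
      d = conv_bwd(d, Out[li], true, Xc[li], net.W[li], 3, cin[li], dWl, dbl,
                   li > 0);
      (*gW)[li] += dWl; (*gb)[li] += dbl;
    }
  }
  return p;
}

// [[Rcpp::export]]
NumericMatrix unet_predict_cpp(List weights, NumericVector x, int H, int W) {
  Net net = parse_weights(weights);
  cube xc(x.begin(), H, W, 3);
  mat p = pass_one(net, xc, nullptr, nullptr, nullptr, nullptr, nullptr);
  return wrap(p);
}

// Mean loss/accuracy and mean parameter gradients over a minibatch.
// xs: list of H x W x 3 arrays (already scaled to [0,1]); ts: list of
// H x W binary matrices.
// [[Rcpp::export]]
List unet_batch_grad_cpp(List weights, List xs, List ts) {
  Net net = parse_weights(weights);
  const int nl = net.W.size();
  std::vector<mat> gW(nl);
  std::vector<rowvec> gb(nl);
  for (int i = 0; i < nl; ++i) {
    gW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    gb[i].zeros(net.b[i].n_elem);
  }
  double loss = 0.0, acc = 0.0;
  const int B = xs.size();
  for (int i = 0; i < B; ++i) {
    NumericVector xv = xs[i];
    IntegerVector dims = as<IntegerVector>(as<RObject>(xv).attr("dim"));
    cube xc(xv.begin(), dims[0], dims[1], 3);
    mat t = as<mat>(ts[i]);
    pass_one(net, xc, &t, &gW, &gb, &loss, &acc);
  }
  List grads(nl);
  for (int i = 0; i < nl; ++i)
    grads[i] = List::create(_["W"] = gW[i] / B, _["b"] = vec(gb[i].t() / B));
  return List::create(_["loss"] = loss / B, _["accuracy"] = acc / B,
                      _["grads"] = grads);
}

// Loss/accuracy only (validation); no gradient work beyond the forward pass.
// [[Rcpp::export]]
List unet_batch_eval_cpp(List weights, List xs, List ts) {
  Net net = parse_weights(weights);
  double loss = 0.0, acc = 0.0;
  const int B = xs.size();
  for (int i = 0; i < B; ++i) {
    NumericVector xv = xs[i];
    IntegerVector dims = as<IntegerVector>(as<RObject>(xv).attr("dim"));
    cube xc(xv.begin(), dims[0], dims[1], 3);
    mat t = as<mat>(ts[i]);
    mat p = pass_one(net, xc, nullptr, nullptr, nullptr, nullptr, nullptr);
    const double n = p.n_elem;
    mat pc = clamp(p, BCE_EPS, 1.0 - BCE_EPS);
    loss += accu(-t % log(pc) - (1.0 - t) % log(1.0 - pc)) / n;
    acc += accu(conv_to<mat>::from(p >= 0.5) == t) / n;
  }
  return List::create(_["loss"] = loss / B, _["accuracy"] = acc / B);
}
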