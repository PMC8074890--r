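// Low-level kernels for the CNN regression engine and the cluster filter.
// Layout convention: image batches are R arrays with dim = c(N, H, W, C),
// i.e. column-major with the sample index fastest. Convolutions are 3x3-style
// same-padding, stride 1, realised as im2col + GEMM per sample.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat im2col(const double *x, int H, int W, int C,
                               int k, int pad) {
  // rows: output pixel (h + H*w), cols: patch entry (kh + k*kw + k*k*c)
  arma::mat out(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        for (int w = 0; w < W; ++w) {
          int iw = w + kw - pad;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            int ih = h + kh - pad;
            if (ih < 0 || ih >= H) continue;
            out(h + H * w, col) = xc[ih + (size_t)H * iw];
          }
        }
      }
    }
  }
  return out;
}

static inline void col2im_add(const arma::mat &cols, double *x, int H, int W,
                              int C, int k, int pad) {
  for (int c = 0; c < C; ++c) {
    double *xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        for (int w = 0; w < W; ++w) {
          int iw = w + kw - pad;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            int ih = h + kh - pad;
            if (ih < 0 || ih >= H) continue;
            xc[ih + (size_t)H * iw] += cols(h + H * w, col);
          }
        }
      }
    }
  }
}

// gather sample n from [N,H,W,C] into contiguous [H,W,C]
static inline void gather_sample(const double *X, int n, int N, int HWC,
                                 double *out) {
  for (int i = 0; i < HWC; ++i) out[i] = X[(size_t)n + (size_t)N * i];
}

static inline void scatter_sample(const double *in, int n, int N, int HWC,
                                  double *X) {
  for (int i = 0; i < HWC; ++i) X[(size_t)n + (size_t)N * i] = in[i];
}

// fill im2col rows for one sample into a preallocated block; writes every
// entry (zeros at padded positions), so the workspace needs no pre-zeroing
static inline void im2col_into(const double *x, int H, int W, int C, int k,
                               int pad, arma::mat &out, size_t row0) {
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        double *oc = out.colptr(col) + row0;
        int h0 = std::max(0, pad - kh), h1 = std::min(H, H + pad - kh);
        for (int w = 0; w < W; ++w) {
          int iw = w + kw - pad;
          double *dst = oc + (size_t)H * w;
          if (iw < 0 || iw >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double *src = xc + (size_t)H * iw;
          for (int h = 0; h < h0; ++h) dst[h] = 0.0;
          for (int h = h0; h < h1; ++h) dst[h] = src[h + kh - pad];
          for (int h = h1; h < H; ++h) dst[h] = 0.0;
        }
      }
    }
  }
}

// samples per internal chunk so the im2col workspace stays modest (~48 MB)
static inline int conv_chunk(int N, size_t HW, int kkC) {
  size_t per = HW * (size_t)kkC * 8;
  int n = (int)std::max((size_t)1, (size_t)(48u * 1024u * 1024u) / per);
  return std::min(N, n);
}

// persistent im2col workspace: reused across calls so large pages are
// faulted in once, not every mini-batch
static arma::mat &conv_workspace(size_t rows, size_t cols_n) {
  static arma::mat ws;
  if (ws.n_rows < rows || ws.n_cols < cols_n)
    ws.zeros(std::max(rows, (size_t)ws.n_rows),
             std::max(cols_n, (size_t)ws.n_cols));
  return ws;
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector X, NumericMatrix Wm,
                             NumericVector b, int k, int pad) {
  IntegerVector d = X.attr("dim");
  int N = d[0], H = d[1], W = d[2], C = d[3];
  int F = Wm.ncol();
  if (Wm.nrow() != k * k * C) stop("weight matrix rows != k*k*C");
  NumericVector Y(N * (size_t)H * W * F);
  Y.attr("dim") = IntegerVector::create(N, H, W, F);
  arma::mat Wa(Wm.begin(), Wm.nrow(), F, false);
  arma::rowvec ba(b.begin(), F);
  size_t HW = (size_t)H * W;
  int chunk = conv_chunk(N, HW, k * k * C);
  arma::mat &cols = conv_workspace(HW * chunk, k * k * C);
  std::vector<double> xs(HW * C);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    int nb = std::min(chunk, N - n0);
    for (int j = 0; j < nb; ++j) {
      gather_sample(X.begin(), n0 + j, N, HW * C, xs.data());
      im2col_into(xs.data(), H, W, C, k, pad, cols, HW * j);
    }
    arma::mat y = cols.submat(0, 0, HW * nb - 1, k * k * C - 1) * Wa;
    y.each_row() += ba;
    for (int j = 0; j < nb; ++j)
      for (int f = 0; f < F; ++f) {
        const double *src = y.colptr(f) + HW * j;
        double *dst = Y.begin();
        size_t base = (size_t)N * (HW * (size_t)f);
        for (size_t i = 0; i < HW; ++i)
          dst[(size_t)(n0 + j) + base + (size_t)N * i] = src[i];
      }
  }
  return Y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector X, NumericMatrix Wm, NumericVector dY,
                     int k, int pad) {
  IntegerVector d = X.attr("dim");
  int N = d[0], H = d[1], W = d[2], C = d[3];
  int F = Wm.ncol();
  NumericVector dX(X.size());
  dX.attr("dim") = d;
  arma::mat Wa(Wm.begin(), Wm.nrow(), F, false);
  arma::mat dW(k * k * C, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  size_t HW = (size_t)H * W;
  int chunk = conv_chunk(N, HW, k * k * C);
  arma::mat &cols = conv_workspace(HW * chunk, k * k * C);
  std::vector<double> xs(HW * C), dxs(HW * C), dys(HW * F);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    int nb = std::min(chunk, N - n0);
    arma::mat dyv(HW * nb, F);
    for (int j = 0; j < nb; ++j) {
      gather_sample(X.begin(), n0 + j, N, HW * C, xs.data());
      im2col_into(xs.data(), H, W, C, k, pad, cols, HW * j);
      gather_sample(dY.begin(), n0 + j, N, HW * F, dys.data());
      for (int f = 0; f < F; ++f)
        std::copy(dys.data() + HW * f, dys.data() + HW * (f + 1),
                  dyv.colptr(f) + HW * j);
    }
    dW += cols.submat(0, 0, HW * nb - 1, k * k * C - 1).t() * dyv;
    db += arma::sum(dyv, 0);
    arma::mat dcols = dyv * Wa.t();
    for (int j = 0; j < nb; ++j) {
      std::fill(dxs.begin(), dxs.end(), 0.0);
      arma::mat drow(HW, k * k * C);
      for (int cc = 0; cc < k * k * C; ++cc)
        std::copy(dcols.colptr(cc) + HW * j, dcols.colptr(cc) + HW * (j + 1),
                  drow.colptr(cc));
      col2im_add(drow, dxs.data(), H, W, C, k, pad);
      scatter_sample(dxs.data(), n0 + j, N, HW * C, dX.begin());
    }
  }
  return List::create(_["dX"] = dX,
                      _["dW"] = NumericMatrix(dW.n_rows, dW.n_cols,
                                              dW.memptr()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2. Returns pooled values and flat argmax indices
// (1-based, into the [N,H,W,C] input) for the backward pass.
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector X) {
  IntegerVector d = X.attr("dim");
  int N = d[0], H = d[1], W = d[2], C = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector Y((size_t)N * Ho * Wo * C);
  Y.attr("dim") = IntegerVector::create(N, Ho, Wo, C);
  NumericVector amax(Y.size());  // double to avoid 32-bit overflow worries
  const double *x = X.begin();
  double *y = Y.begin();
  double *am = amax.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int n = 0; n < N; ++n) {
          double best = -1e300; size_t bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              size_t idx = (size_t)n +
                           (size_t)N * ((2 * ho + dh) +
                                        (size_t)H * ((2 * wo + dw) +
                                                     (size_t)W * c));
              if (x[idx] > best) { best = x[idx]; bi = idx; }
            }
          size_t o = (size_t)n +
                     (size_t)N * (ho + (size_t)Ho * (wo + (size_t)Wo * c));
          y[o] = best;
          am[o] = (double)(bi + 1);
        }
  return List::create(_["Y"] = Y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dY, NumericVector argmax,
                                IntegerVector in_dim) {
  NumericVector dX((size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dX.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dY.size(); ++i)
    dX[(size_t)argmax[i] - 1] += dY[i];
  return dX;
}

// Connected-component labeling of the solid (== 1) phase of a 2D/3D binary
// grid. connectivity: in 3D, 6 (faces) or 26 (faces+edges+corners); in 2D,
// 4 or 8 (accepted aliases of 6 / 26). Returns integer labels, 0 = background.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(IntegerVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int nd = d.size();
  if (nd != 2 && nd != 3) stop("mask must be 2D or 3D");
  int nx = d[0], ny = d[1], nz = (nd == 3) ? d[2] : 1;
  bool full = (connectivity == 26 || connectivity == 8);
  if (!full && connectivity != 6 && connectivity != 4)
    stop("connectivity must be one of 4, 6, 8, 26");

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (nd == 2 && dz != 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (!full && manh != 1) continue;
        off.push_back(dx); off.push_back(dy); off.push_back(dz);
      }

  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = d;
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < (size_t)mask.size(); ++s) {
    if (mask[s] != 1 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      size_t cur = q.front(); q.pop();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((size_t)nx * ny);
      for (size_t j = 0; j < off.size(); j += 3) {
        int xx = x + off[j], yy = y + off[j + 1], zz = z + off[j + 2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        size_t nb = xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (mask[nb] == 1 && lab[nb] == 0) { lab[nb] = next; q.push(nb); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
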