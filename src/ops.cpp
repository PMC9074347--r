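// Low-level kernels for the 2D segmentation network.
//
// Tensor layout throughout: column-major R arrays of dim (C, H, W, N) —
// channels fastest, then rows, columns, batch.  Convolution weights are
// passed as a (Cout x Cin*k*k) matrix whose column order matches the
// im2col row order used here (channel fastest, then kernel row, kernel
// column), i.e. `dim(W) <- c(Cout, Cin*k*k)` of an R array with dim
// (Cout, Cin, k, k).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void get_dims4(const NumericVector &x, int &C, int &H, int &W, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d tensor (C, H, W, N)");
  C = d[0]; H = d[1]; W = d[2]; N = d[3];
}

// Gather im2col patches for one sample into P (Cin*k*k x H*W), zero padding.
static void im2col(const double *x, int C, int H, int W, int k, int pad,
                   arma::mat &P) {
  P.zeros();
  for (int j = 0; j < W; ++j) {
    for (int dw = 0; dw < k; ++dw) {
      int jj = j + dw - pad;
      if (jj < 0 || jj >= W) continue;
      for (int dh = 0; dh < k; ++dh) {
        int rbase = C * (dh + k * dw);
        for (int i = 0; i < H; ++i) {
          int ii = i + dh - pad;
          if (ii < 0 || ii >= H) continue;
          const double *src = x + C * (ii + H * jj);
          double *dst = P.colptr(i + H * j) + rbase;
          std::copy(src, src + C, dst);
        }
      }
    }
  }
}

// Scatter-add of dP back onto dx (col2im), mirroring im2col.
static void col2im(const arma::mat &dP, int C, int H, int W, int k, int pad,
                   double *dx) {
  for (int j = 0; j < W; ++j) {
    for (int dw = 0; dw < k; ++dw) {
      int jj = j + dw - pad;
      if (jj < 0 || jj >= W) continue;
      for (int dh = 0; dh < k; ++dh) {
        int rbase = C * (dh + k * dw);
        for (int i = 0; i < H; ++i) {
          int ii = i + dh - pad;
          if (ii < 0 || ii >= H) continue;
          const double *src = dP.colptr(i + H * j) + rbase;
          double *dst = dx + C * (ii + H * jj);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector bias,
                         int k, int pad) {
  int C, H, W, N;
  get_dims4(x, C, H, W, N);
  int Cout = w.nrow();
  if (w.ncol() != C * k * k) stop("weight shape does not match input channels");
  arma::mat Wm(w.begin(), Cout, C * k * k, false);
  arma::vec b(bias.begin(), Cout, false);
  NumericVector y(static_cast<R_xlen_t>(Cout) * H * W * N);
  y.attr("dim") = IntegerVector::create(Cout, H, W, N);
  arma::mat P(C * k * k, H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<R_xlen_t>(n) * C * H * W, C, H, W, k, pad, P);
    arma::mat Yn(y.begin() + static_cast<R_xlen_t>(n) * Cout * H * W,
                 Cout, H * W, false, true);
    Yn = Wm * P;
    Yn.each_col() += b;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                int k, int pad) {
  int C, H, W, N;
  get_dims4(x, C, H, W, N);
  int Cout = w.nrow();
  arma::mat Wm(w.begin(), Cout, C * k * k, false);
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  arma::mat dW(Cout, C * k * k, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat P(C * k * k, H * W);
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + static_cast<R_xlen_t>(n) * C * H * W;
    im2col(xn, C, H, W, k, pad, P);
    arma::mat dYn(const_cast<double *>(dy.begin()) +
                      static_cast<R_xlen_t>(n) * Cout * H * W,
                  Cout, H * W, false, true);
    dW += dYn * P.t();
    db += arma::sum(dYn, 1);
    arma::mat dP = Wm.t() * dYn;
    col2im(dP, C, H, W, k, pad,
           dx.begin() + static_cast<R_xlen_t>(n) * C * H * W);
  }
  NumericMatrix dWout(Cout, C * k * k);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  NumericVector dbout(Cout);
  std::copy(db.begin(), db.end(), dbout.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWout, _["db"] = dbout);
}

// 2x2 max pooling, stride 2.  Returns pooled tensor and the 1-based linear
// index (within each sample's (C,H,W) block) of each maximum, for backprop.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  int C, H, W, N;
  get_dims4(x, C, H, W, N);
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(C) * Ho * Wo * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  idx.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + static_cast<R_xlen_t>(n) * C * H * W;
    double *yn = y.begin() + static_cast<R_xlen_t>(n) * C * Ho * Wo;
    int *in = idx.begin() + static_cast<R_xlen_t>(n) * C * Ho * Wo;
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          int bidx = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int pos = c + C * ((2 * io + di) + H * (2 * jo + dj));
              if (xn[pos] > best) { best = xn[pos]; bidx = pos; }
            }
          int opos = c + C * (io + Ho * jo);
          yn[opos] = best;
          in[opos] = bidx + 1;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           IntegerVector in_dim) {
  int C = in_dim[0], H = in_dim[1], W = in_dim[2], N = in_dim[3];
  int Co, Ho, Wo, No;
  { IntegerVector d = dy.attr("dim"); Co = d[0]; Ho = d[1]; Wo = d[2]; No = d[3]; }
  NumericVector dx(static_cast<R_xlen_t>(C) * H * W * N);
  dx.attr("dim") = in_dim;
  R_xlen_t per_out = static_cast<R_xlen_t>(Co) * Ho * Wo;
  R_xlen_t per_in = static_cast<R_xlen_t>(C) * H * W;
  for (int n = 0; n < No; ++n) {
    const double *dyn = dy.begin() + n * per_out;
    const int *in = idx.begin() + n * per_out;
    double *dxn = dx.begin() + n * per_in;
    for (R_xlen_t p = 0; p < per_out; ++p) dxn[in[p] - 1] += dyn[p];
  }
  return dx;
}

// Adaptive max pooling onto a (bins x bins) grid (pyramid-pooling branch).
// [[Rcpp::export(name = ".adaptpool_fwd")]]
List adaptpool_fwd(NumericVector x, int bins) {
  int C, H, W, N;
  get_dims4(x, C, H, W, N);
  if (bins < 1 || bins > H || bins > W) stop("invalid bin count");
  NumericVector y(static_cast<R_xlen_t>(C) * bins * bins * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(C, bins, bins, N);
  idx.attr("dim") = IntegerVector::create(C, bins, bins, N);
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + static_cast<R_xlen_t>(n) * C * H * W;
    double *yn = y.begin() + static_cast<R_xlen_t>(n) * C * bins * bins;
    int *in = idx.begin() + static_cast<R_xlen_t>(n) * C * bins * bins;
    for (int bj = 0; bj < bins; ++bj) {
      int j0 = (bj * W) / bins, j1 = ((bj + 1) * W) / bins;
      for (int bi = 0; bi < bins; ++bi) {
        int i0 = (bi * H) / bins, i1 = ((bi + 1) * H) / bins;
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          int bidx = 0;
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i) {
              int pos = c + C * (i + H * j);
              if (xn[pos] > best) { best = xn[pos]; bidx = pos; }
            }
          int opos = c + C * (bi + bins * bj);
          yn[opos] = best;
          in[opos] = bidx + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Nearest-neighbour upsampling to (outH, outW).
// [[Rcpp::export(name = ".upsample_fwd")]]
NumericVector upsample_fwd(NumericVector x, int outH, int outW) {
  int C, H, W, N;
  get_dims4(x, C, H, W, N);
  NumericVector y(static_cast<R_xlen_t>(C) * outH * outW * N);
  y.attr("dim") = IntegerVector::create(C, outH, outW, N);
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + static_cast<R_xlen_t>(n) * C * H * W;
    double *yn = y.begin() + static_cast<R_xlen_t>(n) * C * outH * outW;
    for (int j = 0; j < outW; ++j) {
      int js = (j * W) / outW;
      for (int i = 0; i < outH; ++i) {
        int is = (i * H) / outH;
        const double *src = xn + C * (is + H * js);
        double *dst = yn + C * (i + outH * j);
        std::copy(src, src + C, dst);
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample_bwd")]]
NumericVector upsample_bwd(NumericVector dy, IntegerVector in_dim) {
  int C = in_dim[0], H = in_dim[1], W = in_dim[2], N = in_dim[3];
  int Co, Ho, Wo, No;
  { IntegerVector d = dy.attr("dim"); Co = d[0]; Ho = d[1]; Wo = d[2]; No = d[3]; }
  NumericVector dx(static_cast<R_xlen_t>(C) * H * W * N);
  dx.attr("dim") = in_dim;
  for (int n = 0; n < No; ++n) {
    const double *dyn = dy.begin() + static_cast<R_xlen_t>(n) * Co * Ho * Wo;
    double *dxn = dx.begin() + static_cast<R_xlen_t>(n) * C * H * W;
    for (int j = 0; j < Wo; ++j) {
      int js = (j * W) / Wo;
      for (int i = 0; i < Ho; ++i) {
        int is = (i * H) / Ho;
        const double *src = dyn + Co * (i + Ho * j);
        double *dst = dxn + C * (is + H * js);
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
  return dx;
}
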