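// Low-level CPU kernels: im2col convolution, 2x2 max pooling, nearest
// upsampling and connected-component labelling. Arrays are column-major
// R arrays of dim (H, W, C, N); weights (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int Cin, int kh, int kw,
                   arma::mat& col) {
  // col: (kh*kw*Cin) x (H*W), zero padding to keep spatial size
  const int ph = kh / 2, pw = kw / 2;
  col.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int kr = di + kh * (dj + kw * ci);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dj - pw;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int ih = h + di - ph;
            if (ih < 0 || ih >= H) continue;
            col(kr, h + H * w) = xc[ih + H * iw];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int Cin,
                       int kh, int kw, double* dx) {
  const int ph = kh / 2, pw = kw / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dx + (size_t)ci * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int kr = di + kh * (dj + kw * ci);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dj - pw;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int ih = h + di - ph;
            if (ih < 0 || ih >= H) continue;
            xc[ih + H * iw] += col(kr, h + H * w);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cg_conv2d_fwd")]]
NumericVector cg_conv2d_fwd(NumericVector X, NumericVector Wt, NumericVector b) {
  IntegerVector dx = X.attr("dim"), dw = Wt.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  const int K = kh * kw * Cin, HW = H * W;
  NumericVector Y((size_t)HW * Cout * N);
  Y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(Wt.begin()), K, Cout, false, true);
  arma::mat col(K, HW);
  arma::mat Ym(Cout, HW);
  for (int n = 0; n < N; ++n) {
    im2col(X.begin() + (size_t)n * HW * Cin, H, W, Cin, kh, kw, col);
    Ym = Wm.t() * col;
    double* yp = Y.begin() + (size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      for (int p = 0; p < HW; ++p) yp[p + (size_t)co * HW] = Ym(co, p) + bc;
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".cg_conv2d_bwd")]]
List cg_conv2d_bwd(NumericVector X, NumericVector Wt, NumericVector dY) {
  IntegerVector dx = X.attr("dim"), dw = Wt.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  const int K = kh * kw * Cin, HW = H * W;
  arma::mat Wm(const_cast<double*>(Wt.begin()), K, Cout, false, true);
  NumericVector dX((size_t)HW * Cin * N);
  dX.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat dWm(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(K, HW), dYm(Cout, HW), colg(K, HW);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dY.begin() + (size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      double s = 0.0;
      for (int p = 0; p < HW; ++p) {
        const double v = dyp[p + (size_t)co * HW];
        dYm(co, p) = v;
        s += v;
      }
      db[co] += s;
    }
    im2col(X.begin() + (size_t)n * HW * Cin, H, W, Cin, kh, kw, col);
    dWm += col * dYm.t();
    colg = Wm * dYm;
    col2im_add(colg, H, W, Cin, kh, kw, dX.begin() + (size_t)n * HW * Cin);
  }
  NumericVector dWout(dWm.begin(), dWm.end());
  dWout.attr("dim") = dw;
  return List::create(_["dX"] = dX, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".cg_maxpool_fwd")]]
List cg_maxpool_fwd(NumericVector X) {
  IntegerVector dx = X.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector Y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = X.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const size_t xo = (size_t)cn * H * W, yo = (size_t)cn * Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        int best = 2 * h + H * (2 * w);
        double bv = xp[xo + best];
        const int cand[3] = {2 * h + 1 + H * (2 * w), 2 * h + H * (2 * w + 1),
                             2 * h + 1 + H * (2 * w + 1)};
        for (int k = 0; k < 3; ++k)
          if (xp[xo + cand[k]] > bv) { bv = xp[xo + cand[k]]; best = cand[k]; }
        Y[yo + h + Ho * w] = bv;
        idx[yo + h + Ho * w] = best;  // offset within the (H,W) slab
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cg_maxpool_bwd")]]
NumericVector cg_maxpool_bwd(NumericVector dY, IntegerVector idx, int H, int W) {
  IntegerVector dy = dY.attr("dim");
  const int Ho = dy[0], Wo = dy[1], C = dy[2], N = dy[3];
  NumericVector dX((size_t)H * W * C * N);
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const size_t xo = (size_t)cn * H * W, yo = (size_t)cn * Ho * Wo;
    for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
      dX[xo + idx[yo + p]] += dY[yo + p];
  }
  return dX;
}

// [[Rcpp::export(name = ".cg_upsample2_fwd")]]
NumericVector cg_upsample2_fwd(NumericVector X) {
  IntegerVector dx = X.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector Y((size_t)Ho * Wo * C * N);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const size_t xo = (size_t)cn * H * W, yo = (size_t)cn * Ho * Wo;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = X[xo + h + H * w];
        const size_t b = yo + 2 * h + Ho * (2 * w);
        Y[b] = v; Y[b + 1] = v; Y[b + Ho] = v; Y[b + Ho + 1] = v;
      }
  }
  return Y;
}

// [[Rcpp::export(name = ".cg_upsample2_bwd")]]
NumericVector cg_upsample2_bwd(NumericVector dY) {
  IntegerVector dy = dY.attr("dim");
  const int Ho = dy[0], Wo = dy[1], C = dy[2], N = dy[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dX((size_t)H * W * C * N);
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const size_t xo = (size_t)cn * H * W, yo = (size_t)cn * Ho * Wo;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const size_t b = yo + 2 * h + Ho * (2 * w);
        dX[xo + h + H * w] = dY[b] + dY[b + 1] + dY[b + Ho] + dY[b + Ho + 1];
      }
  }
  return dX;
}

// [[Rcpp::export(name = ".cg_label_components")]]
IntegerMatrix cg_label_components(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  // scan column-major so ties on "first pixel" follow R's linear index order
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      ++next;
      lab(h, w) = next;
      stack.push_back(h + H * w);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int ph = p % H, pw = p / H;
        for (int k = 0; k < nn; ++k) {
          const int qh = ph + dr[k], qw = pw + dc[k];
          if (qh < 0 || qh >= H || qw < 0 || qw >= W) continue;
          if (mask(qh, qw) != 0 && lab(qh, qw) == 0) {
            lab(qh, qw) = next;
            stack.push_back(qh + H * qw);
          }
        }
      }
    }
  }
  return lab;
}
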