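// Minimal convolutional-network kernels: same-padding conv2d and max-pooling
// forward/backward passes over image batches, via im2col + GEMM. Batches are
// R arrays of dim (H, W, C, N), column-major. Filter matrices are
// (K*K*C_in) x F with row index di + K*dj + K*K*c.
//
// The im2col buffer is laid out (H*W) x (K*K*C): output pixel p = i + j*H is
// the row, so every (di, dj, c) tap fills contiguous column segments and the
// forward product cols * W lands directly in the (H, W, F) output layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col(const double* x, int H, int W, int C, int K, mat& cols) {
  const int pad = K / 2;
  const size_t HW = (size_t)H * W;
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int dj = 0; dj < K; ++dj) {
      for (int di = 0; di < K; ++di) {
        double* col = cols.colptr(di + K * dj + K * K * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          const double* src = xc + (size_t)sj * H + (di - pad);
          double* dst = col + (size_t)j * H;
          const int i0 = std::max(0, pad - di);
          const int i1 = std::min(H, H + pad - di);
          std::copy(src + i0, src + i1, dst + i0);
        }
      }
    }
  }
}

static void col2im_add(const mat& cols, int H, int W, int C, int K,
                       double* x) {
  const int pad = K / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * HW;
    for (int dj = 0; dj < K; ++dj) {
      for (int di = 0; di < K; ++di) {
        const double* col = cols.colptr(di + K * dj + K * K * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          double* dst = xc + (size_t)sj * H + (di - pad);
          const double* src = col + (size_t)j * H;
          const int i0 = std::max(0, pad - di);
          const int i1 = std::min(H, H + pad - di);
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

static Rcpp::IntegerVector dims4(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("expected a 4D (H, W, C, N) array");
  return d;
}

// [[Rcpp::export(name = ".conv2d_forward")]]
Rcpp::NumericVector conv2d_forward(Rcpp::NumericVector x,
                                   Rcpp::NumericMatrix w,
                                   Rcpp::NumericVector b, int K) {
  Rcpp::IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = w.ncol();
  if (w.nrow() != K * K * C) Rcpp::stop("filter matrix rows != K*K*C");
  const size_t HW = (size_t)H * W;
  Rcpp::NumericVector out(HW * F * N);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, F, N);
  const mat wm(const_cast<double*>(w.begin()), w.nrow(), F, false, true);
  const rowvec bv(const_cast<double*>(b.begin()), F, false, true);
  mat cols(HW, (size_t)K * K * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, K, cols);
    mat y(out.begin() + (size_t)n * HW * F, HW, F, false, true);
    y = cols * wm;                  // (H*W) x F, already in output layout
    y.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
Rcpp::List conv2d_backward(Rcpp::NumericVector x, Rcpp::NumericMatrix w,
                           Rcpp::NumericVector dy, int K) {
  Rcpp::IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = w.ncol();
  const size_t HW = (size_t)H * W;
  Rcpp::NumericVector dx(HW * C * N);
  dx.attr("dim") = d;
  const mat wm(const_cast<double*>(w.begin()), w.nrow(), F, false, true);
  mat dw(w.nrow(), F, fill::zeros);
  rowvec db(F, fill::zeros);
  mat cols(HW, (size_t)K * K * C);
  mat dcols(HW, (size_t)K * K * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, K, cols);
    const mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * HW * F,
                  HW, F, false, true);
    dw += cols.t() * dyn;
    db += sum(dyn, 0);
    dcols = dyn * wm.t();
    col2im_add(dcols, H, W, C, K, dx.begin() + (size_t)n * HW * C);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dw,
                            Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool_forward")]]
Rcpp::List maxpool_forward(Rcpp::NumericVector x, int k) {
  Rcpp::IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / k, Wo = W / k;
  if (Ho < 1 || Wo < 1) Rcpp::stop("pooling window larger than input");
  Rcpp::NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C, N);
  Rcpp::IntegerVector idx((size_t)Ho * Wo * C * N); // 0-based into (H*W) plane
  idx.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + (size_t)(n * C + c) * H * W;
      double* oplane = out.begin() + (size_t)(n * C + c) * Ho * Wo;
      int* iplane = idx.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = 0;
          for (int dj = 0; dj < k; ++dj) {
            for (int di = 0; di < k; ++di) {
              const int i = io * k + di, j = jo * k + dj;
              const double v = plane[i + (size_t)j * H];
              if (v > best) { best = v; besti = i + j * H; }
            }
          }
          oplane[io + (size_t)jo * Ho] = best;
          iplane[io + (size_t)jo * Ho] = besti;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
Rcpp::NumericVector maxpool_backward(Rcpp::IntegerVector idx,
                                     Rcpp::NumericVector dy,
                                     Rcpp::IntegerVector in_dim) {
  Rcpp::IntegerVector d = dims4(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = in_dim[0], W = in_dim[1];
  Rcpp::NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = in_dim;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dplane = dy.begin() + (size_t)(n * C + c) * Ho * Wo;
      const int* iplane = idx.begin() + (size_t)(n * C + c) * Ho * Wo;
      double* xplane = dx.begin() + (size_t)(n * C + c) * H * W;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) {
        xplane[iplane[p]] += dplane[p];
      }
    }
  }
  return dx;
}
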