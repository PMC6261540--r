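#include <Rcpp.h>
using namespace Rcpp;

// Activations for spatial layers are stored as (npix * B) x C matrices,
// row index = b * npix + p with p column-major within the square image.
// 3x3 convolutions use "same" zero padding. For each kernel offset
// (di, dj) the source pixel of p = (i, j) is p + dj*side + di, valid on the
// contiguous row range [max(1, 1-di), min(side, side-di)] of each valid
// column, so every inner loop below is a contiguous AXPY/dot pass.
// Kernels are flat vectors indexed [k + 9 * (c + Cin * o)], k = offset index
// with di fastest.

static inline void offset_bounds(int k, int side, int& di, int& dj,
                                 int& i0, int& i1, int& j0, int& j1) {
  di = k % 3 - 1;
  dj = k / 3 - 1;
  i0 = (di < 0) ? 1 - di : 1;
  i1 = (di > 0) ? side - di : side;
  j0 = (dj < 0) ? 1 - dj : 1;
  j1 = (dj > 0) ? side - dj : side;
}

// [[Rcpp::export]]
NumericMatrix conv2d_fwd_cpp(const NumericMatrix& A, const int side,
                             const NumericVector& W, const NumericVector& bias,
                             const int B) {
  const int npix = side * side;
  const int Cin = A.ncol();
  const int Cout = bias.size();
  const R_xlen_t N = (R_xlen_t)npix * B;
  NumericMatrix Y(N, Cout);
  const double* a = A.begin();
  const double* w = W.begin();
  double* y = Y.begin();

  for (int o = 0; o < Cout; ++o) {
    double* yo = y + (R_xlen_t)o * N;
    const double bo = bias[o];
    for (R_xlen_t r = 0; r < N; ++r) yo[r] = bo;
  }
  for (int k = 0; k < 9; ++k) {
    int di, dj, i0, i1, j0, j1;
    offset_bounds(k, side, di, dj, i0, i1, j0, j1);
    const int off = dj * side + di;
    const int len = i1 - i0 + 1;
    for (int c = 0; c < Cin; ++c) {
      const double* ac = a + (R_xlen_t)c * N;
      for (int o = 0; o < Cout; ++o) {
        const double wv = w[k + 9 * (c + (R_xlen_t)Cin * o)];
        if (wv == 0.0) continue;
        double* yo = y + (R_xlen_t)o * N;
        for (int b = 0; b < B; ++b) {
          const R_xlen_t bb = (R_xlen_t)b * npix;
          for (int j = j0; j <= j1; ++j) {
            const R_xlen_t s = bb + (R_xlen_t)(j - 1) * side + (i0 - 1);
            const double* as = ac + s + off;
            double* ys = yo + s;
            for (int t = 0; t < len; ++t) ys[t] += wv * as[t];
          }
        }
      }
    }
  }
  return Y;
}

// Gradients w.r.t. input, kernel and bias.
// [[Rcpp::export]]
List conv2d_bwd_cpp(const NumericMatrix& A, const int side,
                    const NumericVector& W, const NumericMatrix& dY,
                    const int B) {
  const int npix = side * side;
  const int Cin = A.ncol();
  const int Cout = dY.ncol();
  const R_xlen_t N = (R_xlen_t)npix * B;
  NumericMatrix dA(N, Cin);
  NumericVector dW(9 * Cin * Cout);
  NumericVector db(Cout);
  const double* a = A.begin();
  const double* w = W.begin();
  const double* dy = dY.begin();
  double* da = dA.begin();

  for (int k = 0; k < 9; ++k) {
    int di, dj, i0, i1, j0, j1;
    offset_bounds(k, side, di, dj, i0, i1, j0, j1);
    const int off = dj * side + di;
    const int len = i1 - i0 + 1;
    for (int c = 0; c < Cin; ++c) {
      const double* ac = a + (R_xlen_t)c * N;
      double* dac = da + (R_xlen_t)c * N;
      for (int o = 0; o < Cout; ++o) {
        const double wv = w[k + 9 * (c + (R_xlen_t)Cin * o)];
        const double* dyo = dy + (R_xlen_t)o * N;
        double dwacc = 0.0;
        for (int b = 0; b < B; ++b) {
          const R_xlen_t bb = (R_xlen_t)b * npix;
          for (int j = j0; j <= j1; ++j) {
            const R_xlen_t s = bb + (R_xlen_t)(j - 1) * side + (i0 - 1);
            const double* as = ac + s + off;
            double* das = dac + s + off;
            const double* dys = dyo + s;
            for (int t = 0; t < len; ++t) {
              das[t] += wv * dys[t];
              dwacc += as[t] * dys[t];
            }
          }
        }
        dW[k + 9 * (c + (R_xlen_t)Cin * o)] = dwacc;
      }
    }
  }
  for (int o = 0; o < Cout; ++o) {
    double s = 0.0;
    const double* dyo = dy + (R_xlen_t)o * N;
    for (R_xlen_t r = 0; r < N; ++r) s += dyo[r];
    db[o] = s;
  }
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db);
}

// Input gradient only (saliency backprop through a frozen model).
// [[Rcpp::export]]
NumericMatrix conv2d_bwd_input_cpp(const int side, const NumericVector& W,
                                   const NumericMatrix& dY, const int Cin,
                                   const int B) {
  const int npix = side * side;
  const int Cout = dY.ncol();
  const R_xlen_t N = (R_xlen_t)npix * B;
  NumericMatrix dA(N, Cin);
  const double* w = W.begin();
  const double* dy = dY.begin();
  double* da = dA.begin();

  for (int k = 0; k < 9; ++k) {
    int di, dj, i0, i1, j0, j1;
    offset_bounds(k, side, di, dj, i0, i1, j0, j1);
    const int off = dj * side + di;
    const int len = i1 - i0 + 1;
    for (int c = 0; c < Cin; ++c) {
      double* dac = da + (R_xlen_t)c * N;
      for (int o = 0; o < Cout; ++o) {
        const double wv = w[k + 9 * (c + (R_xlen_t)Cin * o)];
        if (wv == 0.0) continue;
        const double* dyo = dy + (R_xlen_t)o * N;
        for (int b = 0; b < B; ++b) {
          const R_xlen_t bb = (R_xlen_t)b * npix;
          for (int j = j0; j <= j1; ++j) {
            const R_xlen_t s = bb + (R_xlen_t)(j - 1) * side + (i0 - 1);
            double* das = dac + s + off;
            const double* dys = dyo + s;
            for (int t = 0; t < len; ++t) das[t] += wv * dys[t];
          }
        }
      }
    }
  }
  return dA;
}

// 2x2/2 max pooling with ceil semantics. pm is npix_out x 4 with 1-based
// member pixel indices of each window (0 = absent). arg records the absolute
// source row in A for backprop.
// [[Rcpp::export]]
List maxpool_fwd_cpp(const NumericMatrix& A, const IntegerMatrix& pm,
                     const int npix_in, const int B) {
  const int npix_out = pm.nrow();
  const int C = A.ncol();
  const R_xlen_t Nout = (R_xlen_t)npix_out * B;
  NumericMatrix Y(Nout, C);
  IntegerMatrix arg(Nout, C);

  for (int c = 0; c < C; ++c) {
    const double* ac = &A(0, c);
    for (int b = 0; b < B; ++b) {
      const R_xlen_t ibase = (R_xlen_t)b * npix_in;
      const R_xlen_t obase = (R_xlen_t)b * npix_out;
      for (int q = 0; q < npix_out; ++q) {
        double best = R_NegInf;
        R_xlen_t best_row = 0;
        for (int m = 0; m < 4; ++m) {
          const int src = pm(q, m);
          if (src == 0) continue;
          const R_xlen_t srow = ibase + src - 1;
          const double v = ac[srow];
          if (v > best) { best = v; best_row = srow; }
        }
        Y(obase + q, c) = best;
        arg(obase + q, c) = (int)(best_row + 1);
      }
    }
  }
  return List::create(_["Y"] = Y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bwd_cpp(const NumericMatrix& dY, const IntegerMatrix& arg,
                              const int npix_in, const int B) {
  const int C = dY.ncol();
  const R_xlen_t Nin = (R_xlen_t)npix_in * B;
  const R_xlen_t Nout = dY.nrow();
  NumericMatrix dA(Nin, C);
  for (int c = 0; c < C; ++c)
    for (R_xlen_t r = 0; r < Nout; ++r)
      dA(arg(r, c) - 1, c) += dY(r, c);
  return dA;
}

// ---- batch normalization (column-wise over the normalization axis) ----

// Training-mode forward: returns Y, xhat, istd and the batch moments.
// [[Rcpp::export]]
List bn_fwd_train_cpp(const NumericMatrix& A, const NumericVector& gamma,
                      const NumericVector& beta, const double eps) {
  const R_xlen_t N = A.nrow();
  const int C = A.ncol();
  NumericMatrix Y(N, C), xhat(N, C);
  NumericVector mu(C), v(C), istd(C);
  for (int c = 0; c < C; ++c) {
    const double* ac = &A(0, c);
    double s = 0.0;
    for (R_xlen_t r = 0; r < N; ++r) s += ac[r];
    const double m = s / N;
    double sv = 0.0;
    for (R_xlen_t r = 0; r < N; ++r) { const double d = ac[r] - m; sv += d * d; }
    const double var = sv / N;
    const double is = 1.0 / std::sqrt(var + eps);
    mu[c] = m; v[c] = var; istd[c] = is;
    const double g = gamma[c], bb = beta[c];
    double* xc = &xhat(0, c);
    double* yc = &Y(0, c);
    for (R_xlen_t r = 0; r < N; ++r) {
      const double xh = (ac[r] - m) * is;
      xc[r] = xh;
      yc[r] = g * xh + bb;
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["istd"] = istd,
                      _["mu"] = mu, _["v"] = v);
}

// Training-mode backward: dX, dgamma, dbeta from the cached xhat/istd.
// [[Rcpp::export]]
List bn_bwd_train_cpp(const NumericMatrix& dY, const NumericMatrix& xhat,
                      const NumericVector& istd, const NumericVector& gamma) {
  const R_xlen_t N = dY.nrow();
  const int C = dY.ncol();
  NumericMatrix dX(N, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = &dY(0, c);
    const double* xc = &xhat(0, c);
    double sg = 0.0, sb = 0.0;
    for (R_xlen_t r = 0; r < N; ++r) { sg += dyc[r] * xc[r]; sb += dyc[r]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c], is = istd[c];
    const double mh = g * sb / N;          // mean of dxhat
    const double mx = g * sg / N;          // mean of dxhat * xhat
    double* dxc = &dX(0, c);
    for (R_xlen_t r = 0; r < N; ++r)
      dxc[r] = is * (g * dyc[r] - mh - xc[r] * mx);
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Inference-mode affine: Y = A * scale[col] + shift[col].
// [[Rcpp::export]]
NumericMatrix affine_cols_cpp(const NumericMatrix& A, const NumericVector& scale,
                              const NumericVector& shift) {
  const R_xlen_t N = A.nrow();
  const int C = A.ncol();
  NumericMatrix Y(N, C);
  for (int c = 0; c < C; ++c) {
    const double* ac = &A(0, c);
    double* yc = &Y(0, c);
    const double s = scale[c], sh = shift[c];
    for (R_xlen_t r = 0; r < N; ++r) yc[r] = s * ac[r] + sh;
  }
  return Y;
}

// ReLU forward; backward is dY * (Y > 0).
// [[Rcpp::export]]
NumericMatrix relu_fwd_cpp(const NumericMatrix& A) {
  const R_xlen_t n = A.size();
  NumericMatrix Y(A.nrow(), A.ncol());
  const double* a = A.begin();
  double* y = Y.begin();
  for (R_xlen_t r = 0; r < n; ++r) y[r] = a[r] > 0 ? a[r] : 0.0;
  return Y;
}

// Elementwise dY masked by positivity of the cached forward output.
// [[Rcpp::export]]
NumericMatrix relu_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& Yfwd) {
  const R_xlen_t n = dY.size();
  NumericMatrix dX(dY.nrow(), dY.ncol());
  const double* dy = dY.begin();
  const double* yf = Yfwd.begin();
  double* dx = dX.begin();
  for (R_xlen_t r = 0; r < n; ++r) dx[r] = yf[r] > 0 ? dy[r] : 0.0;
  return dX;
}
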