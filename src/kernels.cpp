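// Low-level CNN kernels. All feature tensors are R double arrays with
// dim = c(H, W, C, N) (column-major, image row index fastest). Convolution
// weights are matrices of shape (kh*kw*cin) x cout with row index
// ki + kh*(kj + kw*ci); 2x2-stride-2 transpose-conv weights use
// ki + 2*(kj + 2*ci). Max-pool windows are 2x2 stride 2 and the stored
// index codes the argmax position within its window in row-major scan
// order: code = 2*di + dj, first position winning ties.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Convolutions are evaluated as "shifted GEMMs": the image is copied once
// into a zero-padded buffer whose flattened layout makes every kernel tap a
// constant row offset, so a k x k convolution is k^2 GEMM-accumulates and
// no im2col matrix is ever materialized. 1x1 convolutions skip the padding
// copy entirely (one image's channel block is contiguous in memory).

static void pad_into(const arma::cube& xc, int n, int H, int W, int C,
                     int ph, int pw, arma::mat& Xp) {
  const int Hp = H + 2 * ph;
  Xp.zeros();
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = xc.slice((size_t)c + (size_t)C * n);
    double* col = Xp.colptr(c);
    for (int j = 0; j < W; ++j)
      std::memcpy(col + (size_t)(j + pw) * Hp + ph, xs.colptr(j),
                  sizeof(double) * H);
  }
}

static void extract_interior(const arma::mat& Yp, arma::cube& yc, int n,
                             int H, int W, int C, int ph, int pw) {
  const int Hp = H + 2 * ph;
  for (int c = 0; c < C; ++c) {
    arma::mat& ys = yc.slice((size_t)c + (size_t)C * n);
    const double* col = Yp.colptr(c);
    for (int j = 0; j < W; ++j)
      std::memcpy(ys.colptr(j), col + (size_t)(j + pw) * Hp + ph,
                  sizeof(double) * H);
  }
}

static arma::uvec tap_rows(int ki, int kj, int kh, int kw, int C) {
  arma::uvec idx(C);
  for (int c = 0; c < C; ++c) idx[c] = ki + kh * (kj + kw * c);
  return idx;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, const arma::mat& w,
                        const arma::vec& b, int kh, int kw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int cout = (int)w.n_cols;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::cube xc(x.begin(), H, W, (size_t)C * N, false, true);
  NumericVector out((R_xlen_t)(H) * (W) * (cout) * (N));
  out.attr("dim") = IntegerVector::create(H, W, cout, N);
  arma::cube yc(out.begin(), H, W, (size_t)cout * N, false, true);
  const size_t hw = (size_t)H * W;
  if (kh == 1 && kw == 1) {
    for (int n = 0; n < N; ++n) {
      const arma::mat X(const_cast<double*>(x.begin()) + hw * C * n,
                        hw, C, false, true);
      arma::mat Y(out.begin() + hw * cout * n, hw, cout, false, true);
      Y = X * w;
      Y.each_row() += b.t();
    }
    return out;
  }
  const int Hp = H + 2 * ph, Wp = W + 2 * pw;
  const size_t Np = (size_t)Hp * Wp;
  arma::mat Xp(Np, C), Yp(Np, cout);
  for (int n = 0; n < N; ++n) {
    pad_into(xc, n, H, W, C, ph, pw, Xp);
    Yp.zeros();
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const long off = (ki - ph) + (long)Hp * (kj - pw);
        const size_t lo = off < 0 ? (size_t)(-off) : 0;
        const size_t hi = Np - 1 - (off > 0 ? (size_t)off : 0);
        arma::mat Wtap = w.rows(tap_rows(ki, kj, kh, kw, C));
        Yp.rows(lo, hi) += Xp.rows(lo + off, hi + off) * Wtap;
      }
    Yp.each_row() += b.t();
    extract_interior(Yp, yc, n, H, W, cout, ph, pw);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector dy, const arma::mat& w,
               int kh, int kw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int cout = (int)w.n_cols;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::cube xc(x.begin(), H, W, (size_t)C * N, false, true);
  arma::cube dyc(dy.begin(), H, W, (size_t)cout * N, false, true);
  NumericVector dxr((R_xlen_t)(H) * (W) * (C) * (N));
  dxr.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::cube dxc(dxr.begin(), H, W, (size_t)C * N, false, true);
  arma::mat dw(w.n_rows, w.n_cols, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  const size_t hw = (size_t)H * W;
  if (kh == 1 && kw == 1) {
    for (int n = 0; n < N; ++n) {
      const arma::mat X(const_cast<double*>(x.begin()) + hw * C * n,
                        hw, C, false, true);
      const arma::mat dY(const_cast<double*>(dy.begin()) + hw * cout * n,
                         hw, cout, false, true);
      arma::mat dX(dxr.begin() + hw * C * n, hw, C, false, true);
      dw += X.t() * dY;
      db += arma::sum(dY, 0).t();
      dX = dY * w.t();
    }
    return List::create(_["dx"] = dxr, _["dw"] = dw, _["db"] = db);
  }
  const int Hp = H + 2 * ph, Wp = W + 2 * pw;
  const size_t Np = (size_t)Hp * Wp;
  arma::mat Xp(Np, C), dYp(Np, cout), dXp(Np, C);
  for (int n = 0; n < N; ++n) {
    pad_into(xc, n, H, W, C, ph, pw, Xp);
    pad_into(dyc, n, H, W, cout, ph, pw, dYp);  // pad rows stay zero
    dXp.zeros();
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const long off = (ki - ph) + (long)Hp * (kj - pw);
        const size_t lo = off < 0 ? (size_t)(-off) : 0;
        const size_t hi = Np - 1 - (off > 0 ? (size_t)off : 0);
        arma::uvec idx = tap_rows(ki, kj, kh, kw, C);
        arma::mat Wtap = w.rows(idx);
        dw.rows(idx) += Xp.rows(lo + off, hi + off).t() * dYp.rows(lo, hi);
        dXp.rows(lo + off, hi + off) += dYp.rows(lo, hi) * Wtap.t();
      }
    db += arma::sum(dYp, 0).t();
    extract_interior(dXp, dxc, n, H, W, C, ph, pw);
  }
  return List::create(_["dx"] = dxr, _["dw"] = dw, _["db"] = db);
}

// 2x2 transpose convolution with stride 2: output is 2H x 2W. Because the
// stride equals the kernel size the output windows do not overlap, so each
// of the four kernel taps is a plain gemm followed by a strided scatter.
// [[Rcpp::export(name = ".tconv2d_fw")]]
NumericVector tconv2d_fw(NumericVector x, const arma::mat& w,
                         const arma::vec& b) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int cout = (int)w.n_cols;
  arma::cube xc(x.begin(), H, W, (size_t)C * N, false, true);
  NumericVector out((R_xlen_t)(2 * H) * (2 * W) * (cout) * (N));
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, cout, N);
  arma::cube yc(out.begin(), 2 * H, 2 * W, (size_t)cout * N, false, true);
  arma::mat X((size_t)H * W, C);
  for (int n = 0; n < N; ++n) {
    for (int ci = 0; ci < C; ++ci)
      std::memcpy(X.colptr(ci), xc.slice_memptr((size_t)ci + (size_t)C * n),
                  sizeof(double) * (size_t)H * W);
    for (int kj = 0; kj < 2; ++kj) {
      for (int ki = 0; ki < 2; ++ki) {
        arma::uvec rows(C);
        for (int ci = 0; ci < C; ++ci) rows[ci] = ki + 2 * (kj + 2 * ci);
        arma::mat Yp = X * w.rows(rows);  // (HW) x cout
        for (int co = 0; co < cout; ++co) {
          arma::mat& ys = yc.slice((size_t)co + (size_t)cout * n);
          const double* src = Yp.colptr(co);
          const double bc = b[co];
          for (int j = 0; j < W; ++j) {
            double* dst = ys.colptr(2 * j + kj);
            const double* s = src + (size_t)H * j;
            for (int i = 0; i < H; ++i) dst[2 * i + ki] = s[i] + bc;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".tconv2d_bw")]]
List tconv2d_bw(NumericVector x, NumericVector dy, const arma::mat& w) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int cout = (int)w.n_cols;
  arma::cube xc(x.begin(), H, W, (size_t)C * N, false, true);
  arma::cube dyc(dy.begin(), 2 * H, 2 * W, (size_t)cout * N, false, true);
  NumericVector dxr((R_xlen_t)(H) * (W) * (C) * (N));
  dxr.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::cube dxc(dxr.begin(), H, W, (size_t)C * N, false, true);
  arma::mat dw(w.n_rows, w.n_cols, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  arma::mat X((size_t)H * W, C), dYp((size_t)H * W, cout);
  for (int n = 0; n < N; ++n) {
    for (int ci = 0; ci < C; ++ci)
      std::memcpy(X.colptr(ci), xc.slice_memptr((size_t)ci + (size_t)C * n),
                  sizeof(double) * (size_t)H * W);
    arma::mat dX((size_t)H * W, C, arma::fill::zeros);
    for (int kj = 0; kj < 2; ++kj) {
      for (int ki = 0; ki < 2; ++ki) {
        arma::uvec rows(C);
        for (int ci = 0; ci < C; ++ci) rows[ci] = ki + 2 * (kj + 2 * ci);
        for (int co = 0; co < cout; ++co) {
          const arma::mat& ds = dyc.slice((size_t)co + (size_t)cout * n);
          double* dst = dYp.colptr(co);
          for (int j = 0; j < W; ++j) {
            const double* s = ds.colptr(2 * j + kj);
            double* d = dst + (size_t)H * j;
            for (int i = 0; i < H; ++i) d[i] = s[2 * i + ki];
          }
        }
        dw.rows(rows) += X.t() * dYp;
        dX += dYp * w.rows(rows).t();
        db += arma::sum(dYp, 0).t();
      }
    }
    for (int ci = 0; ci < C; ++ci)
      std::memcpy(dxc.slice_memptr((size_t)ci + (size_t)C * n), dX.colptr(ci),
                  sizeof(double) * (size_t)H * W);
  }
  return List::create(_["dx"] = dxr, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int h = H / 2, wo = W / 2;
  arma::cube xc(x.begin(), H, W, (size_t)C * N, false, true);
  NumericVector out((R_xlen_t)(h) * (wo) * (C) * (N));
  out.attr("dim") = IntegerVector::create(h, wo, C, N);
  IntegerVector idx((R_xlen_t)(h) * (wo) * (C) * (N));
  idx.attr("dim") = IntegerVector::create(h, wo, C, N);
  arma::cube yc(out.begin(), h, wo, (size_t)C * N, false, true);
  int* ip = idx.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const arma::mat& xs = xc.slice(s);
    arma::mat& ys = yc.slice(s);
    int* is = ip + s * (size_t)h * wo;
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = xs(2 * i, 2 * j);
        int code = 0;  // row-major window scan: (0,0),(0,1),(1,0),(1,1)
        const int order[4][2] = {{0, 0}, {0, 1}, {1, 0}, {1, 1}};
        for (int k = 1; k < 4; ++k) {
          const double v = xs(2 * i + order[k][0], 2 * j + order[k][1]);
          if (v > best) { best = v; code = k; }
        }
        ys(i, j) = best;
        is[i + (size_t)h * j] = code;
      }
    }
  }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// Place each value of a pooled-size tensor at its recorded argmax position
// in the double-size grid, zero elsewhere (index-based unpooling; also the
// gradient of max-pooling).
// [[Rcpp::export(name = ".pool_scatter")]]
NumericVector pool_scatter(NumericVector v, IntegerVector idx) {
  IntegerVector vd = v.attr("dim");
  const int h = vd[0], wo = vd[1], C = vd[2], N = vd[3];
  arma::cube vc(v.begin(), h, wo, (size_t)C * N, false, true);
  NumericVector out((R_xlen_t)(2 * h) * (2 * wo) * (C) * (N));
  out.attr("dim") = IntegerVector::create(2 * h, 2 * wo, C, N);
  arma::cube yc(out.begin(), 2 * h, 2 * wo, (size_t)C * N, false, true);
  const int* ip = idx.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const arma::mat& vs = vc.slice(s);
    arma::mat& ys = yc.slice(s);
    const int* is = ip + s * (size_t)h * wo;
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < h; ++i) {
        const int code = is[i + (size_t)h * j];
        ys(2 * i + (code >> 1), 2 * j + (code & 1)) = vs(i, j);
      }
  }
  return out;
}

// Read the value at each recorded argmax position of a double-size tensor
// (gradient of pool_scatter / unpooling).
// [[Rcpp::export(name = ".pool_gather")]]
NumericVector pool_gather(NumericVector g, IntegerVector idx) {
  IntegerVector gd = g.attr("dim");
  const int H = gd[0], W = gd[1], C = gd[2], N = gd[3];
  const int h = H / 2, wo = W / 2;
  arma::cube gc(g.begin(), H, W, (size_t)C * N, false, true);
  NumericVector out((R_xlen_t)(h) * (wo) * (C) * (N));
  out.attr("dim") = IntegerVector::create(h, wo, C, N);
  arma::cube yc(out.begin(), h, wo, (size_t)C * N, false, true);
  const int* ip = idx.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const arma::mat& gs = gc.slice(s);
    arma::mat& ys = yc.slice(s);
    const int* is = ip + s * (size_t)h * wo;
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < h; ++i) {
        const int code = is[i + (size_t)h * j];
        ys(i, j) = gs(2 * i + (code >> 1), 2 * j + (code & 1));
      }
  }
  return out;
}

// ---- fused elementwise layers (batch norm, activations, sigmoid) ----
// These exist purely to keep the training loop inside the time budget of
// desk-scale runs; semantics match the straightforward R formulations.

// [[Rcpp::export(name = ".lrelu_fw")]]
NumericVector lrelu_fw(NumericVector a, double slope) {
  NumericVector y = clone(a);
  double* p = y.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] *= slope;
  return y;
}

// [[Rcpp::export(name = ".lrelu_bw")]]
NumericVector lrelu_bw(NumericVector dy, NumericVector a, double slope) {
  NumericVector g = clone(dy);
  double* p = g.begin();
  const double* ap = a.begin();
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) if (ap[i] < 0) p[i] *= slope;
  return g;
}

// Per-channel batch normalization over (H, W, N).
// [[Rcpp::export(name = ".bn_fw")]]
List bn_fw(NumericVector x, const arma::vec& gamma, const arma::vec& beta,
           const arma::vec& rmean, const arma::vec& rvar, bool train,
           double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  arma::vec mu(C), var(C);
  const double* xp = x.begin();
  if (train) {
    mu.zeros(); var.zeros();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double* s = xp + hw * (c + (size_t)C * n);
        double acc = 0, acc2 = 0;
        for (size_t i = 0; i < hw; ++i) { acc += s[i]; acc2 += s[i] * s[i]; }
        mu[c] += acc; var[c] += acc2;
      }
    const double m = (double)hw * N;
    mu /= m;
    var = var / m - mu % mu;
  } else {
    mu = rmean; var = rvar;
  }
  arma::vec std = arma::sqrt(var + eps);
  NumericVector xhat((R_xlen_t)hw * C * N), y((R_xlen_t)hw * C * N);
  xhat.attr("dim") = xd; y.attr("dim") = xd;
  double* hp = xhat.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = hw * (c + (size_t)C * n);
      const double* s = xp + off;
      double* h = hp + off;
      double* o = yp + off;
      const double mc = mu[c], sc = std[c], gc = gamma[c], bc = beta[c];
      for (size_t i = 0; i < hw; ++i) {
        h[i] = (s[i] - mc) / sc;
        o[i] = gc * h[i] + bc;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat,
                      _["std"] = Rcpp::wrap(std), _["mean"] = Rcpp::wrap(mu),
                      _["var"] = Rcpp::wrap(var));
}

// [[Rcpp::export(name = ".bn_bw")]]
List bn_bw(NumericVector dy, NumericVector xhat, const arma::vec& std,
           const arma::vec& gamma) {
  IntegerVector xd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  const double m = (double)hw * N;
  arma::vec sum_dy(C, arma::fill::zeros), sum_dyx(C, arma::fill::zeros);
  const double* dp = dy.begin();
  const double* hp = xhat.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = hw * (c + (size_t)C * n);
      const double* d = dp + off;
      const double* h = hp + off;
      double a = 0, b = 0;
      for (size_t i = 0; i < hw; ++i) { a += d[i]; b += d[i] * h[i]; }
      sum_dy[c] += a; sum_dyx[c] += b;
    }
  NumericVector dx((R_xlen_t)hw * C * N);
  dx.attr("dim") = xd;
  double* op = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = hw * (c + (size_t)C * n);
      const double* d = dp + off;
      const double* h = hp + off;
      double* o = op + off;
      const double k = gamma[c] / std[c];
      const double m1 = sum_dy[c] / m, m2 = sum_dyx[c] / m;
      for (size_t i = 0; i < hw; ++i)
        o[i] = k * (d[i] - m1 - h[i] * m2);
    }
  return List::create(_["dx"] = dx, _["dgamma"] = Rcpp::wrap(sum_dyx),
                      _["dbeta"] = Rcpp::wrap(sum_dy));
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Large feature tensors are allocated and freed at every layer call; with
// glibc's default mmap threshold each one triggers mmap/munmap and the
// page-fault cost dwarfs the arithmetic. Raising the thresholds keeps the
// arena on the heap and lets it be reused.
// [[Rcpp::export(name = ".tune_allocator")]]
void tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}
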