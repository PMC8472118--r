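// Low-level numeric kernels for the CNN engine and image plumbing.
// Activations are dense arrays (H, W, C, N), column-major as R stores them.
// Conv weights are matrices of shape (k*k*Cin, Cout) with row index
// ((c*k + kx)*k + ky), matching the im2col layout below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::uvec dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return arma::uvec{(unsigned)d[0], (unsigned)d[1], (unsigned)d[2], (unsigned)d[3]};
}

// im2col for stride-1 same-ish padding: cols is (H*W) x (k*k*Cin).
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& cols) {
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)c * H * W;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        int col = (c * k + kx) * k + ky;
        double* dst = cols.colptr(col);
        int dy = ky - pad, dx = kx - pad;
        for (int j = 0; j < W; ++j) {
          int sj = j + dx;
          if (sj < 0 || sj >= W) continue;
          int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
          if (i1 <= i0) continue;
          std::copy(plane + (size_t)sj * H + i0 + dy,
                    plane + (size_t)sj * H + i1 + dy,
                    dst + (size_t)j * H + i0);
        }
      }
    }
  }
}

// scatter-add inverse of im2col
static void col2im(const arma::mat& cols, int H, int W, int C, int k, int pad,
                   double* gx) {
  for (int c = 0; c < C; ++c) {
    double* plane = gx + (size_t)c * H * W;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        int col = (c * k + kx) * k + ky;
        const double* src = cols.colptr(col);
        int dy = ky - pad, dx = kx - pad;
        for (int j = 0; j < W; ++j) {
          int sj = j + dx;
          if (sj < 0 || sj >= W) continue;
          int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
          for (int i = i0; i < i1; ++i)
            plane[(size_t)sj * H + i + dy] += src[(size_t)j * H + i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, const arma::mat& Wt,
                             const arma::vec& b, int k, int pad) {
  arma::uvec d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = Wt.n_cols;
  if ((int)Wt.n_rows != k * k * C) stop("weight/input channel mismatch");
  NumericVector out = alloc4(H, W, Cout, N);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(REAL(x) + (size_t)n * H * W * C, H, W, C, k, pad, cols);
    arma::mat o = cols * Wt;               // (H*W) x Cout
    o.each_row() += b.t();
    std::copy(o.memptr(), o.memptr() + (size_t)H * W * Cout,
              REAL(out) + (size_t)n * H * W * Cout);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, const arma::mat& Wt, NumericVector gout,
                    int k, int pad) {
  arma::uvec d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = Wt.n_cols;
  NumericVector gx = alloc4(H, W, C, N);
  arma::mat gW(Wt.n_rows, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    const arma::mat go(const_cast<double*>(REAL(gout)) + (size_t)n * H * W * Cout,
                       H * W, Cout, false, true);
    im2col(REAL(x) + (size_t)n * H * W * C, H, W, C, k, pad, cols);
    gW += cols.t() * go;
    gb += arma::sum(go, 0).t();
    arma::mat gcols = go * Wt.t();         // (H*W) x (k*k*C)
    col2im(gcols, H, W, C, k, pad, REAL(gx) + (size_t)n * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; idx stores the linear in-plane argmax offset.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  arma::uvec d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  NumericVector out = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  int* ip = INTEGER(idx);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* plane = xp + p * H * W;
    double* oplane = op + p * Ho * Wo;
    int* iplane = ip + p * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int base = (2 * j) * H + 2 * i;
        int cand[4] = {base, base + 1, base + H, base + H + 1};
        int best = cand[0];
        for (int q = 1; q < 4; ++q) if (plane[cand[q]] > plane[best]) best = cand[q];
        oplane[(size_t)j * Ho + i] = plane[best];
        iplane[(size_t)j * Ho + i] = best;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gout,
                               int H, int W) {
  arma::uvec d = dims4(gout);
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector gx = alloc4(H, W, C, N);
  const double* gp = REAL(gout);
  const int* ip = INTEGER(idx);
  double* xp = REAL(gx);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* gplane = gp + p * Ho * Wo;
    const int* iplane = ip + p * Ho * Wo;
    double* xplane = xp + p * H * W;
    for (size_t q = 0; q < (size_t)Ho * Wo; ++q)
      xplane[iplane[q]] += gplane[q];
  }
  return gx;
}

// 2x2 transposed convolution, stride 2 (non-overlapping up-convolution).
// Wt has shape (Cin, 4*Cout) with column index ((cout*2 + kx)*2 + ky).
// [[Rcpp::export]]
NumericVector cpp_convT2_fwd(NumericVector x, const arma::mat& Wt,
                             const arma::vec& b) {
  arma::uvec d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = Wt.n_cols / 4;
  NumericVector out = alloc4(2 * H, 2 * W, Cout, N);
  for (int n = 0; n < N; ++n) {
    const arma::mat xm(const_cast<double*>(REAL(x)) + (size_t)n * H * W * C,
                       H * W, C, false, true);
    arma::mat o = xm * Wt;                 // (H*W) x (4*Cout)
    double* op = REAL(out) + (size_t)n * 4 * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      double* oplane = op + (size_t)co * 4 * H * W;
      for (int kx = 0; kx < 2; ++kx) {
        for (int ky = 0; ky < 2; ++ky) {
          const double* src = o.colptr((co * 2 + kx) * 2 + ky);
          double bb = b[co];
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              oplane[(size_t)(2 * j + kx) * 2 * H + 2 * i + ky] =
                src[(size_t)j * H + i] + bb;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_convT2_bwd(NumericVector x, const arma::mat& Wt, NumericVector gout) {
  arma::uvec d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = Wt.n_cols / 4;
  NumericVector gx = alloc4(H, W, C, N);
  arma::mat gW(C, 4 * Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat gmat(H * W, 4 * Cout);
  for (int n = 0; n < N; ++n) {
    const double* gp = REAL(gout) + (size_t)n * 4 * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* gplane = gp + (size_t)co * 4 * H * W;
      for (int kx = 0; kx < 2; ++kx) {
        for (int ky = 0; ky < 2; ++ky) {
          double* dst = gmat.colptr((co * 2 + kx) * 2 + ky);
          double acc = 0.0;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              double v = gplane[(size_t)(2 * j + kx) * 2 * H + 2 * i + ky];
              dst[(size_t)j * H + i] = v;
              acc += v;
            }
          gb[co] += acc;
        }
      }
    }
    const arma::mat xm(const_cast<double*>(REAL(x)) + (size_t)n * H * W * C,
                       H * W, C, false, true);
    gW += xm.t() * gmat;
    arma::mat gxm = gmat * Wt.t();         // (H*W) x C
    std::copy(gxm.memptr(), gxm.memptr() + (size_t)H * W * C,
              REAL(gx) + (size_t)n * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Pixel-centre aligned resampling; exact identity when sizes match.
static inline double src_coord(int dst, int n_dst, int n_src) {
  return (dst + 0.5) * ((double)n_src / n_dst) - 0.5;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& img, int oh, int ow) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  for (int j = 0; j < ow; ++j) {
    double sx = src_coord(j, ow, W);
    int x0 = (int)std::floor(sx);
    double fx = sx - x0;
    int xa = std::min(std::max(x0, 0), W - 1);
    int xb = std::min(std::max(x0 + 1, 0), W - 1);
    for (int i = 0; i < oh; ++i) {
      double sy = src_coord(i, oh, H);
      int y0 = (int)std::floor(sy);
      double fy = sy - y0;
      int ya = std::min(std::max(y0, 0), H - 1);
      int yb = std::min(std::max(y0 + 1, 0), H - 1);
      out(i, j) = (1 - fy) * ((1 - fx) * img(ya, xa) + fx * img(ya, xb)) +
                  fy * ((1 - fx) * img(yb, xa) + fx * img(yb, xb));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_nearest(const NumericMatrix& img, int oh, int ow) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  for (int j = 0; j < ow; ++j) {
    int sj = (int)std::floor(src_coord(j, ow, W) + 0.5);
    sj = std::min(std::max(sj, 0), W - 1);
    for (int i = 0; i < oh; ++i) {
      int si = (int)std::floor(src_coord(i, oh, H) + 0.5);
      si = std::min(std::max(si, 0), H - 1);
      out(i, j) = img(si, sj);
    }
  }
  return out;
}

// 6-connectivity 3-d connected components of a logical/integer array.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  int H = d[0], W = d[1], Z = d[2];
  size_t n = (size_t)H * W * Z;
  IntegerVector lab(mask.size());
  lab.attr("dim") = d;
  const int* m = INTEGER(mask);
  int* L = INTEGER(lab);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || L[s]) continue;
    ++next;
    stack.push_back(s);
    L[s] = next;
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int z = v / ((size_t)H * W);
      size_t r = v % ((size_t)H * W);
      int j = r / H, i = r % H;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], zz = z + dz[q];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W || zz < 0 || zz >= Z) continue;
        size_t u = ((size_t)zz * W + jj) * H + ii;
        if (m[u] && !L[u]) { L[u] = next; stack.push_back(u); }
      }
    }
  }
  return lab;
}

// Brute-force confusion counts kept simple on purpose (used everywhere).
// [[Rcpp::export]]
IntegerVector cpp_confusion(IntegerVector pred, IntegerVector gt) {
  if (pred.size() != gt.size()) stop("shape mismatch");
  long long tp = 0, tn = 0, fp = 0, fn = 0;
  const int* p = INTEGER(pred);
  const int* g = INTEGER(gt);
  for (R_xlen_t i = 0; i < pred.size(); ++i) {
    if (p[i] != 0 && p[i] != 1) stop("pred not binary");
    if (g[i] != 0 && g[i] != 1) stop("gt not binary");
    if (p[i] && g[i]) ++tp;
    else if (p[i] && !g[i]) ++fp;
    else if (!p[i] && g[i]) ++fn;
    else ++tn;
  }
  return IntegerVector::create(_["TP"] = (int)tp, _["TN"] = (int)tn,
                               _["FP"] = (int)fp, _["FN"] = (int)fn);
}

// Fused batch-norm + ReLU. Train mode uses batch statistics and updates the
// running estimates in place on copies returned to R; eval mode uses the
// running estimates. xhat is cached for the backward pass.
// [[Rcpp::export]]
List cpp_bn_relu_fwd(NumericVector z, const arma::vec& gamma,
                     const arma::vec& beta, const arma::vec& run_mean,
                     const arma::vec& run_var, bool train, double momentum,
                     double eps) {
  arma::uvec d = dims4(z);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W;
  size_t plane_stride = hw;
  size_t samp_stride = hw * C;
  arma::vec mu(C), va(C);
  const double* zp = REAL(z);
  if (train) {
    for (int c = 0; c < C; ++c) {
      double s1 = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = zp + n * samp_stride + c * plane_stride;
        for (size_t i = 0; i < hw; ++i) { s1 += p[i]; s2 += p[i] * p[i]; }
      }
      double m = s1 / (hw * N);
      mu[c] = m;
      va[c] = std::max(s2 / (hw * N) - m * m, 0.0);
    }
  } else {
    mu = run_mean;
    va = run_var;
  }
  NumericVector out = alloc4(H, W, C, N);
  NumericVector xhat = alloc4(H, W, C, N);
  double* op = REAL(out);
  double* xp = REAL(xhat);
  arma::vec inv = 1.0 / arma::sqrt(va + eps);
  for (int c = 0; c < C; ++c) {
    double iv = inv[c], m = mu[c], g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      size_t off = n * samp_stride + c * plane_stride;
      const double* p = zp + off;
      double* o = op + off;
      double* xh = xp + off;
      for (size_t i = 0; i < hw; ++i) {
        double v = (p[i] - m) * iv;
        xh[i] = v;
        double y = g * v + b;
        o[i] = y > 0 ? y : 0.0;
      }
    }
  }
  arma::vec nm = run_mean, nv = run_var;
  if (train) {
    double n_per = (double)hw * N;
    double corr = n_per > 1 ? n_per / (n_per - 1) : 1.0;
    nm = (1 - momentum) * run_mean + momentum * mu;
    nv = (1 - momentum) * run_var + momentum * va * corr;
  }
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["inv"] = NumericVector(inv.begin(), inv.end()),
                      _["mean"] = NumericVector(nm.begin(), nm.end()),
                      _["var"] = NumericVector(nv.begin(), nv.end()));
}

// [[Rcpp::export]]
List cpp_bn_relu_bwd(NumericVector gout, NumericVector out, NumericVector xhat,
                     const arma::vec& inv, const arma::vec& gamma) {
  arma::uvec d = dims4(gout);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W;
  size_t plane_stride = hw;
  size_t samp_stride = hw * C;
  NumericVector gx = alloc4(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  const double* gp = REAL(gout);
  const double* op = REAL(out);
  const double* xp = REAL(xhat);
  double* gxp = REAL(gx);
  double n_per = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double gsum = 0, gxsum = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = n * samp_stride + c * plane_stride;
      const double* g = gp + off;
      const double* o = op + off;
      const double* xh = xp + off;
      for (size_t i = 0; i < hw; ++i) {
        double gv = o[i] > 0 ? g[i] : 0.0;
        gsum += gv;
        gxsum += gv * xh[i];
      }
    }
    ggamma[c] = gxsum;
    gbeta[c] = gsum;
    double k = gamma[c] * inv[c];
    double mg = gsum / n_per, mgx = gxsum / n_per;
    for (int n = 0; n < N; ++n) {
      size_t off = n * samp_stride + c * plane_stride;
      const double* g = gp + off;
      const double* o = op + off;
      const double* xh = xp + off;
      double* gxo = gxp + off;
      for (size_t i = 0; i < hw; ++i) {
        double gv = o[i] > 0 ? g[i] : 0.0;
        gxo[i] = k * (gv - mg - xh[i] * mgx);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
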