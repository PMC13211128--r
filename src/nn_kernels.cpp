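// Hot-path kernels for the 1-D network layers. Feature maps are arrays of
// dim (channels, time, batch); conv weights (C_out, C_in, k). Inputs and
// outputs are plain R arrays; Armadillo matrices are zero-copy views over
// their memory (the layers are memory-bound, so avoiding Rcpp's conversion
// copies matters more than anything else here). Pure-R reference
// implementations of every kernel live in R/nn.R and the test suite asserts
// exact agreement between the two routes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline void dims3(const NumericVector& v, int& a, int& b, int& c) {
  IntegerVector d = v.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  a = d[0]; b = d[1]; c = d[2];
}

static inline NumericVector alloc3(int a, int b, int c) {
  NumericVector v(Dimension(a, b, c));
  return v;
}

// gather the j-th tap of every output position into Xs (C_in, Tout*B)
static void gather_tap(const double* x, int C, int L, int B, mat& Xs,
                       int j, int stride, int pad, int Tout) {
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (size_t)b * C * L;
    for (int t = 0; t < Tout; ++t) {
      const int src = j + stride * t - pad;
      double* dst = Xs.colptr((size_t)b * Tout + t);
      if (src < 0 || src >= L) std::fill(dst, dst + C, 0.0);
      else std::memcpy(dst, xb + (size_t)src * C, sizeof(double) * C);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv1d_forward(NumericVector x, NumericVector W,
                                 Nullable<NumericVector> bias,
                                 int stride, int pad) {
  int C_in, L, B, C_out, C_in2, k;
  dims3(x, C_in, L, B);
  dims3(W, C_out, C_in2, k);
  if (C_in2 != C_in) stop("conv1d: channel mismatch");
  const int Tout = (L + 2 * pad - k) / stride + 1;
  if (Tout < 1) stop("conv1d: input too short");
  NumericVector outv = alloc3(C_out, Tout, B);
  mat Y(outv.begin(), C_out, (size_t)Tout * B, false, true);
  Y.zeros();
  mat Xs(C_in, (size_t)Tout * B);
  const cube Wc(const_cast<double*>(W.begin()), C_out, C_in, k, false, true);
  for (int j = 0; j < k; ++j) {
    gather_tap(x.begin(), C_in, L, B, Xs, j, stride, pad, Tout);
    Y += Wc.slice(j) * Xs;
  }
  if (bias.isNotNull()) {
    NumericVector bv(bias.get());
    const vec bw(const_cast<double*>(bv.begin()), C_out, false, true);
    Y.each_col() += bw;
  }
  return outv;
}

// [[Rcpp::export]]
List cpp_conv1d_backward(NumericVector dy, NumericVector x, NumericVector W,
                         int stride, int pad, bool has_bias) {
  int C_out, Tout, B, C_in, L, B2, k, C_in2;
  dims3(dy, C_out, Tout, B);
  dims3(x, C_in, L, B2);
  IntegerVector wd = W.attr("dim");
  C_in2 = wd[1]; k = wd[2];
  const mat dYm(const_cast<double*>(dy.begin()), C_out, (size_t)Tout * B, false, true);
  const cube Wc(const_cast<double*>(W.begin()), C_out, C_in, k, false, true);
  NumericVector dWv = alloc3(C_out, C_in, k);
  cube dW(dWv.begin(), C_out, C_in, k, false, true);
  NumericVector dxv = alloc3(C_in, L, B);
  double* dx = dxv.begin();
  std::fill(dx, dx + dxv.size(), 0.0);
  mat Xs(C_in, (size_t)Tout * B);
  for (int j = 0; j < k; ++j) {
    gather_tap(x.begin(), C_in, L, B, Xs, j, stride, pad, Tout);
    dW.slice(j) = dYm * Xs.t();
    const mat dXs = Wc.slice(j).t() * dYm;
    for (int b = 0; b < B; ++b) {
      double* dxb = dx + (size_t)b * C_in * L;
      for (int t = 0; t < Tout; ++t) {
        const int src = j + stride * t - pad;
        if (src < 0 || src >= L) continue;
        double* dst = dxb + (size_t)src * C_in;
        const double* s = dXs.colptr((size_t)b * Tout + t);
        for (int c = 0; c < C_in; ++c) dst[c] += s[c];
      }
    }
  }
  List out = List::create(Named("dx") = dxv, Named("dW") = dWv);
  if (has_bias) {
    vec db = sum(dYm, 1);
    out["db"] = NumericVector(db.begin(), db.end());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool1d_forward(NumericVector x, int k, int stride, int pad) {
  int C, L, B;
  dims3(x, C, L, B);
  const int Tout = (L + 2 * pad - k) / stride + 1;
  NumericVector outv = alloc3(C, Tout, B);
  IntegerVector argv(Dimension(C, Tout, B));
  const double* px = x.begin();
  double* po = outv.begin();
  int* pa = argv.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = px + (size_t)b * C * L;
    for (int t = 0; t < Tout; ++t) {
      const size_t off = ((size_t)b * Tout + t) * C;
      for (int c = 0; c < C; ++c) {
        double best = -datum::inf;
        int bestj = 0;
        for (int j = 0; j < k; ++j) {
          const int src = j + stride * t - pad;
          if (src < 0 || src >= L) continue;
          const double v = xb[(size_t)src * C + c];
          if (v > best) { best = v; bestj = j; }
        }
        po[off + c] = best;
        pa[off + c] = bestj;
      }
    }
  }
  return List::create(Named("out") = outv, Named("arg") = argv);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool1d_backward(NumericVector dy, IntegerVector arg,
                                     int L, int k, int stride, int pad) {
  int C, Tout, B;
  dims3(dy, C, Tout, B);
  NumericVector dxv = alloc3(C, L, B);
  double* dx = dxv.begin();
  std::fill(dx, dx + dxv.size(), 0.0);
  const double* pd = dy.begin();
  const int* pa = arg.begin();
  for (int b = 0; b < B; ++b) {
    double* dxb = dx + (size_t)b * C * L;
    for (int t = 0; t < Tout; ++t) {
      const size_t off = ((size_t)b * Tout + t) * C;
      for (int c = 0; c < C; ++c) {
        const int src = pa[off + c] + stride * t - pad;
        if (src >= 0 && src < L) dxb[(size_t)src * C + c] += pd[off + c];
      }
    }
  }
  return dxv;
}

// [[Rcpp::export]]
List cpp_bn_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector mean_in, NumericVector var_in,
                    bool train, double eps) {
  int C, Tt, B;
  dims3(x, C, Tt, B);
  const size_t n = (size_t)Tt * B;
  vec m(C), v(C);
  const double* p = x.begin();
  if (train) {
    m.zeros(); v.zeros();
    for (size_t i = 0; i < n; ++i) {
      const double* col = p + i * C;
      for (int c = 0; c < C; ++c) { m[c] += col[c]; v[c] += col[c] * col[c]; }
    }
    m /= (double)n;
    v = v / (double)n - m % m;
    v.transform([](double val) { return val < 0 ? 0.0 : val; });
  } else {
    m = vec(const_cast<double*>(mean_in.begin()), C, false, true);
    v = vec(const_cast<double*>(var_in.begin()), C, false, true);
  }
  vec invstd = 1.0 / sqrt(v + eps);
  NumericVector xhatv = alloc3(C, Tt, B);
  NumericVector outv = alloc3(C, Tt, B);
  double* ph = xhatv.begin();
  double* po = outv.begin();
  const double* pg = gamma.begin();
  const double* pb = beta.begin();
  for (size_t i = 0; i < n; ++i) {
    const size_t off = i * C;
    for (int c = 0; c < C; ++c) {
      const double h = (p[off + c] - m[c]) * invstd[c];
      ph[off + c] = h;
      po[off + c] = pg[c] * h + pb[c];
    }
  }
  return List::create(Named("out") = outv, Named("xhat") = xhatv,
                      Named("mean") = NumericVector(m.begin(), m.end()),
                      Named("var") = NumericVector(v.begin(), v.end()),
                      Named("invstd") = NumericVector(invstd.begin(), invstd.end()));
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericVector dy, NumericVector xhat, NumericVector invstd,
                     NumericVector gamma, bool train) {
  int C, Tt, B;
  dims3(dy, C, Tt, B);
  const size_t n = (size_t)Tt * B;
  std::vector<double> dgamma(C, 0.0), dbeta(C, 0.0);
  const double* pd = dy.begin();
  const double* ph = xhat.begin();
  for (size_t i = 0; i < n; ++i) {
    const size_t off = i * C;
    for (int c = 0; c < C; ++c) {
      dgamma[c] += pd[off + c] * ph[off + c];
      dbeta[c] += pd[off + c];
    }
  }
  NumericVector dxv = alloc3(C, Tt, B);
  double* px = dxv.begin();
  const double* pg = gamma.begin();
  const double* pi = invstd.begin();
  if (train) {
    std::vector<double> mdx(C), mdxx(C);
    for (int c = 0; c < C; ++c) {
      mdx[c] = pg[c] * dbeta[c] / (double)n;    // mean of dxhat
      mdxx[c] = pg[c] * dgamma[c] / (double)n;  // mean of dxhat*xhat
    }
    for (size_t i = 0; i < n; ++i) {
      const size_t off = i * C;
      for (int c = 0; c < C; ++c) {
        const double dxh = pd[off + c] * pg[c];
        px[off + c] = pi[c] * (dxh - mdx[c] - ph[off + c] * mdxx[c]);
      }
    }
  } else {
    for (size_t i = 0; i < n; ++i) {
      const size_t off = i * C;
      for (int c = 0; c < C; ++c) px[off + c] = pd[off + c] * pg[c] * pi[c];
    }
  }
  return List::create(Named("dx") = dxv,
                      Named("dgamma") = NumericVector(dgamma.begin(), dgamma.end()),
                      Named("dbeta") = NumericVector(dbeta.begin(), dbeta.end()));
}

// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  const size_t n = y.size();
  for (size_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector dy, NumericVector x) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* pd = dy.begin();
  const double* px = x.begin();
  double* po = dx.begin();
  const size_t n = dy.size();
  for (size_t i = 0; i < n; ++i) po[i] = px[i] > 0 ? pd[i] : 0.0;
  return dx;
}

// Fused batch-norm + ReLU (the backbone's inner pattern): one pass, one
// intermediate (xhat) instead of two, halving the memory traffic of the
// dominant layer sequence.
// [[Rcpp::export]]
List cpp_bnrelu_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                        NumericVector mean_in, NumericVector var_in,
                        bool train, double eps) {
  int C, Tt, B;
  dims3(x, C, Tt, B);
  const size_t n = (size_t)Tt * B;
  vec m(C), v(C);
  const double* p = x.begin();
  if (train) {
    m.zeros(); v.zeros();
    for (size_t i = 0; i < n; ++i) {
      const double* col = p + i * C;
      for (int c = 0; c < C; ++c) { m[c] += col[c]; v[c] += col[c] * col[c]; }
    }
    m /= (double)n;
    v = v / (double)n - m % m;
    v.transform([](double val) { return val < 0 ? 0.0 : val; });
  } else {
    m = vec(const_cast<double*>(mean_in.begin()), C, false, true);
    v = vec(const_cast<double*>(var_in.begin()), C, false, true);
  }
  vec invstd = 1.0 / sqrt(v + eps);
  NumericVector xhatv(no_init(x.size()));
  xhatv.attr("dim") = x.attr("dim");
  NumericVector outv(no_init(x.size()));
  outv.attr("dim") = x.attr("dim");
  double* ph = xhatv.begin();
  double* po = outv.begin();
  const double* pg = gamma.begin();
  const double* pb = beta.begin();
  for (size_t i = 0; i < n; ++i) {
    const size_t off = i * C;
    for (int c = 0; c < C; ++c) {
      const double h = (p[off + c] - m[c]) * invstd[c];
      ph[off + c] = h;
      const double y = pg[c] * h + pb[c];
      po[off + c] = y > 0 ? y : 0.0;
    }
  }
  return List::create(Named("out") = outv, Named("xhat") = xhatv,
                      Named("mean") = NumericVector(m.begin(), m.end()),
                      Named("var") = NumericVector(v.begin(), v.end()),
                      Named("invstd") = NumericVector(invstd.begin(), invstd.end()));
}

// dy arrives post-ReLU; `out` is the fused forward's output (mask source).
// [[Rcpp::export]]
List cpp_bnrelu_backward(NumericVector dy, NumericVector out, NumericVector xhat,
                         NumericVector invstd, NumericVector gamma, bool train) {
  int C, Tt, B;
  dims3(dy, C, Tt, B);
  const size_t n = (size_t)Tt * B;
  std::vector<double> dgamma(C, 0.0), dbeta(C, 0.0);
  const double* pd = dy.begin();
  const double* po = out.begin();
  const double* ph = xhat.begin();
  for (size_t i = 0; i < n; ++i) {
    const size_t off = i * C;
    for (int c = 0; c < C; ++c) {
      const double g = po[off + c] > 0 ? pd[off + c] : 0.0;
      dgamma[c] += g * ph[off + c];
      dbeta[c] += g;
    }
  }
  NumericVector dxv(no_init(dy.size()));
  dxv.attr("dim") = dy.attr("dim");
  double* px = dxv.begin();
  const double* pg = gamma.begin();
  const double* pi = invstd.begin();
  if (train) {
    std::vector<double> mdx(C), mdxx(C);
    for (int c = 0; c < C; ++c) {
      mdx[c] = pg[c] * dbeta[c] / (double)n;
      mdxx[c] = pg[c] * dgamma[c] / (double)n;
    }
    for (size_t i = 0; i < n; ++i) {
      const size_t off = i * C;
      for (int c = 0; c < C; ++c) {
        const double g = po[off + c] > 0 ? pd[off + c] : 0.0;
        px[off + c] = pi[c] * (g * pg[c] - mdx[c] - ph[off + c] * mdxx[c]);
      }
    }
  } else {
    for (size_t i = 0; i < n; ++i) {
      const size_t off = i * C;
      for (int c = 0; c < C; ++c) {
        const double g = po[off + c] > 0 ? pd[off + c] : 0.0;
        px[off + c] = g * pg[c] * pi[c];
      }
    }
  }
  return List::create(Named("dx") = dxv,
                      Named("dgamma") = NumericVector(dgamma.begin(), dgamma.end()),
                      Named("dbeta") = NumericVector(dbeta.begin(), dbeta.end()));
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Large feature maps are allocated and freed on every layer call; with
// glibc's default mmap threshold each one costs a kernel round-trip. Raise
// the thresholds once at load so the arrays recycle through the heap.
// [[Rcpp::export]]
bool cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
  return true;
#else
  return false;
#endif
}
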