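#include <Rcpp.h>
using namespace Rcpp;

// Dense tensors use HWCN layout throughout: column-major array (H, W, C, N).
// im2col column order: oh fastest, then ow, then n.
// im2col row order: kh fastest, then kw, then c.

// Transposed im2col: rows index output positions (oh fastest, then ow, n),
// columns index (kh fastest, then kw, then c). With stride 1 each (kw, c,
// ow, n) slice is a contiguous run over oh, so the copy is cache-friendly.
// [[Rcpp::export]]
NumericMatrix im2col_t(NumericVector x, int H, int W, int C, int N,
                       int K, int stride, int pad) {
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  const size_t M = (size_t)OH * OW * N;
  NumericMatrix out = Rcpp::no_init(M, K * K * C);
  const double* px = x.begin();
  double* po = out.begin();
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        double* col = po + M * (kh + K * (kw + K * c));
        for (int n = 0; n < N; ++n) {
          const double* xc = px + plane * (c + (size_t)C * n);
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow * stride - pad + kw;
            double* dst = col + (size_t)OH * (ow + (size_t)OW * n);
            if (w < 0 || w >= W) {
              for (int oh = 0; oh < OH; ++oh) dst[oh] = 0.0;
              continue;
            }
            const double* src = xc + (size_t)H * w;
            if (stride == 1) {
              // valid oh range: pad-kh <= oh < H+pad-kh
              int lo = pad - kh; if (lo < 0) lo = 0;
              int hi = H + pad - kh; if (hi > OH) hi = OH;
              for (int oh = 0; oh < lo; ++oh) dst[oh] = 0.0;
              if (hi > lo)
                memcpy(dst + lo, src + (lo - pad + kh),
                       (size_t)(hi - lo) * sizeof(double));
              for (int oh = hi; oh < OH; ++oh) dst[oh] = 0.0;
            } else {
              for (int oh = 0; oh < OH; ++oh) {
                const int h = oh * stride - pad + kh;
                dst[oh] = (h >= 0 && h < H) ? src[h] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col_t.
// [[Rcpp::export]]
NumericVector col2im_t(NumericMatrix cols, int H, int W, int C, int N,
                       int K, int stride, int pad) {
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  const size_t M = (size_t)OH * OW * N;
  NumericVector x((size_t)H * W * C * N);
  double* px = x.begin();
  const double* po = cols.begin();
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const double* col = po + M * (kh + K * (kw + K * c));
        for (int n = 0; n < N; ++n) {
          double* xc = px + plane * (c + (size_t)C * n);
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            const double* src = col + (size_t)OH * (ow + (size_t)OW * n);
            double* dst = xc + (size_t)H * w;
            if (stride == 1) {
              int lo = pad - kh; if (lo < 0) lo = 0;
              int hi = H + pad - kh; if (hi > OH) hi = OH;
              double* d2 = dst + (lo - pad + kh);
              for (int oh = lo; oh < hi; ++oh) d2[oh - lo] += src[oh];
            } else {
              for (int oh = 0; oh < OH; ++oh) {
                const int h = oh * stride - pad + kh;
                if (h >= 0 && h < H) dst[h] += src[oh];
              }
            }
          }
        }
      }
    }
  }
  return x;
}

// Position-major variants: activations are ((oh,ow,n)-rows x channel-cols)
// matrices, so channel reductions are contiguous and no transposition is
// ever needed between layers.
// [[Rcpp::export]]
NumericMatrix im2col_pos(NumericMatrix x, int H, int W, int N,
                         int K, int stride, int pad) {
  const int C = x.ncol();
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  const size_t M = (size_t)OH * OW * N;
  const size_t MR = (size_t)H * W * N;
  NumericMatrix out = Rcpp::no_init(M, K * K * C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        double* col = po + M * (kh + K * (kw + K * c));
        for (int n = 0; n < N; ++n) {
          const double* xc = px + MR * c + (size_t)H * W * n;
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow * stride - pad + kw;
            double* dst = col + (size_t)OH * (ow + (size_t)OW * n);
            if (w < 0 || w >= W) {
              for (int oh = 0; oh < OH; ++oh) dst[oh] = 0.0;
              continue;
            }
            const double* src = xc + (size_t)H * w;
            if (stride == 1) {
              int lo = pad - kh; if (lo < 0) lo = 0;
              int hi = H + pad - kh; if (hi > OH) hi = OH;
              for (int oh = 0; oh < lo; ++oh) dst[oh] = 0.0;
              if (hi > lo)
                memcpy(dst + lo, src + (lo - pad + kh),
                       (size_t)(hi - lo) * sizeof(double));
              for (int oh = hi; oh < OH; ++oh) dst[oh] = 0.0;
            } else {
              for (int oh = 0; oh < OH; ++oh) {
                const int h = oh * stride - pad + kh;
                dst[oh] = (h >= 0 && h < H) ? src[h] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im_pos(NumericMatrix cols, int H, int W, int C, int N,
                         int K, int stride, int pad) {
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  const size_t M = (size_t)OH * OW * N;
  const size_t MR = (size_t)H * W * N;
  NumericMatrix x(MR, C);
  double* px = x.begin();
  const double* po = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const double* col = po + M * (kh + K * (kw + K * c));
        for (int n = 0; n < N; ++n) {
          double* xc = px + MR * c + (size_t)H * W * n;
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            const double* src = col + (size_t)OH * (ow + (size_t)OW * n);
            double* dst = xc + (size_t)H * w;
            if (stride == 1) {
              int lo = pad - kh; if (lo < 0) lo = 0;
              int hi = H + pad - kh; if (hi > OH) hi = OH;
              double* d2 = dst + (lo - pad + kh);
              for (int oh = lo; oh < hi; ++oh) d2[oh - lo] += src[oh];
            } else {
              for (int oh = 0; oh < OH; ++oh) {
                const int h = oh * stride - pad + kh;
                if (h >= 0 && h < H) dst[h] += src[oh];
              }
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2 stride-2 max pooling on the position-major layout.
// [[Rcpp::export]]
List maxpool2_pos(NumericMatrix x, int H, int W, int N) {
  const int C = x.ncol();
  const int OH = H / 2, OW = W / 2;
  const size_t MR = (size_t)H * W * N;
  const size_t MO = (size_t)OH * OW * N;
  NumericMatrix y = Rcpp::no_init(MO, C);
  IntegerVector arg = Rcpp::no_init(MO * C);
  const double* px = x.begin();
  double* py = y.begin();
  int* pa = arg.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double* xc = px + MR * c + (size_t)H * W * n;
      const size_t off = MR * c + (size_t)H * W * n;
      double* yc = py + MO * c + (size_t)OH * OW * n;
      int* ac = pa + MO * c + (size_t)OH * OW * n;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = -1e300; size_t bidx = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t idx = (size_t)(2 * oh + dh) + (size_t)H * (2 * ow + dw);
              if (xc[idx] > best) { best = xc[idx]; bidx = idx; }
            }
          yc[oh + (size_t)OH * ow] = best;
          ac[oh + (size_t)OH * ow] = (int)(off + bidx) + 1;
        }
      }
    }
  }
  return List::create(_["value"] = y, _["argmax"] = arg);
}



// Depthwise convolution, stride 1, 'same' zero padding (K odd).
// wgt is (K, K, C) column-major.
// [[Rcpp::export]]
NumericVector dwconv_fwd(NumericVector x, int H, int W, int C, int N,
                         NumericVector wgt, int K) {
  const int pad = (K - 1) / 2;
  NumericVector y((size_t)H * W * C * N);
  const double* px = x.begin();
  const double* pw = wgt.begin();
  double* py = y.begin();
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = px + plane * (c + (size_t)C * n);
      double* yc = py + plane * (c + (size_t)C * n);
      const double* wc = pw + (size_t)K * K * c;
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          double acc = 0.0;
          for (int kw = 0; kw < K; ++kw) {
            const int ww = w + kw - pad;
            if (ww < 0 || ww >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              const int hh = h + kh - pad;
              if (hh < 0 || hh >= H) continue;
              acc += xc[hh + (size_t)H * ww] * wc[kh + K * kw];
            }
          }
          yc[h + (size_t)H * w] = acc;
        }
      }
    }
  }
  return y;
}

// Gradient wrt input: correlation of upstream grad with the flipped kernel.
// [[Rcpp::export]]
NumericVector dwconv_bwd_x(NumericVector g, int H, int W, int C, int N,
                           NumericVector wgt, int K) {
  const int pad = (K - 1) / 2;
  NumericVector dx((size_t)H * W * C * N);
  const double* pg = g.begin();
  const double* pw = wgt.begin();
  double* pd = dx.begin();
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* gc = pg + plane * (c + (size_t)C * n);
      double* dc = pd + plane * (c + (size_t)C * n);
      const double* wc = pw + (size_t)K * K * c;
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          double acc = 0.0;
          for (int kw = 0; kw < K; ++kw) {
            const int ww = w - (kw - pad);
            if (ww < 0 || ww >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              const int hh = h - (kh - pad);
              if (hh < 0 || hh >= H) continue;
              acc += gc[hh + (size_t)H * ww] * wc[kh + K * kw];
            }
          }
          dc[h + (size_t)H * w] = acc;
        }
      }
    }
  }
  return dx;
}

// Gradient wrt the depthwise kernel.
// [[Rcpp::export]]
NumericVector dwconv_bwd_w(NumericVector x, NumericVector g, int H, int W,
                           int C, int N, int K) {
  const int pad = (K - 1) / 2;
  NumericVector dw((size_t)K * K * C);
  const double* px = x.begin();
  const double* pg = g.begin();
  double* pd = dw.begin();
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = px + plane * (c + (size_t)C * n);
      const double* gc = pg + plane * (c + (size_t)C * n);
      double* dc = pd + (size_t)K * K * c;
      for (int kw = 0; kw < K; ++kw) {
        for (int kh = 0; kh < K; ++kh) {
          double acc = 0.0;
          for (int w = 0; w < W; ++w) {
            const int ww = w + kw - pad;
            if (ww < 0 || ww >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int hh = h + kh - pad;
              if (hh < 0 || hh >= H) continue;
              acc += xc[hh + (size_t)H * ww] * gc[h + (size_t)H * w];
            }
          }
          dc[kh + K * kw] += acc;
        }
      }
    }
  }
  return dw;
}


// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector g, IntegerVector arg, int len) {
  NumericVector dx(len);
  double* pd = dx.begin();
  const double* pg = g.begin();
  const int* pa = arg.begin();
  const R_xlen_t m = g.size();
  for (R_xlen_t i = 0; i < m; ++i) pd[pa[i] - 1] += pg[i];
  return dx;
}

// ---- column batch normalization (channels in columns) ----

// Per-column mean and biased variance in one pass.
// [[Rcpp::export]]
List bn_cols_stats(NumericMatrix v) {
  const int m = v.nrow(), C = v.ncol();
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* x = &v(0, c);
    double s = 0, s2 = 0;
    for (int i = 0; i < m; ++i) { s += x[i]; s2 += x[i] * x[i]; }
    mu[c] = s / m;
    var[c] = s2 / m - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// out[i,c] = (v[i,c] - mu[c]) * istd[c] * gamma[c] + beta[c]
// [[Rcpp::export]]
NumericMatrix bn_cols_fwd(NumericMatrix v, NumericVector mu,
                          NumericVector istd, NumericVector gamma,
                          NumericVector beta) {
  const int m = v.nrow(), C = v.ncol();
  NumericMatrix out = Rcpp::no_init(m, C);
  for (int c = 0; c < C; ++c) {
    const double a = istd[c] * gamma[c];
    const double b = beta[c] - mu[c] * a;
    const double* x = &v(0, c);
    double* y = &out(0, c);
    for (int i = 0; i < m; ++i) y[i] = x[i] * a + b;
  }
  return out;
}

// Backward through column batch norm; `training` selects whether the batch
// statistics are part of the graph.
// [[Rcpp::export]]
List bn_cols_bwd(NumericMatrix v, NumericMatrix g, NumericVector mu,
                 NumericVector istd, NumericVector gamma, bool training) {
  const int m = v.nrow(), C = v.ncol();
  NumericMatrix dx = Rcpp::no_init(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* x = &v(0, c);
    const double* gg = &g(0, c);
    double* d = &dx(0, c);
    const double is = istd[c], mc = mu[c];
    double sg = 0, sgx = 0;
    for (int i = 0; i < m; ++i) {
      const double xh = (x[i] - mc) * is;
      sg += gg[i];
      sgx += gg[i] * xh;
    }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    const double a = gamma[c] * is;
    if (training) {
      const double t1 = sg / m, t2 = sgx / m;
      for (int i = 0; i < m; ++i) {
        const double xh = (x[i] - mc) * is;
        d[i] = a * (gg[i] - t1 - xh * t2);
      }
    } else {
      for (int i = 0; i < m; ++i) d[i] = a * gg[i];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
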