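#include <Rcpp.h>
using namespace Rcpp;

// Volumetric tensors are R arrays with dims (D, H, W, C, B), column-major.
// Direct 3D convolution kernels (forward, weight gradient, input gradient)
// over zero-padded inputs: loops are ordered so the innermost axis walks the
// fastest-varying (depth) dimension of both operands, avoiding any im2col
// intermediate. Weights are R arrays of dim (k, k, k, C_in, C_out).

// [[Rcpp::export]]
NumericVector nf_conv3d_fwd(NumericVector xp, IntegerVector dims,
                            NumericVector w, NumericVector bias,
                            int k, int stride) {
  const int Dp = dims[0], Hp = dims[1], Wp = dims[2], C = dims[3], B = dims[4];
  const int Do = (Dp - k) / stride + 1;
  const int Ho = (Hp - k) / stride + 1;
  const int Wo = (Wp - k) / stride + 1;
  const int Co = bias.size();
  const R_xlen_t planeIn = (R_xlen_t)Dp * Hp * Wp;
  const R_xlen_t planeOut = (R_xlen_t)Do * Ho * Wo;
  NumericVector out((R_xlen_t)planeOut * Co * B);
  const double *px = xp.begin(), *pw = w.begin(), *pb = bias.begin();
  double *po = out.begin();
  const int kk3 = k * k * k;
  std::vector<double> acc(Do);
  for (int b = 0; b < B; ++b) {
    const double *xbase = px + (R_xlen_t)b * C * planeIn;
    for (int co = 0; co < Co; ++co) {
      double *ob = po + ((R_xlen_t)b * Co + co) * planeOut;
      const double *wco = pw + (R_xlen_t)co * C * kk3;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          for (int dd = 0; dd < Do; ++dd) acc[dd] = pb[co];
          for (int ci = 0; ci < C; ++ci) {
            const double *xb = xbase + (R_xlen_t)ci * planeIn;
            const double *wc = wco + (R_xlen_t)ci * kk3;
            for (int kw = 0; kw < k; ++kw) {
              const double *xw = xb + (R_xlen_t)(wo * stride + kw) * Dp * Hp;
              for (int kh = 0; kh < k; ++kh) {
                const double *xh = xw + (R_xlen_t)(ho * stride + kh) * Dp;
                const double *wk = wc + (R_xlen_t)kw * k * k + kh * k;
                for (int kd = 0; kd < k; ++kd) {
                  const double wv = wk[kd];
                  const double *xd = xh + kd;
                  if (stride == 1) {
                    for (int dd = 0; dd < Do; ++dd) acc[dd] += wv * xd[dd];
                  } else {
                    for (int dd = 0; dd < Do; ++dd) acc[dd] += wv * xd[dd * stride];
                  }
                }
              }
            }
          }
          double *oh = ob + (R_xlen_t)wo * Do * Ho + (R_xlen_t)ho * Do;
          for (int dd = 0; dd < Do; ++dd) oh[dd] = acc[dd];
        }
      }
    }
  }
  return out;
}

// Gradient with respect to the weights; returns (k,k,k,C,Co) vector.
// [[Rcpp::export]]
NumericVector nf_conv3d_dw(NumericVector xp, IntegerVector dims,
                           NumericVector dout, int Co, int k, int stride) {
  const int Dp = dims[0], Hp = dims[1], Wp = dims[2], C = dims[3], B = dims[4];
  const int Do = (Dp - k) / stride + 1;
  const int Ho = (Hp - k) / stride + 1;
  const int Wo = (Wp - k) / stride + 1;
  const R_xlen_t planeIn = (R_xlen_t)Dp * Hp * Wp;
  const R_xlen_t planeOut = (R_xlen_t)Do * Ho * Wo;
  const int kk3 = k * k * k;
  NumericVector dw((R_xlen_t)kk3 * C * Co);
  const double *px = xp.begin(), *pd = dout.begin();
  double *pw = dw.begin();
  for (int b = 0; b < B; ++b) {
    const double *xbase = px + (R_xlen_t)b * C * planeIn;
    for (int co = 0; co < Co; ++co) {
      const double *db = pd + ((R_xlen_t)b * Co + co) * planeOut;
      for (int ci = 0; ci < C; ++ci) {
        const double *xb = xbase + (R_xlen_t)ci * planeIn;
        double *wc = pw + ((R_xlen_t)co * C + ci) * kk3;
        for (int wo = 0; wo < Wo; ++wo) {
          for (int ho = 0; ho < Ho; ++ho) {
            const double *dh = db + (R_xlen_t)wo * Do * Ho + (R_xlen_t)ho * Do;
            for (int kw = 0; kw < k; ++kw) {
              const double *xw = xb + (R_xlen_t)(wo * stride + kw) * Dp * Hp;
              for (int kh = 0; kh < k; ++kh) {
                const double *xh = xw + (R_xlen_t)(ho * stride + kh) * Dp;
                double *wk = wc + (R_xlen_t)kw * k * k + kh * k;
                for (int kd = 0; kd < k; ++kd) {
                  const double *xd = xh + kd;
                  double acc = 0.0;
                  if (stride == 1) {
                    for (int dd = 0; dd < Do; ++dd) acc += xd[dd] * dh[dd];
                  } else {
                    for (int dd = 0; dd < Do; ++dd) acc += xd[dd * stride] * dh[dd];
                  }
                  wk[kd] += acc;
                }
              }
            }
          }
        }
      }
    }
  }
  return dw;
}

// Gradient with respect to the (padded) input; returns padded-dims vector.
// [[Rcpp::export]]
NumericVector nf_conv3d_dx(NumericVector w, IntegerVector dims,
                           NumericVector dout, int Co, int k, int stride) {
  const int Dp = dims[0], Hp = dims[1], Wp = dims[2], C = dims[3], B = dims[4];
  const int Do = (Dp - k) / stride + 1;
  const int Ho = (Hp - k) / stride + 1;
  const int Wo = (Wp - k) / stride + 1;
  const R_xlen_t planeIn = (R_xlen_t)Dp * Hp * Wp;
  const R_xlen_t planeOut = (R_xlen_t)Do * Ho * Wo;
  const int kk3 = k * k * k;
  NumericVector dx((R_xlen_t)planeIn * C * B);
  const double *pw = w.begin(), *pd = dout.begin();
  double *px = dx.begin();
  for (int b = 0; b < B; ++b) {
    double *xbase = px + (R_xlen_t)b * C * planeIn;
    for (int co = 0; co < Co; ++co) {
      const double *db = pd + ((R_xlen_t)b * Co + co) * planeOut;
      for (int ci = 0; ci < C; ++ci) {
        double *xb = xbase + (R_xlen_t)ci * planeIn;
        const double *wc = pw + ((R_xlen_t)co * C + ci) * kk3;
        for (int wo = 0; wo < Wo; ++wo) {
          for (int ho = 0; ho < Ho; ++ho) {
            const double *dh = db + (R_xlen_t)wo * Do * Ho + (R_xlen_t)ho * Do;
            for (int kw = 0; kw < k; ++kw) {
              double *xw = xb + (R_xlen_t)(wo * stride + kw) * Dp * Hp;
              for (int kh = 0; kh < k; ++kh) {
                double *xh = xw + (R_xlen_t)(ho * stride + kh) * Dp;
                const double *wk = wc + (R_xlen_t)kw * k * k + kh * k;
                for (int kd = 0; kd < k; ++kd) {
                  const double wv = wk[kd];
                  double *xd = xh + kd;
                  if (stride == 1) {
                    for (int dd = 0; dd < Do; ++dd) xd[dd] += wv * dh[dd];
                  } else {
                    for (int dd = 0; dd < Do; ++dd) xd[dd * stride] += wv * dh[dd];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling over k^3 windows of a zero-padded input. Returns pooled values
// (dims Do,Ho,Wo,C,B) and 1-based argmax linear indices into the padded
// input, for the backward scatter.
// [[Rcpp::export]]
List nf_maxpool_fwd(NumericVector x, IntegerVector dims, int k, int stride) {
  const int Dp = dims[0], Hp = dims[1], Wp = dims[2], C = dims[3], B = dims[4];
  const int Do = (Dp - k) / stride + 1;
  const int Ho = (Hp - k) / stride + 1;
  const int Wo = (Wp - k) / stride + 1;
  const R_xlen_t planeC = (R_xlen_t)Dp * Hp * Wp;
  const R_xlen_t n_out = (R_xlen_t)Do * Ho * Wo * C * B;
  NumericVector out(n_out);
  NumericVector arg(n_out);  // double to hold big indices safely
  const double *px = x.begin();
  double *po = out.begin();
  double *pa = arg.begin();
  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t chan0 = (R_xlen_t)b * planeC * C + (R_xlen_t)c * planeC;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          for (int dd = 0; dd < Do; ++dd) {
            double best = R_NegInf;
            R_xlen_t besti = 0;
            for (int kw = 0; kw < k; ++kw) {
              for (int kh = 0; kh < k; ++kh) {
                for (int kd = 0; kd < k; ++kd) {
                  R_xlen_t idx = chan0 +
                    (R_xlen_t)(wo * stride + kw) * Dp * Hp +
                    (R_xlen_t)(ho * stride + kh) * Dp +
                    (dd * stride + kd);
                  double v = px[idx];
                  if (v > best) { best = v; besti = idx; }
                }
              }
            }
            po[o] = best;
            pa[o] = (double)(besti + 1);
            ++o;
          }
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector nf_maxpool_bwd(NumericVector dout, NumericVector argmax, double n_padded) {
  NumericVector dx((R_xlen_t)n_padded);
  const double *pd = dout.begin();
  const double *pa = argmax.begin();
  double *px = dx.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) px[(R_xlen_t)pa[i] - 1] += pd[i];
  return dx;
}
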