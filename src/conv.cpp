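// im2col convolution forward/backward used by the layer library.
// Activation layout is [H, W, N, C] (column-major, H fastest), matching the
// R side. Weight matrices are (k*k*Cin) x Cout with rows ordered
// (row-offset fastest, then column-offset, then input channel).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const double* x, int H, int W, int N, int Ci,
                        int k, int s, int p, int Ho, int Wo) {
  arma::mat M(static_cast<size_t>(Ho) * Wo * N, static_cast<size_t>(k) * k * Ci);
  for (int c = 0; c < Ci; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        double* dst = M.colptr(col);
        for (int n = 0; n < N; ++n) {
          const double* xc = x + (static_cast<size_t>(c) * N + n) * H * W;
          for (int j = 0; j < Wo; ++j) {
            const int sj = j * s + dj - p;
            const size_t base = (static_cast<size_t>(n) * Wo + j) * Ho;
            if (sj < 0 || sj >= W) {
              for (int i = 0; i < Ho; ++i) dst[base + i] = 0.0;
              continue;
            }
            const double* xcol = xc + static_cast<size_t>(sj) * H;
            for (int i = 0; i < Ho; ++i) {
              const int si = i * s + di - p;
              dst[base + i] = (si >= 0 && si < H) ? xcol[si] : 0.0;
            }
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
List conv_fwd_cpp(NumericVector x, IntegerVector dims, const arma::mat& W,
                  NumericVector b, int k, int s, int p) {
  const int H = dims[0], Wd = dims[1], N = dims[2], Ci = dims[3];
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (Wd + 2 * p - k) / s + 1;
  arma::mat M = im2col(x.begin(), H, Wd, N, Ci, k, s, p, Ho, Wo);
  arma::mat Y = M * W;
  Y.each_row() += arma::rowvec(b.begin(), b.size());
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, (int) W.n_cols);
  return List::create(_["out"] = out, _["M"] = M,
                      _["ho"] = Ho, _["wo"] = Wo);
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(const arma::mat& M, const arma::mat& W, NumericVector dy,
                  IntegerVector in_dims, int k, int s, int p,
                  int Ho, int Wo) {
  const int H = in_dims[0], Wd = in_dims[1], N = in_dims[2], Ci = in_dims[3];
  const int Co = (int) W.n_cols;
  arma::mat dY(dy.begin(), static_cast<size_t>(Ho) * Wo * N, Co, false);
  arma::mat dW = M.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dM = dY * W.t();

  NumericVector dx(static_cast<R_xlen_t>(H) * Wd * N * Ci);
  double* dxp = dx.begin();
  for (int c = 0; c < Ci; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        const double* src = dM.colptr(col);
        for (int n = 0; n < N; ++n) {
          double* xc = dxp + (static_cast<size_t>(c) * N + n) * H * Wd;
          for (int j = 0; j < Wo; ++j) {
            const int sj = j * s + dj - p;
            if (sj < 0 || sj >= Wd) continue;
            double* xcol = xc + static_cast<size_t>(sj) * H;
            const size_t base = (static_cast<size_t>(n) * Wo + j) * Ho;
            for (int i = 0; i < Ho; ++i) {
              const int si = i * s + di - p;
              if (si >= 0 && si < H) xcol[si] += src[base + i];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, Wd, N, Ci);
  return List::create(_["dW"] = dW, _["db"] = NumericVector(db.begin(), db.end()),
                      _["dx"] = dx);
}

// Batch normalization over an (m x C) activation where each channel is one
// contiguous column (both the [H,W,N,C] conv layout collapsed to
// (H*W*N) x C and the dense [N, D] case).

// [[Rcpp::export(name = ".bn_fwd_cpp")]]
List bn_fwd_cpp(NumericVector x, int m, int C, NumericVector gamma,
                NumericVector beta, NumericVector run_mean,
                NumericVector run_var, double eps, bool training) {
  NumericVector out(x.size()), xhat(x.size());
  NumericVector mu(C), v(C), inv(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + static_cast<size_t>(c) * m;
    double mean, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int i = 0; i < m; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mean = s / m;
      var = s2 / m - mean * mean;
      if (var < 0) var = 0;
    } else {
      mean = run_mean[c];
      var = run_var[c];
    }
    const double ic = 1.0 / std::sqrt(var + eps);
    const double g = gamma[c], b = beta[c];
    double* oc = out.begin() + static_cast<size_t>(c) * m;
    double* hc = xhat.begin() + static_cast<size_t>(c) * m;
    for (int i = 0; i < m; ++i) {
      const double h = (xc[i] - mean) * ic;
      hc[i] = h;
      oc[i] = g * h + b;
    }
    mu[c] = mean; v[c] = var; inv[c] = ic;
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mu"] = mu,
                      _["v"] = v, _["inv"] = inv);
}

// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(NumericVector xhat, NumericVector inv, NumericVector gamma,
                NumericVector dy, int m, int C) {
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* hc = xhat.begin() + static_cast<size_t>(c) * m;
    const double* dc = dy.begin() + static_cast<size_t>(c) * m;
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < m; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c] * inv[c];
    const double mg = sg / m, mb = sb / m;
    double* xc = dx.begin() + static_cast<size_t>(c) * m;
    for (int i = 0; i < m; ++i) {
      xc[i] = g * (dc[i] - mb - hc[i] * mg);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
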