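// Batched 1D convolution kernels for the residual CNN.
//
// Activations are (channels x time*batch) column-major matrices, batch
// elements stacked along columns in blocks of the temporal length. The
// convolution is computed as one BLAS matrix product on an im2col buffer
// built here (building it in R would allocate and zero hundreds of MB per
// minibatch). Zero padding is implicit in the buffer construction.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Minibatch training allocates and frees multi-hundred-MB im2col buffers
// every step; with glibc's default mmap threshold each round trip returns
// the pages to the kernel and the next step faults them back in, roughly
// doubling wall time. Raising the thresholds keeps the buffers on the heap
// for reuse.
// [[Rcpp::export(name = ".tune_allocator_cpp")]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// Fill the im2col buffer: X2 has C_in*K rows and T_out*B columns; column
// (b, t_out) holds the K input frames covering output position t_out.
static void im2col(const mat &xm, int T, int B, int K, int stride, int pad,
                   int T_out, mat &x2) {
  const int C_in = xm.n_rows;
  for (int b = 0; b < B; ++b) {
    const double *xb = xm.colptr((size_t)b * T);
    for (int t = 0; t < T_out; ++t) {
      double *dst = x2.colptr((size_t)b * T_out + t);
      const int start = t * stride - pad;
      for (int k = 0; k < K; ++k) {
        const int ti = start + k;
        if (ti >= 0 && ti < T)
          std::memcpy(dst + (size_t)k * C_in, xb + (size_t)ti * C_in,
                      C_in * sizeof(double));
        else
          std::memset(dst + (size_t)k * C_in, 0, C_in * sizeof(double));
      }
    }
  }
}

// [[Rcpp::export(name = ".conv1d_fw_cpp")]]
Rcpp::List conv1d_fw_cpp(const arma::mat &xm, int T, int B,
                         const arma::mat &w2, int K, int stride, int pad) {
  const int T_out = (T + 2 * pad - K) / stride + 1;
  mat x2((size_t)xm.n_rows * K, (size_t)T_out * B, fill::none);
  im2col(xm, T, B, K, stride, pad, T_out, x2);
  mat y = w2 * x2;
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("T_out") = T_out);
}

// [[Rcpp::export(name = ".conv1d_bw_cpp")]]
Rcpp::List conv1d_bw_cpp(const arma::mat &xm, const arma::mat &dyf, int T,
                         int B, const arma::mat &w2, int K, int stride,
                         int pad) {
  const int C_in = xm.n_rows;
  const int T_out = (T + 2 * pad - K) / stride + 1;
  mat x2((size_t)C_in * K, (size_t)T_out * B, fill::none);
  im2col(xm, T, B, K, stride, pad, T_out, x2);

  mat dw2 = dyf * x2.t();
  mat dx2 = w2.t() * dyf;       // (C_in*K) x (T_out*B)

  mat dx(C_in, (size_t)T * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    double *xb = dx.colptr((size_t)b * T);
    for (int t = 0; t < T_out; ++t) {
      const double *src = dx2.colptr((size_t)b * T_out + t);
      const int start = t * stride - pad;
      for (int k = 0; k < K; ++k) {
        const int ti = start + k;
        if (ti < 0 || ti >= T) continue;
        double *dst = xb + (size_t)ti * C_in;
        const double *s = src + (size_t)k * C_in;
        for (int c = 0; c < C_in; ++c) dst[c] += s[c];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw2);
}

// Fused batchnorm + ReLU + inverted-dropout forward used on the training
// hot path: y = act(g * (x - mu) * ivar + be) * mask, with the combined
// multiplicative mask (relu derivative x dropout scale) returned for the
// backward pass. `keep` holds pre-drawn uniforms (empty => no dropout).
// [[Rcpp::export(name = ".bn_act_fw_cpp")]]
Rcpp::List bn_act_fw_cpp(const arma::mat &xm, const arma::vec &g,
                         const arma::vec &be, const arma::vec &mu,
                         const arma::vec &ivar, const arma::vec &keep,
                         double p) {
  const int C = xm.n_rows;
  const size_t N = xm.n_cols;
  mat xhat(C, N, fill::none), y(C, N, fill::none), mask(C, N, fill::none);
  const bool drop = keep.n_elem > 0;
  const double scale = drop ? 1.0 / (1.0 - p) : 1.0;
  const double *kp = drop ? keep.memptr() : nullptr;
  for (size_t j = 0; j < N; ++j) {
    const double *x = xm.colptr(j);
    double *xh = xhat.colptr(j), *yy = y.colptr(j), *mm = mask.colptr(j);
    for (int c = 0; c < C; ++c) {
      const double h = (x[c] - mu[c]) * ivar[c];
      xh[c] = h;
      const double a = g[c] * h + be[c];
      double m = a > 0 ? 1.0 : 0.0;
      if (drop && kp[j * C + c] < p) m = 0.0;
      m *= scale;
      mm[c] = m;
      yy[c] = a * m;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("mask") = mask);
}
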