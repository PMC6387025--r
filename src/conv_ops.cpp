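#include <Rcpp.h>
using namespace Rcpp;

// Valid ("no padding") 1-D convolutions along time, evaluated directly with
// cache-blocked accumulation loops. Activations are matrices whose rows are
// (time, block) positions laid out time-fastest within each of n_blocks
// independent sequences of length H_in, and whose columns are features.
// Weights are (k, fin, fout) arrays in R layout: w[j + fi*k + fo*k*fin].

// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(const NumericMatrix& M, const NumericVector& w,
                           int H_in, int k, int fout, int n_blocks) {
  const int fin = M.ncol();
  const int H_out = H_in - k + 1;
  const std::size_t NM = (std::size_t)H_in * n_blocks;
  const std::size_t NZ = (std::size_t)H_out * n_blocks;
  NumericMatrix Z((R_xlen_t)NZ, fout);
  const double* Mp = M.begin();
  const double* wp = w.begin();
  double* Zp = Z.begin();
  for (int b = 0; b < n_blocks; ++b) {
    for (int fo = 0; fo < fout; ++fo) {
      double* __restrict__ z = Zp + fo * NZ + (std::size_t)b * H_out;
      for (int fi = 0; fi < fin; ++fi) {
        const double* m = Mp + fi * NM + (std::size_t)b * H_in;
        const double* wc = wp + ((std::size_t)fo * fin + fi) * k;
        for (int j = 0; j < k; ++j) {
          const double wv = wc[j];
          const double* __restrict__ mj = m + j;
          for (int t = 0; t < H_out; ++t) z[t] += wv * mj[t];
        }
      }
    }
  }
  return Z;
}

// gradient w.r.t. the weights: dW[j, fi, fo] = sum_{t,b} M[t+j, fi] dZ[t, fo]
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_w(const NumericMatrix& M, const NumericMatrix& dZ,
                             int H_in, int k, int n_blocks) {
  const int fin = M.ncol();
  const int fout = dZ.ncol();
  const int H_out = H_in - k + 1;
  const std::size_t NM = (std::size_t)H_in * n_blocks;
  const std::size_t NZ = (std::size_t)H_out * n_blocks;
  NumericVector dW((R_xlen_t)k * fin * fout);
  dW.attr("dim") = IntegerVector::create(k, fin, fout);
  const double* Mp = M.begin();
  const double* dZp = dZ.begin();
  double* dWp = dW.begin();
  for (int b = 0; b < n_blocks; ++b) {
    for (int fo = 0; fo < fout; ++fo) {
      const double* __restrict__ z = dZp + fo * NZ + (std::size_t)b * H_out;
      for (int fi = 0; fi < fin; ++fi) {
        const double* m = Mp + fi * NM + (std::size_t)b * H_in;
        double* wc = dWp + ((std::size_t)fo * fin + fi) * k;
        for (int j = 0; j < k; ++j) {
          const double* __restrict__ mj = m + j;
          // 4-way unrolled reduction: breaks the add latency chain
          double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
          int t = 0;
          for (; t + 3 < H_out; t += 4) {
            a0 += mj[t] * z[t];
            a1 += mj[t + 1] * z[t + 1];
            a2 += mj[t + 2] * z[t + 2];
            a3 += mj[t + 3] * z[t + 3];
          }
          for (; t < H_out; ++t) a0 += mj[t] * z[t];
          wc[j] += (a0 + a1) + (a2 + a3);
        }
      }
    }
  }
  return dW;
}

// gradient w.r.t. the input: dM[t+j, fi] += w[j, fi, fo] dZ[t, fo]
// [[Rcpp::export]]
NumericMatrix cpp_conv_bwd_x(const NumericMatrix& dZ, const NumericVector& w,
                             int H_in, int k, int fin, int n_blocks) {
  const int fout = dZ.ncol();
  const int H_out = H_in - k + 1;
  const std::size_t NM = (std::size_t)H_in * n_blocks;
  const std::size_t NZ = (std::size_t)H_out * n_blocks;
  NumericMatrix dM((R_xlen_t)NM, fin);
  const double* dZp = dZ.begin();
  const double* wp = w.begin();
  double* dMp = dM.begin();
  for (int b = 0; b < n_blocks; ++b) {
    for (int fi = 0; fi < fin; ++fi) {
      double* m = dMp + fi * NM + (std::size_t)b * H_in;
      for (int fo = 0; fo < fout; ++fo) {
        const double* z = dZp + fo * NZ + (std::size_t)b * H_out;
        const double* wc = wp + ((std::size_t)fo * fin + fi) * k;
        for (int j = 0; j < k; ++j) {
          const double wv = wc[j];
          double* __restrict__ mj = m + j;
          const double* __restrict__ zz = z;
          for (int t = 0; t < H_out; ++t) mj[t] += wv * zz[t];
        }
      }
    }
  }
  return dM;
}
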