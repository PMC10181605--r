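// Batched kernels for one convolution block of the shock-advisory
// network: Conv1D ("same" zero padding, stride 1) -> ReLU ->
// MaxPool(2). Dropout and the dense head stay in R (the dropout mask
// must come from R's RNG stream for seed reproducibility).
//
// Activations are (C*length) x B matrices with the channel index
// fastest. With zero padding baked into the rows of Ap, the im2col
// column for output position t of sample b is a contiguous slice of
// Ap's column b, and the whole convolution is a single BLAS gemm.
// Backward recomputes the ReLU/pool decisions from the stored
// pre-activation Y instead of shipping mask matrices back and forth.
//
// Arithmetic runs in single precision, as deep-learning frameworks
// train by default; R sees doubles at the interface. The large scratch
// matrices are recycled between calls (shapes repeat every minibatch)
// to avoid allocator traffic.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>

using arma::fmat;
using arma::fvec;
using arma::mat;
using arma::vec;

static std::map<std::pair<int, std::pair<size_t, size_t> >, fmat>&
scratch_pool() {
  static std::map<std::pair<int, std::pair<size_t, size_t> >, fmat> pool;
  return pool;
}

// evict the pool between kernel calls only: references handed out by
// scratch() below stay valid for the duration of one exported call
static void scratch_gc(size_t max_entries) {
  if (scratch_pool().size() > max_entries) scratch_pool().clear();
}

static fmat& scratch(int slot, size_t rows, size_t cols) {
  fmat& m = scratch_pool()[std::make_pair(slot,
                                          std::make_pair(rows, cols))];
  if (m.n_rows != rows || m.n_cols != cols) m.set_size(rows, cols);
  return m;
}

static void fill_im2col(const fmat& Ap, fmat& Xcol, int N, int K, int C) {
  const int B = Ap.n_cols;
  const size_t KC = (size_t)K * C;
  for (int bb = 0; bb < B; ++bb) {
    const float* src = Ap.colptr(bb);
    for (int t = 0; t < N; ++t) {
      std::memcpy(Xcol.colptr((size_t)bb * N + t), src + (size_t)C * t,
                  sizeof(float) * KC);
    }
  }
}

// zero-pad A (C*N x B) to Ap (C*(N+K-1) x B) with padL leading positions
static void pad_activation(const mat& A, fmat& Ap, int N, int K, int C,
                           int padL) {
  const int B = A.n_cols;
  const int Npad = N + K - 1;
  Ap.zeros((size_t)C * Npad, B);
  for (int bb = 0; bb < B; ++bb) {
    const double* src = A.colptr(bb);
    float* dst = Ap.colptr(bb) + (size_t)C * padL;
    for (size_t j = 0; j < (size_t)C * N; ++j) dst[j] = (float)src[j];
  }
}

// forward for one block. A: (C*N) x B input. Returns
//   P  : (F*No) x B pooled ReLU output (No = N %/% 2)
//   Y  : F x (N*B) pre-activation (kept for backward)
//   Ap : padded input in floats (kept for backward)
// [[Rcpp::export]]
Rcpp::List conv_block_fwd(const arma::mat& A, const arma::mat& W,
                          const arma::vec& b, int N, int K, int C) {
  const int B = A.n_cols;
  const int F = W.n_rows;
  const int padL = (K - 1) / 2;
  const int No = N / 2;
  scratch_gc(24);
  fmat Ap;
  pad_activation(A, Ap, N, K, C, padL);
  fmat& Xcol = scratch(0, (size_t)K * C, (size_t)N * B);
  fill_im2col(Ap, Xcol, N, K, C);
  fmat Wf = arma::conv_to<fmat>::from(W);
  fvec bf = arma::conv_to<fvec>::from(b);
  fmat Y = Wf * Xcol;
  Y.each_col() += bf;
  mat P((size_t)F * No, B);
  for (int bb = 0; bb < B; ++bb) {
    double* dst = P.colptr(bb);
    for (int j = 0; j < No; ++j) {
      const float* y1 = Y.colptr((size_t)bb * N + 2 * j);
      const float* y2 = Y.colptr((size_t)bb * N + 2 * j + 1);
      double* d = dst + (size_t)F * j;
      for (int f = 0; f < F; ++f) {
        float z1 = y1[f] > 0 ? y1[f] : 0;
        float z2 = y2[f] > 0 ? y2[f] : 0;
        d[f] = (double)(z1 >= z2 ? z1 : z2);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("P") = P,
                            Rcpp::Named("Y") = Y,
                            Rcpp::Named("Ap") = Ap);
}

// backward for one block. dP: (F*No) x B gradient at the pooled output
// (dropout already applied by the caller). Y and Ap are the float
// caches from conv_block_fwd. Returns dW, db and -- when need_dA --
// dA ((C*N) x B) for the previous block.
// [[Rcpp::export]]
Rcpp::List conv_block_bwd(const arma::fmat& Ap, const arma::mat& W,
                          const arma::fmat& Y, const arma::mat& dP,
                          int N, int K, int C, bool need_dA) {
  const int B = Ap.n_cols;
  const int F = W.n_rows;
  const int padL = (K - 1) / 2;
  const int No = N / 2;
  scratch_gc(24);
  // un-pool + ReLU gradient: dY (F x N*B)
  fmat& dY = scratch(2, (size_t)F, (size_t)N * B);
  dY.zeros();
  for (int bb = 0; bb < B; ++bb) {
    const double* src = dP.colptr(bb);
    for (int j = 0; j < No; ++j) {
      const float* y1 = Y.colptr((size_t)bb * N + 2 * j);
      const float* y2 = Y.colptr((size_t)bb * N + 2 * j + 1);
      float* d1 = dY.colptr((size_t)bb * N + 2 * j);
      float* d2 = dY.colptr((size_t)bb * N + 2 * j + 1);
      const double* s = src + (size_t)F * j;
      for (int f = 0; f < F; ++f) {
        float z1 = y1[f] > 0 ? y1[f] : 0;
        float z2 = y2[f] > 0 ? y2[f] : 0;
        // winner takes the gradient; ReLU blocks non-positive inputs
        if (z1 >= z2) {
          if (y1[f] > 0) d1[f] = (float)s[f];
        } else if (y2[f] > 0) {
          d2[f] = (float)s[f];
        }
      }
    }
  }
  fmat& Xcol = scratch(0, (size_t)K * C, (size_t)N * B);
  fill_im2col(Ap, Xcol, N, K, C);
  fmat Wf = arma::conv_to<fmat>::from(W);
  mat dW = arma::conv_to<mat>::from(dY * Xcol.t());
  vec db = arma::conv_to<vec>::from(fvec(arma::sum(dY, 1)));
  mat dA;
  if (need_dA) {
    fmat& dXcol = scratch(1, (size_t)K * C, (size_t)N * B);
    dXcol = Wf.t() * dY;               // (K*C) x (N*B)
    const size_t KC = (size_t)K * C;
    fmat& dAp = scratch(3, Ap.n_rows, (size_t)B);
    dAp.zeros();
    for (int bb = 0; bb < B; ++bb) {
      float* dst = dAp.colptr(bb);
      for (int t = 0; t < N; ++t) {
        const float* s = dXcol.colptr((size_t)bb * N + t);
        float* d = dst + (size_t)C * t;
        for (size_t j = 0; j < KC; ++j) d[j] += s[j];
      }
    }
    // strip the padding rows
    dA.set_size((size_t)C * N, B);
    for (int bb = 0; bb < B; ++bb) {
      const float* s = dAp.colptr(bb) + (size_t)C * padL;
      double* d = dA.colptr(bb);
      for (size_t j = 0; j < (size_t)C * N; ++j) d[j] = (double)s[j];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dA") = dA);
}
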