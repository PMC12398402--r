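// Numerical core: Elman-style recurrent forward pass with per-window weight
// switching, backpropagation through time for the window-wise gradients, and
// input-space gradients for path-integral attribution.
//
// Conventions shared with the R side:
//   X is an [n_trials, T, R] array; hidden states are row-major per trial,
//   i.e. H is n x N and the recursion is H <- tanh(H %*% t(W_h) + X_t %*%
//   t(W_x) + b_h).  Window assignment `win` is a 0-based index per time step.
//   Training runs in single precision (the convention of the deep-learning
//   frameworks this mirrors); analysis-time forward passes and attribution
//   gradients run in double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

#if defined(__SSE2__)
#include <immintrin.h>
#endif

namespace {

// Gradients shrink exponentially through long horizons; without this the
// backward pass spends most of its time in denormal-float arithmetic.
inline void flush_denormals() {
#if defined(__SSE2__)
  _mm_setcsr(_mm_getcsr() | 0x8040);  // FTZ | DAZ
#endif
}

struct WinW {
  arma::mat Wx, Wh;   // N x R, N x N
  arma::vec wy, bh;   // N
  double by;
};

struct WinWf {
  arma::fmat Wx, Wh;
  arma::fvec wy, bh;
  float by;
};

std::vector<WinW> unpack_windows(const List& windows) {
  std::vector<WinW> out(windows.size());
  for (int k = 0; k < windows.size(); ++k) {
    List w = windows[k];
    out[k].Wx = as<arma::mat>(w["W_x"]);
    out[k].Wh = as<arma::mat>(w["W_h"]);
    out[k].wy = as<arma::vec>(w["w_y"]);
    out[k].bh = as<arma::vec>(w["b_h"]);
    out[k].by = as<double>(w["b_y"]);
  }
  return out;
}

std::vector<WinWf> unpack_windows_f(const List& windows) {
  std::vector<WinWf> out(windows.size());
  for (int k = 0; k < windows.size(); ++k) {
    List w = windows[k];
    out[k].Wx = arma::conv_to<arma::fmat>::from(as<arma::mat>(w["W_x"]));
    out[k].Wh = arma::conv_to<arma::fmat>::from(as<arma::mat>(w["W_h"]));
    out[k].wy = arma::conv_to<arma::fvec>::from(as<arma::vec>(w["w_y"]));
    out[k].bh = arma::conv_to<arma::fvec>::from(as<arma::vec>(w["b_h"]));
    out[k].by = (float) as<double>(w["b_y"]);
  }
  return out;
}

// slice t of the [n, T, R] array as an n x R matrix
template <typename M>
void fill_slice(M& dst, const double* x, int n, int T, int R, int t) {
  for (int r = 0; r < R; ++r) {
    const double* col = x + (size_t) n * (t + (size_t) T * r);
    for (int i = 0; i < n; ++i) dst(i, r) = col[i];
  }
}

}  // namespace

// Forward pass in double precision.  Returns per-time-point sigmoid outputs
// and, optionally, the full hidden trajectory.
// [[Rcpp::export(name = ".cpp_forward")]]
List cpp_forward(NumericVector X, List windows, IntegerVector win, bool keep_h) {
  flush_denormals();
  IntegerVector dims = X.attr("dim");
  int n = dims[0], T = dims[1], R = dims[2];
  std::vector<WinW> W = unpack_windows(windows);
  int N = W[0].Wh.n_rows;

  arma::mat H(n, N, arma::fill::zeros);
  arma::mat Xt(n, R);
  NumericMatrix Y(n, T);
  arma::cube Hc;
  if (keep_h) Hc.set_size(n, N, T);

  for (int t = 0; t < T; ++t) {
    const WinW& w = W[win[t]];
    fill_slice(Xt, X.begin(), n, T, R, t);
    H = arma::tanh(H * w.Wh.t() + Xt * w.Wx.t() +
                   arma::repmat(w.bh.t(), n, 1));
    arma::vec z = H * w.wy + w.by;
    for (int i = 0; i < n; ++i) Y(i, t) = 1.0 / (1.0 + std::exp(-z(i)));
    if (keep_h) Hc.slice(t) = H;
  }
  List out = List::create(Named("y") = Y);
  if (keep_h) {
    NumericVector h(Hc.begin(), Hc.end());
    h.attr("dim") = IntegerVector::create(n, N, T);
    out["h"] = h;
  }
  return out;
}

// Forward pass in single precision (training path); outputs only.
// [[Rcpp::export(name = ".cpp_forward_f")]]
NumericMatrix cpp_forward_f(NumericVector X, List windows, IntegerVector win) {
  flush_denormals();
  IntegerVector dims = X.attr("dim");
  int n = dims[0], T = dims[1], R = dims[2];
  std::vector<WinWf> W = unpack_windows_f(windows);
  int N = W[0].Wh.n_rows;

  arma::fmat H(n, N, arma::fill::zeros);
  arma::fmat Xt(n, R);
  NumericMatrix Y(n, T);
  for (int t = 0; t < T; ++t) {
    const WinWf& w = W[win[t]];
    fill_slice(Xt, X.begin(), n, T, R, t);
    H = arma::tanh(H * w.Wh.t() + Xt * w.Wx.t() +
                   arma::repmat(w.bh.t(), n, 1));
    arma::fvec z = H * w.wy + w.by;
    for (int i = 0; i < n; ++i) Y(i, t) = 1.0 / (1.0 + std::exp(-z(i)));
  }
  return Y;
}

// One forward + backward pass over a batch: mean-over-trials binary
// cross-entropy with per-time-step weights `loss_w` (sums to 1 over the
// steps it covers), gradients accumulated per window.  Single precision.
// [[Rcpp::export(name = ".cpp_train_grad")]]
List cpp_train_grad(NumericVector X, NumericVector ylab, List windows,
                    IntegerVector win, NumericVector loss_w) {
  flush_denormals();
  IntegerVector dims = X.attr("dim");
  int n = dims[0], T = dims[1], R = dims[2];
  std::vector<WinWf> W = unpack_windows_f(windows);
  int N = W[0].Wh.n_rows;
  int K = (int) W.size();

  arma::fvec y = arma::conv_to<arma::fvec>::from(as<arma::vec>(ylab));

  // forward, keeping hidden states and probabilities
  arma::fcube Hc(n, N, T);
  arma::fmat P(n, T);
  std::vector<arma::fmat> Xts(T, arma::fmat(n, R));
  {
    arma::fmat H(n, N, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      const WinWf& w = W[win[t]];
      fill_slice(Xts[t], X.begin(), n, T, R, t);
      H = arma::tanh(H * w.Wh.t() + Xts[t] * w.Wx.t() +
                     arma::repmat(w.bh.t(), n, 1));
      Hc.slice(t) = H;
      arma::fvec z = H * w.wy + w.by;
      P.col(t) = 1.0f / (1.0f + arma::exp(-z));
    }
  }

  // loss
  double loss = 0.0;
  const float eps = 1e-12f;
  for (int t = 0; t < T; ++t) {
    if (loss_w[t] == 0) continue;
    arma::fvec p = P.col(t);
    arma::fvec l = -(y % arma::log(p + eps) + (1.0f - y) % arma::log(1.0f - p + eps));
    loss += loss_w[t] * arma::mean(l);
  }

  // backward
  std::vector<arma::fmat> gWx(K), gWh(K);
  std::vector<arma::fvec> gwy(K), gbh(K);
  std::vector<float> gby(K, 0.0f);
  for (int k = 0; k < K; ++k) {
    gWx[k].zeros(N, R); gWh[k].zeros(N, N);
    gwy[k].zeros(N); gbh[k].zeros(N);
  }

  arma::fmat dH(n, N, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    int k = win[t];
    const WinWf& w = W[k];
    const arma::fmat& Ht = Hc.slice(t);
    if (loss_w[t] != 0) {
      arma::fvec dz = (P.col(t) - y) * (float)(loss_w[t] / n);
      gwy[k] += Ht.t() * dz;
      gby[k] += arma::accu(dz);
      dH += dz * w.wy.t();
    }
    arma::fmat dA = dH % (1.0f - Ht % Ht);
    if (t > 0) gWh[k] += dA.t() * Hc.slice(t - 1);
    gWx[k] += dA.t() * Xts[t];
    gbh[k] += arma::sum(dA, 0).t();
    dH = dA * w.Wh;
  }

  List grads(K);
  for (int k = 0; k < K; ++k) {
    grads[k] = List::create(
      Named("W_x") = wrap(arma::conv_to<arma::mat>::from(gWx[k])),
      Named("W_h") = wrap(arma::conv_to<arma::mat>::from(gWh[k])),
      Named("w_y") = wrap(arma::conv_to<arma::vec>::from(gwy[k])),
      Named("b_h") = wrap(arma::conv_to<arma::vec>::from(gbh[k])),
      Named("b_y") = (double) gby[k]);
  }
  return List::create(Named("loss") = loss, Named("grads") = grads);
}

// Gradient of the output y_{t_out} with respect to every input entry, per
// trial, in double precision.  Returns [n, T, R] plus the outputs y_{t_out}.
// [[Rcpp::export(name = ".cpp_input_grad")]]
List cpp_input_grad(NumericVector X, List windows, IntegerVector win, int t_out) {
  flush_denormals();
  IntegerVector dims = X.attr("dim");
  int n = dims[0], T = dims[1], R = dims[2];
  std::vector<WinW> W = unpack_windows(windows);
  int N = W[0].Wh.n_rows;

  arma::cube Hc(n, N, T);
  arma::mat Xt(n, R);
  {
    arma::mat H(n, N, arma::fill::zeros);
    for (int t = 0; t <= t_out; ++t) {
      const WinW& w = W[win[t]];
      fill_slice(Xt, X.begin(), n, T, R, t);
      H = arma::tanh(H * w.Wh.t() + Xt * w.Wx.t() +
                     arma::repmat(w.bh.t(), n, 1));
      Hc.slice(t) = H;
    }
  }
  const WinW& wo = W[win[t_out]];
  arma::vec z = Hc.slice(t_out) * wo.wy + wo.by;
  arma::vec p = 1.0 / (1.0 + arma::exp(-z));

  NumericVector G((size_t) n * T * R);  // zero-initialised
  G.attr("dim") = IntegerVector::create(n, T, R);

  arma::mat dH = (p % (1.0 - p)) * wo.wy.t();  // n x N
  for (int t = t_out; t >= 0; --t) {
    const WinW& w = W[win[t]];
    arma::mat dA = dH % (1.0 - arma::square(Hc.slice(t)));
    arma::mat dX = dA * w.Wx;  // n x R
    for (int r = 0; r < R; ++r) {
      double* col = G.begin() + (size_t) n * (t + (size_t) T * r);
      for (int i = 0; i < n; ++i) col[i] = dX(i, r);
    }
    dH = dA * w.Wh;
  }
  return List::create(Named("grad") = G, Named("y") = wrap(p));
}

// CRC-32 (IEEE 802.3), needed by the NPZ (zip container) writer.
// [[Rcpp::export(name = ".cpp_crc32")]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double) (crc ^ 0xFFFFFFFFu);
}
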