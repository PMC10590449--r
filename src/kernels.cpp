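// Compiled kernels for the pulse network: 1-D convolution (standard and
// depthwise), batch normalization and ReLU, forward and backward.
// Layout: activations are (channels, length, batch) arrays; conv weights
// are (C_out, C_in * k) with column blocks ordered by tap (same convention
// as the plain-R reference implementations in R/net-layers.R, which serve
// as the oracle for these kernels). Stride 1, "same" padding, left pad
// floor((k-1)/2). im2col matrices are rebuilt on the fly, keeping the
// training memory footprint flat. Aux-memory Armadillo views avoid copies
// on the way in.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::List;

static cube view3(NumericVector a) {
  Rcpp::IntegerVector d = a.attr("dim");
  return cube(a.begin(), d[0], d[1], d[2], false, true);
}

static NumericVector alloc3(uword c, uword l, uword b) {
  NumericVector out(c * l * b);
  out.attr("dim") = Rcpp::IntegerVector::create(c, l, b);
  return out;
}

static void im2col_sample(const cube& x, uword b, uword k, uword pl,
                          mat& Xc) {
  const uword C = x.n_rows, L = x.n_cols;
  Xc.zeros(C * k, L);
  for (uword j = 0; j < k; ++j) {
    const int shift = (int)j - (int)pl;
    const int lo = std::max(0, -shift);
    const int hi = std::min((int)L, (int)L - shift);
    for (int l = lo; l < hi; ++l) {
      for (uword c = 0; c < C; ++c) {
        Xc(j * C + c, l) = x(c, l + shift, b);
      }
    }
  }
}

// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
NumericVector conv1d_fwd_cpp(NumericVector x_, const arma::mat& W,
                             const arma::vec& b, int k) {
  cube x = view3(x_);
  const uword L = x.n_cols, B = x.n_slices, Co = W.n_rows;
  const uword pl = (k - 1) / 2;
  NumericVector y_ = alloc3(Co, L, B);
  cube y(y_.begin(), Co, L, B, false, true);
  mat Xc;
  for (uword s = 0; s < B; ++s) {
    im2col_sample(x, s, k, pl, Xc);
    y.slice(s) = W * Xc;
    y.slice(s).each_col() += b;
  }
  return y_;
}

// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
List conv1d_bwd_cpp(NumericVector x_, const arma::mat& W,
                    NumericVector dy_, int k) {
  cube x = view3(x_), dy = view3(dy_);
  const uword C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const uword Co = W.n_rows;
  const uword pl = (k - 1) / 2;
  mat dW(Co, C * k, fill::zeros);
  vec db(Co, fill::zeros);
  NumericVector dx_ = alloc3(C, L, B);
  cube dx(dx_.begin(), C, L, B, false, true);
  mat Xc, dXc;
  for (uword s = 0; s < B; ++s) {
    im2col_sample(x, s, k, pl, Xc);
    const mat& dY = dy.slice(s);
    dW += dY * Xc.t();
    db += sum(dY, 1);
    dXc = W.t() * dY;
    for (uword j = 0; j < (uword)k; ++j) {
      const int shift = (int)j - (int)pl;
      const int lo = std::max(0, -shift);
      const int hi = std::min((int)L, (int)L - shift);
      for (int l = lo; l < hi; ++l) {
        for (uword c = 0; c < C; ++c) {
          dx(c, l + shift, s) += dXc(j * C + c, l);
        }
      }
    }
  }
  return List::create(Rcpp::Named("dx") = dx_,
                      Rcpp::Named("dW") = dW,
                      Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".dwconv_fwd_cpp")]]
NumericVector dwconv_fwd_cpp(NumericVector x_, const arma::mat& Wd, int k) {
  cube x = view3(x_);
  const uword C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const uword pl = (k - 1) / 2;
  NumericVector y_ = alloc3(C, L, B);
  cube y(y_.begin(), C, L, B, false, true);
  y.zeros();
  for (uword s = 0; s < B; ++s) {
    for (uword j = 0; j < (uword)k; ++j) {
      const int shift = (int)j - (int)pl;
      const int lo = std::max(0, -shift);
      const int hi = std::min((int)L, (int)L - shift);
      for (int l = lo; l < hi; ++l) {
        for (uword c = 0; c < C; ++c) {
          y(c, l, s) += Wd(c, j) * x(c, l + shift, s);
        }
      }
    }
  }
  return y_;
}

// [[Rcpp::export(name = ".dwconv_bwd_cpp")]]
List dwconv_bwd_cpp(NumericVector x_, const arma::mat& Wd,
                    NumericVector dy_, int k) {
  cube x = view3(x_), dy = view3(dy_);
  const uword C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const uword pl = (k - 1) / 2;
  mat dWd(C, k, fill::zeros);
  NumericVector dx_ = alloc3(C, L, B);
  cube dx(dx_.begin(), C, L, B, false, true);
  dx.zeros();
  for (uword s = 0; s < B; ++s) {
    for (uword j = 0; j < (uword)k; ++j) {
      const int shift = (int)j - (int)pl;
      const int lo = std::max(0, -shift);
      const int hi = std::min((int)L, (int)L - shift);
      for (int l = lo; l < hi; ++l) {
        for (uword c = 0; c < C; ++c) {
          dWd(c, j) += dy(c, l, s) * x(c, l + shift, s);
          dx(c, l + shift, s) += Wd(c, j) * dy(c, l, s);
        }
      }
    }
  }
  return List::create(Rcpp::Named("dx") = dx_,
                      Rcpp::Named("dWd") = dWd);
}

// batch normalization over (length, batch) per channel, biased variance
// [[Rcpp::export(name = ".bn_train_fwd_cpp")]]
List bn_train_fwd_cpp(NumericVector x_, const arma::vec& gamma,
                      const arma::vec& beta, double eps) {
  cube x = view3(x_);
  const uword C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const double n = (double)(L * B);
  vec mu(C, fill::zeros), v(C, fill::zeros);
  for (uword s = 0; s < B; ++s)
    for (uword l = 0; l < L; ++l)
      for (uword c = 0; c < C; ++c) mu(c) += x(c, l, s);
  mu /= n;
  for (uword s = 0; s < B; ++s)
    for (uword l = 0; l < L; ++l)
      for (uword c = 0; c < C; ++c) {
        const double d = x(c, l, s) - mu(c);
        v(c) += d * d;
      }
  v /= n;
  vec istd = 1.0 / sqrt(v + eps);
  NumericVector y_ = alloc3(C, L, B), xhat_ = alloc3(C, L, B);
  cube y(y_.begin(), C, L, B, false, true);
  cube xhat(xhat_.begin(), C, L, B, false, true);
  for (uword s = 0; s < B; ++s)
    for (uword l = 0; l < L; ++l)
      for (uword c = 0; c < C; ++c) {
        const double h = (x(c, l, s) - mu(c)) * istd(c);
        xhat(c, l, s) = h;
        y(c, l, s) = gamma(c) * h + beta(c);
      }
  return List::create(Rcpp::Named("y") = y_, Rcpp::Named("xhat") = xhat_,
                      Rcpp::Named("mu") = mu, Rcpp::Named("var") = v,
                      Rcpp::Named("istd") = istd);
}

// dx = gamma*istd * (dy - mean(dy) - xhat*mean(dy*xhat)) per channel
// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(NumericVector dy_, NumericVector xhat_,
                const arma::vec& gamma, const arma::vec& istd) {
  cube dy = view3(dy_), xhat = view3(xhat_);
  const uword C = dy.n_rows, L = dy.n_cols, B = dy.n_slices;
  const double n = (double)(L * B);
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  for (uword s = 0; s < B; ++s)
    for (uword l = 0; l < L; ++l)
      for (uword c = 0; c < C; ++c) {
        dgamma(c) += dy(c, l, s) * xhat(c, l, s);
        dbeta(c) += dy(c, l, s);
      }
  NumericVector dx_ = alloc3(C, L, B);
  cube dx(dx_.begin(), C, L, B, false, true);
  vec a = gamma % istd, mb = dbeta / n, mg = dgamma / n;
  for (uword s = 0; s < B; ++s)
    for (uword l = 0; l < L; ++l)
      for (uword c = 0; c < C; ++c) {
        dx(c, l, s) = a(c) *
          (dy(c, l, s) - mb(c) - xhat(c, l, s) * mg(c));
      }
  return List::create(Rcpp::Named("dx") = dx_,
                      Rcpp::Named("dgamma") = dgamma,
                      Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
NumericVector relu_fwd_cpp(NumericVector x_) {
  NumericVector y_(x_.size());
  y_.attr("dim") = x_.attr("dim");
  const double* x = x_.begin();
  double* y = y_.begin();
  for (R_xlen_t i = 0; i < x_.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y_;
}

// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector dy_, NumericVector y_) {
  NumericVector dx_(dy_.size());
  dx_.attr("dim") = dy_.attr("dim");
  const double* dy = dy_.begin();
  const double* y = y_.begin();
  double* dx = dx_.begin();
  for (R_xlen_t i = 0; i < dy_.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  return dx_;
}

// add shortcut then ReLU: y = max(a + b, 0)
// [[Rcpp::export(name = ".add_relu_fwd_cpp")]]
NumericVector add_relu_fwd_cpp(NumericVector a_, NumericVector b_) {
  NumericVector y_(a_.size());
  y_.attr("dim") = a_.attr("dim");
  const double* a = a_.begin();
  const double* b = b_.begin();
  double* y = y_.begin();
  for (R_xlen_t i = 0; i < a_.size(); ++i) {
    const double s = a[i] + b[i];
    y[i] = s > 0 ? s : 0.0;
  }
  return y_;
}
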