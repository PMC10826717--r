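// Minimal dense 2-D convolution primitives for the cGAN layers.
// Layout convention throughout: feature maps are R arrays (H, W, C, N)
// (column-major, so one sample's channels are contiguous cubes) and
// convolution weights are (k, k, Cin, Cout).  Transposed convolution is
// expressed through conv_bwd_x / conv_fwd with the weight roles swapped,
// so only three primitives are needed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void get_dim4(const NumericVector& a, int d[4]) {
  IntegerVector dm = a.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Unfold one sample (H, W, C cube backed by aux memory) into a
// (k*k*C) x (Ho*Wo) matrix; rows ordered ki, kj, c to match the
// column-major flattening of a (k, k, Cin, Cout) weight array.
static void im2col(const arma::cube& x, int k, int s, int p, arma::mat& out) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  out.zeros(k * k * C, Ho * Wo);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * kj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * s - p + kj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * s - p + ki;
            if (i < 0 || i >= H) continue;
            out(row, io + Ho * jo) = x(i, j, c);
          }
        }
      }
}

// Scatter-add the column matrix back onto the (H, W, C) grid.
static void col2im_acc(const arma::mat& cols, int k, int s, int p,
                       arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * kj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * s - p + kj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * s - p + ki;
            if (i < 0 || i >= H) continue;
            x(i, j, c) += cols(row, io + Ho * jo);
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x_, NumericVector w_,
                           NumericVector b_, int stride, int pad) {
  int xd[4], wd[4];
  get_dim4(x_, xd);
  get_dim4(w_, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k) stop("kernel must be square");
  if (wd[2] != C) stop("input channels do not match the weights");
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");

  const arma::mat Wm(const_cast<double*>(&w_[0]), k * k * C, Cout, false);
  const arma::vec bv(const_cast<double*>(&b_[0]), Cout, false);

  NumericVector y_(Ho * Wo * Cout * N);
  y_.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    const arma::cube xc(const_cast<double*>(&x_[0]) + (size_t)n * H * W * C,
                        H, W, C, false);
    im2col(xc, k, stride, pad, cols);
    // (Ho*Wo) x Cout, column-major == the (Ho, Wo, Cout) output cube
    arma::mat ym = cols.t() * Wm;
    ym.each_row() += bv.t();
    std::memcpy(&y_[0] + (size_t)n * Ho * Wo * Cout, ym.memptr(),
                sizeof(double) * ym.n_elem);
  }
  return y_;
}

// Gradient w.r.t. the convolution input (also the forward pass of a
// stride-s transposed convolution).  Hx, Wx give the target spatial size.
// [[Rcpp::export]]
NumericVector conv_bwd_x_cpp(NumericVector dy_, NumericVector w_, int stride,
                             int pad, int Hx, int Wx) {
  int yd[4], wd[4];
  get_dim4(dy_, yd);
  get_dim4(w_, wd);
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2], N = yd[3];
  const int k = wd[0], C = wd[2];
  if (wd[3] != Cout) stop("gradient channels do not match the weights");
  if ((Hx + 2 * pad - k) / stride + 1 != Ho ||
      (Wx + 2 * pad - k) / stride + 1 != Wo)
    stop("target size is inconsistent with the gradient size");

  const arma::mat Wm(const_cast<double*>(&w_[0]), k * k * C, Cout, false);

  NumericVector dx_(Hx * Wx * C * N);
  dx_.attr("dim") = IntegerVector::create(Hx, Wx, C, N);

  for (int n = 0; n < N; ++n) {
    const arma::mat dym(const_cast<double*>(&dy_[0]) +
                            (size_t)n * Ho * Wo * Cout,
                        Ho * Wo, Cout, false);
    arma::mat cols = Wm * dym.t();  // (k*k*C) x (Ho*Wo)
    arma::cube dxc(&dx_[0] + (size_t)n * Hx * Wx * C, Hx, Wx, C, false, true);
    col2im_acc(cols, k, stride, pad, dxc);
  }
  return dx_;
}

// Gradient w.r.t. weights and bias; returns list(dw, db).
// [[Rcpp::export]]
List conv_bwd_w_cpp(NumericVector x_, NumericVector dy_, int k, int stride,
                    int pad) {
  int xd[4], yd[4];
  get_dim4(x_, xd);
  get_dim4(dy_, yd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  if (yd[3] != N) stop("batch sizes differ");

  arma::mat dW(k * k * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    const arma::cube xc(const_cast<double*>(&x_[0]) + (size_t)n * H * W * C,
                        H, W, C, false);
    const arma::mat dym(const_cast<double*>(&dy_[0]) +
                            (size_t)n * Ho * Wo * Cout,
                        Ho * Wo, Cout, false);
    im2col(xc, k, stride, pad, cols);
    dW += cols * dym;
    db += dym.t() * arma::ones<arma::vec>(Ho * Wo);
  }
  NumericVector dw_(k * k * C * Cout);
  std::memcpy(&dw_[0], dW.memptr(), sizeof(double) * dW.n_elem);
  dw_.attr("dim") = IntegerVector::create(k, k, C, Cout);
  NumericVector db_(Cout);
  std::memcpy(&db_[0], db.memptr(), sizeof(double) * Cout);
  return List::create(_["dw"] = dw_, _["db"] = db_);
}
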