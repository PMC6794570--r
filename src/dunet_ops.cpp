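// Convolutional primitives for the densely connected U-Net: same-padded
// k x k convolution (im2col + GEMM), 2x2 max pooling, and 2x2 stride-2
// transposed convolution, each with its backward pass. Feature maps are
// H x W x C cubes; convolution weights are (k*k*Cin) x Cout matrices with
// the (dr, dc, ci) index fastest in rows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col_same(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = k / 2;
  mat cols(k * k * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        const int row = c * k * k + dc * k + dr;
        const int orow = dr - p, ocol = dc - p;
        const int r0 = std::max(0, -orow), r1 = std::min(H, H - orow);
        const int c0 = std::max(0, -ocol), c1 = std::min(W, W - ocol);
        for (int j = c0; j < c1; ++j) {
          const double* src = xc.colptr(j + ocol);
          double* dst = cols.colptr(j * H);
          // strided write: element (row, j*H + i)
          for (int i = r0; i < r1; ++i)
            dst[(std::size_t)i * cols.n_rows + row] = src[i + orow];
        }
      }
    }
  }
  return cols;
}

static void col2im_same(const mat& cols, int H, int W, int C, int k, cube& out) {
  const int p = k / 2;
  out.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    mat& oc = out.slice(c);
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        const int row = c * k * k + dc * k + dr;
        const int orow = dr - p, ocol = dc - p;
        const int r0 = std::max(0, -orow), r1 = std::min(H, H - orow);
        const int c0 = std::max(0, -ocol), c1 = std::min(W, W - ocol);
        for (int j = c0; j < c1; ++j) {
          double* dst = oc.colptr(j + ocol);
          const double* src = cols.colptr(j * H);
          for (int i = r0; i < r1; ++i)
            dst[i + orow] += src[(std::size_t)i * cols.n_rows + row];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k, bool relu) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  mat cols = im2col_same(x, k);
  mat y = W.t() * cols;           // Cout x (H*W)
  y.each_col() += b;
  if (relu) y = clamp(y, 0.0, datum::inf);
  cube out(H, Wd, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.row(c), H, Wd);
  return out;
}

// dY is the gradient at the (post-activation) output; `y` the forward
// output (used for the ReLU derivative mask when relu = true).
// [[Rcpp::export(name = ".conv2d_backward")]]
Rcpp::List conv2d_backward(const arma::cube& x, const arma::mat& W,
                           const arma::cube& y, const arma::cube& dy,
                           int k, bool relu) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  mat dy_m(Cout, H * Wd);
  for (int c = 0; c < Cout; ++c) {
    if (relu) {
      mat g = dy.slice(c) % conv_to<mat>::from(y.slice(c) > 0);
      dy_m.row(c) = vectorise(g).t();
    } else {
      dy_m.row(c) = vectorise(dy.slice(c)).t();
    }
  }
  mat cols = im2col_same(x, k);
  mat dW = cols * dy_m.t();              // (k*k*Cin) x Cout
  vec db = sum(dy_m, 1);
  mat dcols = W * dy_m;                  // (k*k*Cin) x (H*W)
  cube dx;
  col2im_same(dcols, H, Wd, Cin, k, dx);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool_forward")]]
Rcpp::List maxpool_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube arg(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf; uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            uword idx = (uword)(2 * j + dj) * H + (2 * i + di);
            double v = xc[idx];
            if (v > best) { best = v; bi = idx; }
          }
        y(i, j, c) = best;
        arg(i, j, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("arg") = arg);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
arma::cube maxpool_backward(const arma::ucube& arg, const arma::cube& dy,
                            int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dxc = dx.slice(c);
    const mat& dyc = dy.slice(c);
    const umat& ac = arg.slice(c);
    for (uword j = 0; j < dyc.n_cols; ++j)
      for (uword i = 0; i < dyc.n_rows; ++i)
        dxc[ac(i, j)] += dyc(i, j);
  }
  return dx;
}

// Transposed convolution, kernel 2, stride 2: W is (4*Cout) x Cin, row
// index (dr + 2*dc + 4*co).
// [[Rcpp::export(name = ".tconv2_forward")]]
arma::cube tconv2_forward(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, bool relu) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_rows / 4;
  mat xm(Cin, H * Wd);
  for (int c = 0; c < Cin; ++c) xm.row(c) = vectorise(x.slice(c)).t();
  mat ym = W * xm;                        // (4*Cout) x (H*W)
  cube out(2 * H, 2 * Wd, Cout);
  for (int co = 0; co < Cout; ++co) {
    mat& oc = out.slice(co);
    for (int dc = 0; dc < 2; ++dc)
      for (int dr = 0; dr < 2; ++dr) {
        const rowvec& r = ym.row(4 * co + dc * 2 + dr);
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            oc(2 * i + dr, 2 * j + dc) = r[(std::size_t)j * H + i] + b[co];
      }
  }
  if (relu) out = clamp(out, 0.0, datum::inf);
  return out;
}

// [[Rcpp::export(name = ".tconv2_backward")]]
Rcpp::List tconv2_backward(const arma::cube& x, const arma::mat& W,
                           const arma::cube& y, const arma::cube& dy,
                           bool relu) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_rows / 4;
  mat dym(4 * Cout, H * Wd);
  vec db(Cout, fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    mat g = dy.slice(co);
    if (relu) g %= conv_to<mat>::from(y.slice(co) > 0);
    db[co] = accu(g);
    for (int dc = 0; dc < 2; ++dc)
      for (int dr = 0; dr < 2; ++dr) {
        rowvec r(H * Wd);
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            r[(std::size_t)j * H + i] = g(2 * i + dr, 2 * j + dc);
        dym.row(4 * co + dc * 2 + dr) = r;
      }
  }
  mat xm(Cin, H * Wd);
  for (int c = 0; c < Cin; ++c) xm.row(c) = vectorise(x.slice(c)).t();
  mat dW = dym * xm.t();                  // (4*Cout) x Cin
  mat dxm = W.t() * dym;                  // Cin x (H*W)
  cube dx(H, Wd, Cin);
  for (int c = 0; c < Cin; ++c)
    dx.slice(c) = reshape(dxm.row(c), H, Wd);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
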