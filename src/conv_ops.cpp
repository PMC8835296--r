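// Low-level compute kernels for the 2D U-Net: same-padding convolution
// (im2col + gemm), 2x2 max pooling, and x2 bilinear upsampling, each with
// its backward pass. Layout: activations are H x W x C cubes; a convolution
// weight arrives as a Cout x (k*k*Cin) matrix whose columns are ordered
// (di fastest, then dj, then cin) to match as.vector() on an R array of
// dim c(k, k, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// patches-as-rows layout: colsT is (H*W) x (k*k*Cin); column r of colsT is
// the shifted image plane for tap (di, dj) of channel c, contiguous in
// memory, so shifts are plain submatrix copies on an aliased H x W view
static arma::mat im2colT(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  arma::mat colsT(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        const int oi = di - p, oj = dj - p; // source offset
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        arma::mat view(colsT.colptr(r), H, W, false, true);
        view.zeros();
        if (i0 >= i1 || j0 >= j1) continue;
        view.submat(i0, j0, i1 - 1, j1 - 1) =
          x.slice(c).submat(i0 + oi, j0 + oj, i1 - 1 + oi, j1 - 1 + oj);
      }
    }
  }
  return colsT;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& wmat,
                      const arma::vec& bias, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = wmat.n_rows;
  arma::mat yT = im2colT(x, k) * wmat.t(); // HW x Cout, channels contiguous
  arma::cube out(H, W, Cout);
  std::memcpy(out.memptr(), yT.memptr(), sizeof(double) * yT.n_elem);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) += bias(c);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const arma::mat& wmat,
                const arma::cube& gy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices, p = k / 2;
  const int Cout = gy.n_slices;
  // gy's memory already is (HW x Cout) column-major
  const arma::mat GT(const_cast<double*>(gy.memptr()), H * W, Cout, false,
                     true);
  arma::mat colsT = im2colT(x, k);
  arma::mat gw = GT.t() * colsT;          // Cout x k*k*Cin
  arma::vec gb = arma::sum(GT, 0).t();
  arma::mat gcolsT = GT * wmat;           // HW x k*k*Cin
  arma::cube gx(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        const int oi = di - p, oj = dj - p;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        if (i0 >= i1 || j0 >= j1) continue;
        const arma::mat plane(gcolsT.colptr(r), H, W, false, true);
        gx.slice(c).submat(i0 + oi, j0 + oj, i1 - 1 + oi, j1 - 1 + oj) +=
          plane.submat(i0, j0, i1 - 1, j1 - 1);
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C); // linear index into x of the argmax
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) {
              best = v;
              bi = (arma::uword)c * H * W + (arma::uword)jj * H + ii;
            }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::ucube& idx, const arma::cube& gy,
                        const int H, const int W) {
  const int C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (arma::uword n = 0; n < gy.n_elem; ++n)
    gx(idx(n)) += gy(n);
  return gx;
}

// half-pixel-centres bilinear interpolation grid for a x2 upsample
static void up2_grid(const int n, arma::ivec& lo, arma::ivec& hi,
                     arma::vec& w) {
  lo.set_size(2 * n); hi.set_size(2 * n); w.set_size(2 * n);
  for (int i = 0; i < 2 * n; ++i) {
    const double src = (i + 0.5) / 2.0 - 0.5;
    const double fl = std::floor(src);
    double wt = src - fl;
    int l = (int)fl, h = l + 1;
    if (l < 0) { l = 0; h = 0; wt = 0.0; }
    if (h > n - 1) { h = n - 1; if (l > n - 1) l = n - 1; if (l == h) wt = 0.0; }
    lo(i) = l; hi(i) = h; w(i) = wt;
  }
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::ivec rlo, rhi, clo, chi;
  arma::vec rw, cw;
  up2_grid(H, rlo, rhi, rw);
  up2_grid(W, clo, chi, cw);
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    for (int j = 0; j < 2 * W; ++j) {
      const int j0 = clo(j), j1 = chi(j);
      const double wj = cw(j);
      for (int i = 0; i < 2 * H; ++i) {
        const int i0 = rlo(i), i1 = rhi(i);
        const double wi = rw(i);
        y(i, j, c) = (1 - wi) * (1 - wj) * s(i0, j0) + wi * (1 - wj) * s(i1, j0)
                   + (1 - wi) * wj * s(i0, j1) + wi * wj * s(i1, j1);
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
arma::cube upsample2_bwd(const arma::cube& gy, const int H, const int W) {
  const int C = gy.n_slices;
  arma::ivec rlo, rhi, clo, chi;
  arma::vec rw, cw;
  up2_grid(H, rlo, rhi, rw);
  up2_grid(W, clo, chi, cw);
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < 2 * W; ++j) {
      const int j0 = clo(j), j1 = chi(j);
      const double wj = cw(j);
      for (int i = 0; i < 2 * H; ++i) {
        const int i0 = rlo(i), i1 = rhi(i);
        const double wi = rw(i);
        const double g = gy(i, j, c);
        gx(i0, j0, c) += (1 - wi) * (1 - wj) * g;
        gx(i1, j0, c) += wi * (1 - wj) * g;
        gx(i0, j1, c) += (1 - wi) * wj * g;
        gx(i1, j1, c) += wi * wj * g;
      }
    }
  }
  return gx;
}
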