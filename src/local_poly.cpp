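#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Weighted local polynomial regression on a fixed evaluation grid.
//
// For each grid point g the observations with |t_j - g| < h receive
// Epanechnikov weights w_j = 1 - ((t_j - g)/h)^2 and a polynomial of the
// requested degree in (t_j - g) is fitted by weighted least squares; the
// intercept estimates x(g) and the slope estimates x'(g).  Windows are
// asymmetric near the boundaries (no reflection).  When a window holds
// fewer than min_pts observations it is either widened to the nearest
// min_pts points (expand = true) or the fit aborts naming the grid point.
// [[Rcpp::export]]
List local_poly_cpp(const arma::vec& t, const arma::vec& y, double h,
                    int degree, const arma::vec& grid, bool expand,
                    int min_pts) {
  const int m = grid.n_elem, n = t.n_elem, q = degree + 1;
  if (min_pts > n)
    stop("singular smoothing setup: %d observations cannot provide windows "
         "of %d points", n, min_pts);
  arma::vec val(m), der(m), used_h(m);
  for (int k = 0; k < m; ++k) {
    const double g = grid(k);
    double hk = h;
    // sorted times: locate the window by binary search
    arma::uvec lo_hi(2);
    int lo = std::lower_bound(t.begin(), t.end(), g - hk) - t.begin();
    int hi = std::upper_bound(t.begin(), t.end(), g + hk) - t.begin();
    if (hi - lo < min_pts) {
      if (!expand)
        stop("singular smoothing window at grid point t = %f: only %d "
             "observation(s) within bandwidth %f (need %d)",
             g, hi - lo, h, min_pts);
      // widen so the nearest min_pts observations sit strictly inside the
      // kernel support (outermost at |u| = 0.9, i.e. weight 0.19)
      arma::vec dist = arma::abs(t - g);
      arma::vec sorted = arma::sort(dist);
      hk = sorted(min_pts - 1) / 0.9 + 1e-300;
      if (hk < h) hk = h;
      lo = std::lower_bound(t.begin(), t.end(), g - hk) - t.begin();
      hi = std::upper_bound(t.begin(), t.end(), g + hk) - t.begin();
    }
    const int nw = hi - lo;
    // regressors in u = (t - g)/hk for conditioning; slope rescaled after
    arma::mat X(nw, q);
    arma::vec w(nw), yy(nw);
    for (int j = 0; j < nw; ++j) {
      const double u = (t(lo + j) - g) / hk;
      double pw = 1.0;
      for (int c = 0; c < q; ++c) { X(j, c) = pw; pw *= u; }
      w(j) = 1.0 - u * u;            // Epanechnikov (up to a constant)
      if (w(j) < 1e-12) w(j) = 1e-12;
      yy(j) = y(lo + j);
    }
    arma::mat Xw = X.each_col() % w;
    arma::mat A = X.t() * Xw;
    arma::vec b = Xw.t() * yy;
    arma::vec beta;
    bool ok = arma::solve(beta, A, b, arma::solve_opts::no_approx);
    if (!ok)
      stop("singular local design at grid point t = %f (bandwidth %f)", g, hk);
    val(k) = beta(0);
    der(k) = degree >= 1 ? beta(1) / hk : 0.0;
    used_h(k) = hk;
  }
  return List::create(_["value"] = val, _["deriv"] = der,
                      _["bandwidth_used"] = used_h);
}
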