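#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Batched per-gene weighted least squares.
//
// Y: G x n response matrix (one row per gene), X: n x k design matrix,
// W: G x n strictly positive observation weights (gene-specific, so the
// normal equations cannot share a factorization across genes).
//
// Returns per-gene coefficients, residual variance s^2 = RSS/(n-k), the
// diagonal of (X'WX)^{-1} (for t-statistics) and the full (X'WX)^{-1}
// as a k x k x G cube (for multi-column F-tests).
// [[Rcpp::export(name = ".wls_batch")]]
List wls_batch(const arma::mat& Y, const arma::mat& X, const arma::mat& W) {
  const arma::uword G = Y.n_rows, n = Y.n_cols, k = X.n_cols;
  if (W.n_rows != G || W.n_cols != n)
    stop("weight matrix dimensions do not match the responses");
  if (X.n_rows != n)
    stop("design matrix row count does not match the number of samples");
  if (n <= k)
    stop("no residual degrees of freedom: rank(X) must be < n");

  arma::mat beta(G, k), vdiag(G, k);
  arma::vec sigma2(G);
  arma::cube xtwxinv(k, k, G);

  arma::mat XtW(k, n), A(k, k), Ainv(k, k);
  arma::vec b(k), coef(k), resid(n);

  for (arma::uword g = 0; g < G; ++g) {
    const arma::rowvec w = W.row(g);
    const arma::rowvec y = Y.row(g);
    // X' W  (W diagonal): scale columns of X' by w
    XtW = X.t();
    XtW.each_row() %= w;
    A = XtW * X;          // X'WX
    b = XtW * y.t();      // X'Wy
    bool ok = arma::inv_sympd(Ainv, A);
    if (!ok) stop("singular weighted cross-product at gene %d", (int)(g + 1));
    coef = Ainv * b;
    resid = y.t() - X * coef;
    double rss = arma::dot(w.t() % resid, resid);
    beta.row(g) = coef.t();
    sigma2(g) = rss / (double)(n - k);
    vdiag.row(g) = Ainv.diag().t();
    xtwxinv.slice(g) = Ainv;
  }

  return List::create(_["beta"] = beta,
                      _["sigma2"] = sigma2,
                      _["vdiag"] = vdiag,
                      _["xtwxinv"] = xtwxinv);
}
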