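// PLS1 (NIPALS) regression core shared by the wavelength selectors and the
// PLSR model. Compiled because the model-population selectors fit on the
// order of 10^5 sub-models per run.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Fit PLS1 by NIPALS on (X, y); fill B (p x A) with the regression vector for
// 1..A components on the original (uncentred) scale and b0 with intercepts.
// Components stop early when the residual covariance vanishes; remaining
// columns repeat the last attainable solution so a caller asking for lv = k
// gets the best fit of rank <= k (ties resolve to the smaller lv upstream).
static void pls1_nipals(const mat& X, const vec& y, int maxLv, mat& B, vec& b0) {
  const int n = X.n_rows, p = X.n_cols;
  int A = std::min(maxLv, std::min(p, n - 1));
  if (A < 1) A = 1;

  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xd = X.each_row() - xm;
  vec yd = y - ym;

  mat W(p, A, fill::zeros), P(p, A, fill::zeros);
  vec q(A, fill::zeros);
  int a = 0;
  for (; a < A; ++a) {
    vec w = Xd.t() * yd;
    double nw = norm(w);
    if (nw < 1e-12) break;
    w /= nw;
    vec t = Xd * w;
    double tt = dot(t, t);
    if (tt < 1e-24) break;
    vec pv = Xd.t() * t / tt;
    double qa = dot(yd, t) / tt;
    W.col(a) = w;
    P.col(a) = pv;
    q(a) = qa;
    Xd -= t * pv.t();
    yd -= qa * t;
  }
  const int Aeff = a;

  B.set_size(p, A);
  b0.set_size(A);
  if (Aeff == 0) {
    B.zeros();
    b0.fill(ym);
    return;
  }
  for (int k = 1; k <= Aeff; ++k) {
    mat Wk = W.cols(0, k - 1), Pk = P.cols(0, k - 1);
    vec qk = q.subvec(0, k - 1);
    vec beta;
    bool ok = solve(beta, Pk.t() * Wk, qk, solve_opts::no_approx);
    vec bk;
    if (ok) {
      bk = Wk * beta;
    } else {
      bk = (k > 1) ? vec(B.col(k - 2)) : vec(p, fill::zeros);
    }
    B.col(k - 1) = bk;
    b0(k - 1) = ym - dot(conv_to<vec>::from(xm), bk);
  }
  for (int k = Aeff; k < A; ++k) {
    B.col(k) = B.col(Aeff - 1);
    b0(k) = b0(Aeff - 1);
  }
}

//' @noRd
// [[Rcpp::export(name = ".cppPlsFit")]]
Rcpp::List cppPlsFit(const arma::mat& X, const arma::vec& y, int maxLv) {
  mat B;
  vec b0;
  pls1_nipals(X, y, maxLv, B, b0);
  return Rcpp::List::create(Rcpp::Named("coefs") = B,
                            Rcpp::Named("intercepts") = b0);
}

// Cross-validated RMSE per latent-variable count. folds holds 1-based test
// index vectors; the per-fold component cap is min over folds, so every lv in
// the returned vector was fitted in every fold.
//' @noRd
// [[Rcpp::export(name = ".cppPlsCvRmse")]]
arma::vec cppPlsCvRmse(const arma::mat& X, const arma::vec& y,
                       const Rcpp::List& folds, int maxLv) {
  const int n = X.n_rows, p = X.n_cols, K = folds.size();
  int A = std::min(maxLv, p);
  for (int k = 0; k < K; ++k) {
    Rcpp::IntegerVector f = folds[k];
    A = std::min(A, n - (int)f.size() - 1);
  }
  if (A < 1) A = 1;

  vec sse(A, fill::zeros);
  int nPred = 0;
  for (int k = 0; k < K; ++k) {
    Rcpp::IntegerVector f = folds[k];
    uvec te(f.size());
    for (int i = 0; i < f.size(); ++i) te(i) = f[i] - 1;
    uvec all = regspace<uvec>(0, n - 1);
    std::vector<char> isTest(n, 0);
    for (unsigned i = 0; i < te.n_elem; ++i) isTest[te(i)] = 1;
    uvec tr(n - te.n_elem);
    int j = 0;
    for (int i = 0; i < n; ++i) if (!isTest[i]) tr(j++) = i;

    mat B;
    vec b0;
    pls1_nipals(X.rows(tr), y.elem(tr), A, B, b0);
    mat pred = X.rows(te) * B;             // n_te x A
    pred.each_row() += b0.t();
    for (int a2 = 0; a2 < A; ++a2) {
      vec r = pred.col(a2) - y.elem(te);
      sse(a2) += dot(r, r);
    }
    nPred += te.n_elem;
  }
  return sqrt(sse / nPred);
}
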