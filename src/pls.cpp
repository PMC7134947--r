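// NIPALS PLS1 core: single fit, leave-one-out PRESS for latent-variable
// selection, and the resampling validation loop. X and y arrive uncentered;
// every fit centers on its own training rows (no information leak).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// NIPALS PLS1 on centered data. Fills W, P (p x A), q, tt (A). Returns the
// number of components actually extracted (may stop early on rank
// exhaustion).
static int nipals_core(mat X, vec y, int ncomp, mat& W, mat& P, vec& q,
                       vec& tt) {
  const double tol = 1e-12;
  int a = 0;
  for (; a < ncomp; ++a) {
    vec w = X.t() * y;
    double nw = norm(w);
    if (nw < tol) break;
    w /= nw;
    vec t = X * w;
    double t2 = dot(t, t);
    if (t2 < tol) break;
    vec p = X.t() * t / t2;
    double qa = dot(t, y) / t2;
    X -= t * p.t();
    y -= qa * t;
    W.col(a) = w;
    P.col(a) = p;
    q(a) = qa;
    tt(a) = t2;
  }
  return a;
}

// [[Rcpp::export(name = ".pls1_fit_cpp")]]
Rcpp::List pls1_fit_cpp(const arma::mat& X, const arma::vec& y, int ncomp) {
  const int n = X.n_rows, p = X.n_cols;
  ncomp = std::min(ncomp, std::min(n - 1, p));
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;
  mat W(p, ncomp, fill::zeros), P(p, ncomp, fill::zeros);
  vec q(ncomp, fill::zeros), tt(ncomp, fill::zeros);
  int a = nipals_core(Xc, yc, ncomp, W, P, q, tt);
  return Rcpp::List::create(
      Rcpp::Named("W") = W.cols(0, std::max(a - 1, 0)),
      Rcpp::Named("P") = P.cols(0, std::max(a - 1, 0)),
      Rcpp::Named("q") = q.subvec(0, std::max(a - 1, 0)),
      Rcpp::Named("tt") = tt.subvec(0, std::max(a - 1, 0)),
      Rcpp::Named("ncomp") = a,
      Rcpp::Named("x_mean") = xm,
      Rcpp::Named("y_mean") = ym);
}

// Predict one centered sample through the NIPALS recursion at every rank
// 1..a. preds must have length >= a.
static void predict_path(const mat& W, const mat& P, const vec& q, int a,
                         rowvec x0, double y0, double* preds) {
  double yhat = y0;
  for (int j = 0; j < a; ++j) {
    double t0 = dot(x0, W.col(j));
    yhat += q(j) * t0;
    x0 -= t0 * P.col(j).t();
    preds[j] = yhat;
  }
}

// Leave-one-out PRESS per candidate LV (1..max_lv). Each fold re-centers
// and refits. Ranks beyond a fold's extraction limit reuse that fold's
// deepest available prediction.
// [[Rcpp::export(name = ".pls1_press_cpp")]]
arma::vec pls1_press_cpp(const arma::mat& X, const arma::vec& y, int max_lv) {
  const int n = X.n_rows, p = X.n_cols;
  max_lv = std::min(max_lv, std::min(n - 2, p));
  vec press(max_lv, fill::zeros);
  mat W(p, max_lv), P(p, max_lv);
  vec q(max_lv), tt(max_lv);
  std::vector<double> preds(max_lv);
  for (int i = 0; i < n; ++i) {
    mat Xt(n - 1, p);
    vec yt(n - 1);
    int r = 0;
    for (int k = 0; k < n; ++k) {
      if (k == i) continue;
      Xt.row(r) = X.row(k);
      yt(r) = y(k);
      ++r;
    }
    rowvec xm = mean(Xt, 0);
    double ym = mean(yt);
    Xt.each_row() -= xm;
    yt -= ym;
    W.zeros(); P.zeros(); q.zeros(); tt.zeros();
    int a = nipals_core(Xt, yt, max_lv, W, P, q, tt);
    predict_path(W, P, q, a, X.row(i) - xm, ym, preds.data());
    for (int j = a; j < max_lv; ++j) preds[j] = (a > 0) ? preds[a - 1] : ym;
    for (int j = 0; j < max_lv; ++j) {
      double e = y(i) - preds[j];
      press(j) += e * e;
    }
  }
  return press;
}

// Resampling validation: for each column of `test_idx` (1-based test-set
// indices), fit on the complement with LOO-PRESS LV selection capped at
// max_lv, then predict the held-out rows. Accumulates per-sample prediction
// sums and hold-out counts.
// [[Rcpp::export(name = ".pls1_resample_cpp")]]
Rcpp::List pls1_resample_cpp(const arma::mat& X, const arma::vec& y,
                             const arma::imat& test_idx, int max_lv) {
  const int n = X.n_rows, p = X.n_cols;
  const int n_test = test_idx.n_rows, R = test_idx.n_cols;
  const int n_train = n - n_test;
  vec pred_sum(n, fill::zeros);
  vec cnt(n, fill::zeros);
  ivec lv_sel(R);
  int cap = std::min(max_lv, std::min(n_train - 2, p));
  mat W(p, cap), P(p, cap);
  vec q(cap), tt(cap);
  std::vector<double> preds(cap);
  std::vector<char> is_test(n);
  for (int r = 0; r < R; ++r) {
    std::fill(is_test.begin(), is_test.end(), 0);
    for (int j = 0; j < n_test; ++j) is_test[test_idx(j, r) - 1] = 1;
    mat Xt(n_train, p);
    vec yt(n_train);
    int m = 0;
    for (int k = 0; k < n; ++k) {
      if (is_test[k]) continue;
      Xt.row(m) = X.row(k);
      yt(m) = y(k);
      ++m;
    }
    // LV selection by LOO PRESS on the training part (first minimum wins)
    vec press = pls1_press_cpp(Xt, yt, cap);
    int best = 0;
    for (int j = 1; j < (int)press.n_elem; ++j) {
      if (press(j) < press(best)) best = j;
    }
    int nlv = best + 1;
    lv_sel(r) = nlv;
    // fit at nlv on the training part, predict hold-outs
    rowvec xm = mean(Xt, 0);
    double ym = mean(yt);
    Xt.each_row() -= xm;
    yt -= ym;
    W.zeros(); P.zeros(); q.zeros(); tt.zeros();
    int a = nipals_core(Xt, yt, nlv, W, P, q, tt);
    for (int j = 0; j < n_test; ++j) {
      int k = test_idx(j, r) - 1;
      predict_path(W, P, q, a, X.row(k) - xm, ym, preds.data());
      double yhat = (a > 0) ? preds[a - 1] : ym;
      pred_sum(k) += yhat;
      cnt(k) += 1.0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("pred_sum") = pred_sum,
                            Rcpp::Named("count") = cnt,
                            Rcpp::Named("lv_selected") = lv_sel);
}
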