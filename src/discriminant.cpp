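// Sliding-window ridge-logistic discriminant: IRLS fits, leave-one-out
// held-out scores, midrank ROC area, and the label-permutation null.
// These loops sit inside bootstrap x LOO x window grids (tens of millions
// of small refits), hence compiled code and a closed-form first Newton
// step for each leave-one-out refit (rank-one downdate of the full-data
// Hessian); every refit is still iterated to the gradient tolerance.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// workspace shared across refits of one window (sizes fixed)
struct Ws {
  vec eta, mu, r, w, g, step, pen;
  mat Xw, H;
  Ws(uword n, uword p1, double lambda)
      : eta(n), mu(n), r(n), w(n), g(p1), step(p1), pen(p1), Xw(n, p1),
        H(p1, p1) {
    pen.fill(lambda);
    pen(0) = 0.0;  // intercept unpenalized
  }
};

// residuals/weights at beta given eta; row `hold` masked out (-1 = none)
static inline void update_mu(const vec &y, int hold, Ws &ws) {
  const uword n = y.n_elem;
  for (uword i = 0; i < n; ++i) {
    double m = 1.0 / (1.0 + std::exp(-ws.eta(i)));
    ws.mu(i) = m;
    ws.r(i) = y(i) - m;
    double v = m * (1.0 - m);
    ws.w(i) = v < 1e-10 ? 1e-10 : v;
  }
  if (hold >= 0) {
    ws.r(hold) = 0.0;
    ws.w(hold) = 0.0;
  }
}

// Damped Newton (IRLS) on the ridge-penalized logistic likelihood with one
// optional held-out row. Assumes nothing about beta. Returns iterations
// used (negative if max_iter hit).
static int irls(const mat &Xa, const vec &y, int hold, double /*lambda*/,
                vec &beta, int max_iter, double tol, Ws &ws) {
  for (int it = 1; it <= max_iter; ++it) {
    ws.eta = Xa * beta;
    update_mu(y, hold, ws);
    ws.g = Xa.t() * ws.r - ws.pen % beta;
    if (abs(ws.g).max() < tol) return it;
    ws.Xw = Xa.each_col() % ws.w;
    ws.H = Xa.t() * ws.Xw;
    ws.H.diag() += ws.pen;
    if (!solve(ws.step, ws.H, ws.g,
               solve_opts::likely_sympd + solve_opts::no_approx))
      return -it;
    double sm = abs(ws.step).max();
    if (sm > 50.0) ws.step *= 50.0 / sm;  // quasi-separable safeguard
    beta += ws.step;
  }
  return -max_iter;
}

// [[Rcpp::export]]
Rcpp::List cpp_ridge_logistic(const arma::mat &X, const arma::vec &y,
                              double lambda, int max_iter = 100,
                              double tol = 1e-6) {
  mat Xa = join_rows(ones<vec>(X.n_rows), X);
  Ws ws(Xa.n_rows, Xa.n_cols, lambda);
  vec beta(Xa.n_cols, fill::zeros);
  int it = irls(Xa, y, -1, lambda, beta, max_iter, tol, ws);
  return Rcpp::List::create(
      Rcpp::Named("intercept") = beta(0),
      Rcpp::Named("weights") = vec(beta.subvec(1, beta.n_elem - 1)),
      Rcpp::Named("iterations") = std::abs(it),
      Rcpp::Named("converged") = it > 0);
}

// ROC area with midrank tie handling (Mann-Whitney form)
// [[Rcpp::export]]
double cpp_auc(const arma::vec &scores, const arma::vec &y) {
  const uword n = scores.n_elem;
  uvec ord = sort_index(scores);
  vec ranks(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && scores(ord(j + 1)) == scores(ord(i))) ++j;
    double mid = 0.5 * (i + j) + 1.0;  // 1-based midrank
    for (uword k = i; k <= j; ++k) ranks(ord(k)) = mid;
    i = j + 1;
  }
  double n1 = accu(y), n0 = n - n1;
  if (n1 == 0 || n0 == 0) Rcpp::stop("both classes required for Az");
  double rank_sum = dot(ranks, y);
  return (rank_sum - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

// LOO held-out scores for one window. The full-data fit is converged
// first; each leave-one-out refit then starts from the exact Newton step
// of the reduced problem, obtained in closed form by a Sherman-Morrison
// rank-one downdate of the full-data Hessian, and keeps iterating until
// the reduced problem's gradient is below tol. The held-out trial is
// projected with the refit coefficients (intercept included).
static vec loo_scores_impl(const mat &Xa, const vec &y, double lambda,
                           int max_iter, double tol, Ws &ws) {
  const uword n = Xa.n_rows, p1 = Xa.n_cols;
  vec beta_full(p1, fill::zeros);
  irls(Xa, y, -1, lambda, beta_full, max_iter, tol, ws);

  // state at the full-data solution
  ws.eta = Xa * beta_full;
  update_mu(y, -1, ws);
  vec g_full = Xa.t() * ws.r - ws.pen % beta_full;
  ws.Xw = Xa.each_col() % ws.w;
  ws.H = Xa.t() * ws.Xw;
  ws.H.diag() += ws.pen;
  mat Hinv = inv_sympd(ws.H);
  mat U = Xa * Hinv;                    // row i = (H^{-1} x_i)'
  vec q = sum(U % Xa, 1);               // q_i = x_i' H^{-1} x_i
  vec r0 = ws.r, w0 = ws.w;
  vec hg = Hinv * g_full;               // ~0 at convergence, kept exact

  vec out(n);
  vec beta(p1), g_i(p1), hx(p1);
  for (uword i = 0; i < n; ++i) {
    // exact Newton step of the held-out problem from beta_full:
    // (H - w_i x_i x_i')^{-1} (g_full - r_i x_i) via Sherman-Morrison
    double denom = 1.0 - w0(i) * q(i);
    if (denom < 1e-8) denom = 1e-8;
    hx = U.row(i).t();
    double a = dot(g_full, hx);
    beta = beta_full + hg + ((w0(i) * a - r0(i)) / denom) * hx;
    // iterate to tolerance with the downdated Hessian held fixed
    // (modified Newton; exact gradient), full IRLS as fallback
    bool ok = false;
    for (int it = 0; it < 8; ++it) {
      ws.eta = Xa * beta;
      update_mu(y, (int)i, ws);
      g_i = Xa.t() * ws.r - ws.pen % beta;
      if (abs(g_i).max() < tol) { ok = true; break; }
      beta += Hinv * g_i + (w0(i) / denom) * dot(hx, g_i) * hx;
    }
    if (!ok) irls(Xa, y, (int)i, lambda, beta, max_iter, tol, ws);
    out(i) = dot(Xa.row(i), beta);
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_loo_scores(const arma::mat &X, const arma::vec &y,
                         double lambda, int max_iter = 50,
                         double tol = 1e-3) {
  mat Xa = join_rows(ones<vec>(X.n_rows), X);
  Ws ws(Xa.n_rows, Xa.n_cols, lambda);
  return loo_scores_impl(Xa, y, lambda, max_iter, tol, ws);
}

// LOO Az for every window of a trials x channels x windows feature cube
// [[Rcpp::export]]
arma::vec cpp_az_grid(const arma::cube &F, const arma::vec &y, double lambda,
                      int max_iter = 50, double tol = 1e-3) {
  const uword W = F.n_slices;
  vec az(W);
  Ws ws(F.n_rows, F.n_cols + 1, lambda);
  for (uword w = 0; w < W; ++w) {
    mat Xa = join_rows(ones<vec>(F.n_rows), F.slice(w));
    az(w) = cpp_auc(loo_scores_impl(Xa, y, lambda, max_iter, tol, ws), y);
  }
  return az;
}

// Label-permutation null: rows of `perms` are 0-based permutations of the
// trial order; each is applied to the labels and the full LOO Az grid is
// recomputed. Returns n_perm x n_window Az matrix.
// [[Rcpp::export]]
arma::mat cpp_null_az(const arma::cube &F, const arma::vec &y,
                      const arma::umat &perms, double lambda,
                      int max_iter = 50, double tol = 1e-3) {
  const uword W = F.n_slices, B = perms.n_rows;
  std::vector<mat> Xas(W);
  for (uword w = 0; w < W; ++w)
    Xas[w] = join_rows(ones<vec>(F.n_rows), F.slice(w));
  Ws ws(F.n_rows, F.n_cols + 1, lambda);
  mat out(B, W);
  vec yp(y.n_elem);
  for (uword b = 0; b < B; ++b) {
    for (uword i = 0; i < y.n_elem; ++i) yp(i) = y(perms(b, i));
    for (uword w = 0; w < W; ++w)
      out(b, w) = cpp_auc(loo_scores_impl(Xas[w], yp, lambda, max_iter, tol, ws), yp);
    if (b % 50 == 49) Rcpp::checkUserInterrupt();
  }
  return out;
}
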