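// Alternating simplex-constrained least squares for archetypal analysis.
//
// The sum-to-one constraint is enforced with the classical penalty device:
// each simplex-constrained row solve min ||A b - y||^2 s.t. b >= 0, sum(b) = 1
// is approximated by non-negative least squares on the augmented system
// [A; M 1'] b ~ [y; M] with a large weight M, i.e. on the normal equations
// (A'A + M^2 J) b = A'y + M^2 1.  Rows are renormalized to the simplex after
// each solve to remove the O(1/M^2) penalty slack.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fast NNLS (Bro & de Jong 1997) on pre-computed normal equations.
// Solves min ||A x - y||^2, x >= 0 given AtA, Aty.
static vec fnnls(const mat& AtA, const vec& Aty) {
  const uword q = AtA.n_cols;
  vec x(q, fill::zeros);
  std::vector<bool> passive(q, false);
  vec w = Aty;  // gradient at x = 0
  const double tolw = 1e-10 * std::max(1.0, abs(Aty).max());
  const uword max_outer = 30 * q + 30;

  for (uword outer = 0; outer < max_outer; ++outer) {
    // pick most violating coordinate in the active (zero) set
    int jstar = -1;
    double wmax = tolw;
    for (uword j = 0; j < q; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jstar = (int)j; }
    }
    if (jstar < 0) break;  // KKT satisfied
    passive[(uword)jstar] = true;

    for (uword inner = 0; inner < max_outer; ++inner) {
      std::vector<uword> pidx;
      for (uword j = 0; j < q; ++j) if (passive[j]) pidx.push_back(j);
      uvec P = conv_to<uvec>::from(pidx);
      vec s(q, fill::zeros);
      vec sP;
      bool ok = solve(sP, AtA.submat(P, P), Aty.elem(P),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) sP = pinv(AtA.submat(P, P)) * Aty.elem(P);
      s.elem(P) = sP;

      if (sP.min() > 0) { x = s; break; }

      // step toward s until the first passive coordinate hits zero
      double alpha = datum::inf;
      for (uword idx = 0; idx < P.n_elem; ++idx) {
        uword j = P(idx);
        if (s(j) <= 0) {
          double a = x(j) / (x(j) - s(j));
          if (a < alpha) alpha = a;
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      x += alpha * (s - x);
      for (uword j = 0; j < q; ++j) {
        if (passive[j] && x(j) <= tolw) { passive[j] = false; x(j) = 0.0; }
      }
    }
    w = Aty - AtA * x;
  }
  return x;
}

// Solve all alpha rows (simplex weights of samples on archetypes).
static mat alpha_step(const mat& X, const mat& Z, double M) {
  const uword n = X.n_rows, k = Z.n_rows;
  const double M2 = M * M;
  mat G = Z * Z.t();
  G += M2 * ones<mat>(k, k);
  mat B = Z * X.t();        // k x n
  B += M2;
  mat alpha(n, k);
  for (uword i = 0; i < n; ++i) {
    vec a = fnnls(G, B.col(i));
    double s = accu(a);
    if (s > 0) a /= s; else a.fill(1.0 / k);
    alpha.row(i) = a.t();
  }
  return alpha;
}

// [[Rcpp::export]]
arma::mat aa_alpha_cpp(const arma::mat& X, const arma::mat& Z, double M) {
  return alpha_step(X, Z, M);
}

// [[Rcpp::export]]
Rcpp::List aa_fit_cpp(const arma::mat& X, const arma::uvec& init_idx,
                      int max_iter, double tol, double M) {
  const uword n = X.n_rows, k = init_idx.n_elem;
  const double M2 = M * M;

  mat Gb = X * X.t();
  Gb += M2 * ones<mat>(n, n);

  mat Z = X.rows(init_idx);
  mat beta(k, n, fill::zeros);
  for (uword j = 0; j < k; ++j) beta(j, init_idx(j)) = 1.0;

  mat alpha;
  double prev_rss = datum::inf;
  std::vector<double> history;
  bool converged = false;
  int iters = 0;

  // best (monotone) state
  mat alpha_best, beta_best = beta, Z_best = Z;
  double rss_best = datum::inf;

  for (int it = 1; it <= max_iter; ++it) {
    iters = it;
    alpha = alpha_step(X, Z, M);
    double rss = accu(square(X - alpha * Z));

    if (rss > prev_rss * (1.0 + 1e-9)) {
      // numerical wobble of the two-step update: keep the best state
      converged = true;
      break;
    }
    history.push_back(rss);
    alpha_best = alpha; beta_best = beta; Z_best = Z; rss_best = rss;

    if (std::isfinite(prev_rss) &&
        (prev_rss - rss) <= tol * std::max(prev_rss, 1e-300)) {
      converged = true;
      break;
    }
    prev_rss = rss;

    // beta step: unconstrained archetypes, then project onto convex hull of X
    mat AtA = alpha.t() * alpha;
    AtA.diag() += 1e-12 * (1.0 + trace(AtA));
    mat Ztil;
    bool ok = solve(Ztil, AtA, alpha.t() * X,
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) Ztil = pinv(AtA) * (alpha.t() * X);
    for (uword j = 0; j < k; ++j) {
      vec b = fnnls(Gb, X * Ztil.row(j).t() + M2);
      double s = accu(b);
      if (s > 0) b /= s; else b.fill(1.0 / n);
      beta.row(j) = b.t();
    }
    Z = beta * X;
  }

  if (!alpha_best.is_empty()) {
    alpha = alpha_best; beta = beta_best; Z = Z_best;
  }
  return Rcpp::List::create(
    Rcpp::Named("alpha") = alpha,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("Z") = Z,
    Rcpp::Named("rss") = rss_best,
    Rcpp::Named("history") = history,
    Rcpp::Named("n_iter") = iters,
    Rcpp::Named("converged") = converged);
}
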