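// Fuzzy c-means alternating optimization core.
// Kept in compiled code because the relevance analysis refits the partition
// thousands of times (R replicates x features x experiment repetitions).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// squared Euclidean distances, cells (rows of X) x centroids (rows of U)
static mat dist2_mat(const mat& X, const mat& U) {
  mat D2 = -2.0 * X * U.t();
  D2.each_col() += sum(square(X), 1);
  D2.each_row() += sum(square(U), 1).t();
  D2.elem(find(D2 < 0.0)).zeros(); // numerical guard
  return D2;
}

// memberships from squared distances; a cell coincident with one or more
// centroids (distance < 1e-12) splits its membership equally among them
static mat memberships_from_dist2(const mat& D2, double mu) {
  const double ex = -1.0 / (mu - 1.0); // applied to d^2: (d^2)^(-1/(mu-1)) = d^(-2/(mu-1))
  const double coincide2 = 1e-24;      // (1e-12)^2
  // scale each row by its minimum so that ratios are >= 1 and powers <= 1;
  // keeps the computation stable for mu close to 1 (large exponents)
  vec dmin = min(D2, 1);
  vec dsafe = dmin;
  dsafe.elem(find(dsafe <= 0.0)).ones();
  mat M = pow(D2.each_col() / dsafe, ex);
  M.each_col() /= sum(M, 1);
  // cells coincident with >= 1 centroid split membership equally among them
  uvec deg = find(dmin < coincide2);
  for (uword k = 0; k < deg.n_elem; ++k) {
    uword i = deg(k);
    uvec hit = find(D2.row(i) < coincide2);
    M.row(i).zeros();
    for (uword h = 0; h < hit.n_elem; ++h) M(i, hit(h)) = 1.0 / hit.n_elem;
  }
  return M;
}

// [[Rcpp::export(name = ".fcm_core")]]
Rcpp::List fcm_core(const arma::mat& X, const arma::mat& U0, double mu,
                    double tol, int max_iter) {
  mat U = U0;
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  bool converged = false;
  int iter = 0;
  mat M;
  for (iter = 1; iter <= max_iter; ++iter) {
    mat D2 = dist2_mat(X, U);
    M = memberships_from_dist2(D2, mu);
    mat W = pow(M, mu);
    trace.push_back(accu(W % D2)); // J of the (M_t, U_t) pair
    rowvec cs = sum(W, 0);
    if (cs.min() <= 0.0)
      Rcpp::stop("empty cluster: a membership column has zero total weight");
    mat Unew = W.t() * X;
    Unew.each_col() /= cs.t();
    double disp = abs(Unew - U).max();
    U = Unew;
    if (disp < tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;
  // final membership/centroid pair and its cost
  mat D2 = dist2_mat(X, U);
  M = memberships_from_dist2(D2, mu);
  double J = accu(pow(M, mu) % D2);
  trace.push_back(J);
  return Rcpp::List::create(
    Rcpp::Named("centroids") = U,
    Rcpp::Named("memberships") = M,
    Rcpp::Named("cost") = J,
    Rcpp::Named("cost_trace") = trace,
    Rcpp::Named("n_iterations") = iter,
    Rcpp::Named("converged") = converged);
}

// [[Rcpp::export(name = ".fcm_memberships_cpp")]]
arma::mat fcm_memberships_cpp(const arma::mat& X, const arma::mat& U, double mu) {
  return memberships_from_dist2(dist2_mat(X, U), mu);
}
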