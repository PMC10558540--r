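#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Proper (det = +1) rotation R minimizing ||X R - ref||_F for centered k x 3
// matrices, via SVD of the cross-covariance with the reflection sign fix.
static mat proper_rotation(const mat& X, const mat& ref) {
  mat M = X.t() * ref;  // 3 x 3
  mat U, V;
  vec d;
  if (!svd(U, d, V, M)) Rcpp::stop("SVD failure in rotation step");
  mat R = U * V.t();
  if (det(R) < 0) {
    U.col(2) *= -1.0;  // flip axis of the smallest singular value
    R = U * V.t();
  }
  return R;
}

static void center_inplace(mat& X) {
  rowvec c = mean(X, 0);
  X.each_row() -= c;
}

static double csize_of(const mat& Xc) {  // Xc already centered
  return std::sqrt(accu(square(Xc)));
}

static void check_nondegenerate(const mat& Xc, int idx) {
  if (csize_of(Xc) < 1e-12)
    Rcpp::stop("degenerate configuration (all points coincide) at specimen %d", idx + 1);
  if (arma::rank(Xc) < 2)
    Rcpp::stop("degenerate (collinear) configuration at specimen %d", idx + 1);
}

// Generalized Procrustes analysis on a k x 3 x n cube.
// [[Rcpp::export]]
Rcpp::List cpp_gpa(const arma::cube& X, bool scale, double tol, int max_iter) {
  const int n = X.n_slices;
  cube A = X;
  vec csize(n);
  for (int i = 0; i < n; ++i) {
    mat Xi = A.slice(i);
    center_inplace(Xi);
    check_nondegenerate(Xi, i);
    csize(i) = csize_of(Xi);
    if (scale) Xi /= csize(i);
    A.slice(i) = Xi;
  }
  mat consensus = mean(A, 2);
  center_inplace(consensus);
  if (scale) consensus /= csize_of(consensus);

  double change = datum::inf;
  int it = 0;
  while (it < max_iter) {
    ++it;
    for (int i = 0; i < n; ++i)
      A.slice(i) = A.slice(i) * proper_rotation(A.slice(i), consensus);
    mat newcons = mean(A, 2);
    center_inplace(newcons);
    if (scale) newcons /= csize_of(newcons);
    change = std::sqrt(accu(square(newcons - consensus)) / newcons.n_elem);
    consensus = newcons;
    if (change < tol) break;
  }
  // final rotation pass so the stored consensus is exactly the mean of aligned
  for (int i = 0; i < n; ++i)
    A.slice(i) = A.slice(i) * proper_rotation(A.slice(i), consensus);
  consensus = mean(A, 2);

  return Rcpp::List::create(
      Rcpp::Named("aligned") = A, Rcpp::Named("csize") = csize,
      Rcpp::Named("consensus") = consensus, Rcpp::Named("iterations") = it,
      Rcpp::Named("final_change") = change, Rcpp::Named("converged") = (change < tol));
}

// Ordinary Procrustes superimposition of X onto a fixed reference.
// [[Rcpp::export]]
Rcpp::List cpp_opa(const arma::mat& X, const arma::mat& ref, bool scale) {
  mat Xc = X, Rc = ref;
  rowvec ref_centroid = mean(Rc, 0);
  center_inplace(Xc);
  center_inplace(Rc);
  check_nondegenerate(Xc, 0);
  mat M = Xc.t() * Rc;
  mat U, V;
  vec d;
  if (!svd(U, d, V, M)) Rcpp::stop("SVD failure in OPA");
  mat R = U * V.t();
  double trace_d;
  if (det(R) < 0) {
    U.col(2) *= -1.0;
    R = U * V.t();
    trace_d = d(0) + d(1) - d(2);
  } else {
    trace_d = accu(d);
  }
  double s = scale ? trace_d / accu(square(Xc)) : 1.0;
  mat aligned = s * Xc * R;
  aligned.each_row() += ref_centroid;
  double residual = std::sqrt(accu(square(aligned - ref)));
  return Rcpp::List::create(Rcpp::Named("aligned") = aligned,
                            Rcpp::Named("rotation") = R, Rcpp::Named("scale") = s,
                            Rcpp::Named("residual") = residual);
}

// Center each slice, optionally rescale to unit centroid size, and rotate
// onto a centered reference. Used to project held-out specimens into a
// training consensus frame; returns the aligned cube plus original centroid
// sizes.
// [[Rcpp::export]]
Rcpp::List cpp_project_to_consensus(const arma::cube& X, const arma::mat& ref, bool unit_scale) {
  const int n = X.n_slices;
  cube A = X;
  vec csize(n);
  for (int i = 0; i < n; ++i) {
    mat Xi = A.slice(i);
    center_inplace(Xi);
    check_nondegenerate(Xi, i);
    csize(i) = csize_of(Xi);
    if (unit_scale) Xi /= csize(i);
    A.slice(i) = Xi * proper_rotation(unit_scale ? Xi : Xi, ref);
  }
  return Rcpp::List::create(Rcpp::Named("aligned") = A, Rcpp::Named("csize") = csize);
}

// Centroid sizes of a subset of points (0-based indices) for every specimen.
// [[Rcpp::export]]
arma::vec cpp_subset_csize(const arma::cube& X, const arma::uvec& idx0) {
  const int n = X.n_slices;
  vec out(n);
  for (int i = 0; i < n; ++i) {
    mat Xi = X.slice(i);
    mat S = Xi.rows(idx0);
    center_inplace(S);
    out(i) = csize_of(S);
  }
  return out;
}
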