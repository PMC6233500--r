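#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Batch orthogonal matching pursuit.
//
// D: patch_dim x n_atoms dictionary with unit-norm columns.
// X: patch_dim x n_signals matrix of signals to code.
// sparsity: maximum number of atoms per signal.
// res_tol: stop when the residual 2-norm drops below this.
//
// Greedy rule: at each step pick the atom with the largest |<atom, residual>|
// (ties resolved to the lowest atom index), then refit all selected
// coefficients by least squares on the original signal. Returns the dense
// n_atoms x n_signals coefficient matrix (zeros off the support).
// [[Rcpp::export]]
arma::mat omp_encode_cpp(const arma::mat& D, const arma::mat& X,
                         const int sparsity, const double res_tol) {
  const uword n_atoms = D.n_cols;
  const uword n_sig = X.n_cols;
  mat W(n_atoms, n_sig, fill::zeros);

  for (uword n = 0; n < n_sig; ++n) {
    const vec x = X.col(n);
    vec r = x;
    uvec support(sparsity);
    vec w;
    int s = 0;
    while (s < sparsity && norm(r) > res_tol) {
      vec c = abs(D.t() * r);
      for (int j = 0; j < s; ++j) c(support(j)) = -1.0;  // never reselect
      const uword jstar = c.index_max();  // first occurrence on exact ties
      support(s++) = jstar;
      const mat Ds = D.cols(support.head(s));
      // SVD-based least squares: stable (and silent) even when near-duplicate
      // atoms make the selected set ill-conditioned
      w = solve(Ds, x, solve_opts::force_approx);
      r = x - Ds * w;
    }
    for (int j = 0; j < s; ++j) W(support(j), n) = w(j);
  }
  return W;
}
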