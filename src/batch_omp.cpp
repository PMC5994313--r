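// Sparse coding and dictionary learning kernels.
//
// batch_omp_engine: batch orthogonal matching pursuit with the
// precomputed-Gram formulation (progressive Cholesky).  Per column: greedy
// selection of the atom with the largest absolute correlation with the
// current residual, least-squares refit over the selected set, stop when the
// residual 2-norm drops to the relative tolerance (with an absolute floor)
// or the sparsity cap is reached.
//
// ksvd_engine: K-SVD sweeps alternating Batch-OMP coding with atom-by-atom
// rank-1 (dominant singular pair) updates of the restricted representation
// error, plus dead-atom replacement and a per-column monotonicity safeguard.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat omp_code(const mat& D, const mat& G, const mat& X,
                    const double residual_tol, const int max_atoms,
                    const double abs_floor) {
  const uword K = D.n_cols;
  const uword P = X.n_cols;
  const int M = max_atoms;

  mat codes(K, P, fill::zeros);
  const mat A0 = D.t() * X;              // all initial correlations, one GEMM

  // preallocated per-column workspaces (manual triangular solves keep the
  // hot loop free of allocations)
  std::vector<double> Lb(static_cast<size_t>(M) * M, 0.0);
  std::vector<double> w(M), gamma(M), a0(M), tmp(M);
  std::vector<uword> sel(M);
  std::vector<char> used(K);
  mat Gsub(K, M, fill::zeros);
  vec alpha(K);

  for (uword p = 0; p < P; ++p) {
    const double nx2 = dot(X.col(p), X.col(p));
    const double tgt = std::max(residual_tol * std::sqrt(nx2), abs_floor);
    const double target = tgt * tgt;
    if (nx2 <= target) continue;

    const double* alpha0 = A0.colptr(p);
    alpha = A0.col(p);
    std::fill(used.begin(), used.end(), 0);
    int m = 0;
    Lb[0] = 1.0;

    while (m < M) {
      uword k = K;
      double best = -1.0;
      const double* ap = alpha.memptr();
      for (uword i = 0; i < K; ++i) {
        if (used[i]) continue;
        const double a = std::fabs(ap[i]);
        if (a > best) { best = a; k = i; }
      }
      if (k == K || best <= 1e-14) break;

      if (m > 0) {
        // forward solve L w = Gsub(k, 0:m-1)
        double w2 = 0.0;
        for (int i = 0; i < m; ++i) {
          double s = Gsub(k, i);
          const double* Li = &Lb[static_cast<size_t>(i) * M];
          for (int j = 0; j < i; ++j) s -= Li[j] * w[j];
          w[i] = s / Li[i];
          w2 += w[i] * w[i];
        }
        const double d2 = 1.0 - w2;
        if (d2 <= 1e-14) break;  // atom (near-)dependent on selection
        double* Lm = &Lb[static_cast<size_t>(m) * M];
        for (int i = 0; i < m; ++i) Lm[i] = w[i];
        Lm[m] = std::sqrt(d2);
      }
      sel[m] = k;
      Gsub.col(m) = G.col(k);
      a0[m] = alpha0[k];
      used[k] = 1;
      ++m;

      // gamma from L L^T gamma = a0 (forward then backward substitution)
      for (int i = 0; i < m; ++i) {
        double s = a0[i];
        const double* Li = &Lb[static_cast<size_t>(i) * M];
        for (int j = 0; j < i; ++j) s -= Li[j] * tmp[j];
        tmp[i] = s / Li[i];
      }
      double eps = nx2;
      for (int i = m - 1; i >= 0; --i) {
        double s = tmp[i];
        for (int j = i + 1; j < m; ++j) s -= Lb[static_cast<size_t>(j) * M + i] * gamma[j];
        gamma[i] = s / Lb[static_cast<size_t>(i) * M + i];
      }
      for (int i = 0; i < m; ++i) eps -= gamma[i] * a0[i];
      if (eps <= target || m == M) break;

      // alpha = alpha0 - Gsub[, 0:m-1] %*% gamma
      alpha = A0.col(p);
      alpha -= Gsub.head_cols(m) * vec(&gamma[0], m, false, true);
    }

    for (int i = 0; i < m; ++i) codes(sel[i], p) = gamma[i];
  }
  return codes;
}

// [[Rcpp::export]]
arma::mat batch_omp_engine(const arma::mat& D, const arma::mat& X,
                           const double residual_tol, const int max_atoms,
                           const double abs_floor) {
  const mat G = D.t() * D;
  return omp_code(D, G, X, residual_tol, max_atoms, abs_floor);
}

// [[Rcpp::export]]
Rcpp::List ksvd_engine(const arma::mat& X, const arma::mat& D_init,
                       const int iterations, const double residual_tol,
                       const int max_atoms, const double abs_floor) {
  mat D = D_init;
  const uword K = D.n_cols;
  const uword P = X.n_cols;
  mat codes(K, P, fill::zeros);
  mat R;
  mat R_prev;
  rowvec res_prev;
  vec errors(iterations, fill::zeros);

  for (int it = 0; it < iterations; ++it) {
    const mat G = D.t() * D;
    mat new_codes = omp_code(D, G, X, residual_tol, max_atoms, abs_floor);
    R = X - D * new_codes;
    if (it > 0) {
      // monotonicity safeguard: never let re-coding worsen a column
      const rowvec res_new = sum(square(R), 0);
      for (uword p = 0; p < P; ++p) {
        if (res_prev(p) < res_new(p)) {
          new_codes.col(p) = codes.col(p);
          R.col(p) = R_prev.col(p);
        }
      }
    }
    codes = new_codes;
    errors(it) = std::sqrt(accu(square(R)));

    uvec worst_order;          // residual ranking for dead-atom replacement
    uword n_replaced = 0;
    for (uword j = 0; j < K; ++j) {
      const uvec idx = find(codes.row(j) != 0.0);
      if (idx.n_elem == 0) {
        // replace the dead atom with the next worst-represented sample
        if (worst_order.is_empty()) {
          worst_order = sort_index(sum(square(R), 0).t(), "descend");
        }
        while (n_replaced < P) {
          const uword worst = worst_order(n_replaced++);
          const double nc = norm(X.col(worst));
          if (nc > 1e-12) { D.col(j) = X.col(worst) / nc; break; }
        }
        continue;
      }
      mat E = R.cols(idx);
      const rowvec cj = codes.row(j);
      for (uword t = 0; t < idx.n_elem; ++t) E.col(t) += D.col(j) * cj(idx(t));
      // dominant singular pair via the small d x d cross-product (exact)
      vec eigval;
      mat eigvec;
      eig_sym(eigval, eigvec, E * E.t());
      vec d_new = eigvec.col(eigvec.n_cols - 1);
      const uword imax = index_max(abs(d_new));
      if (d_new(imax) < 0) d_new = -d_new;   // deterministic sign
      const vec c_new = E.t() * d_new;
      for (uword t = 0; t < idx.n_elem; ++t) {
        R.col(idx(t)) = E.col(t) - d_new * c_new(t);
        codes(j, idx(t)) = c_new(t);
      }
      D.col(j) = d_new;
    }
    res_prev = sum(square(R), 0);
    R_prev = R;
  }

  return Rcpp::List::create(Rcpp::Named("dictionary") = D,
                            Rcpp::Named("errors") = errors);
}
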