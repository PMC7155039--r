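#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// FCLS unmixing specialised for a small endmember count: the augmented
// design A is shared by every pixel, so the restricted least-squares
// solver for each passive subset of endmembers is precomputed once
// (2^k - 1 subsets) and Lawson-Hanson NNLS per pixel reduces to small
// matrix-vector products.

// [[Rcpp::export(name = ".fcls_cpp")]]
Rcpp::List fcls_cpp(const arma::mat& spectra, const arma::mat& M,
                    const double delta) {
  const uword n = spectra.n_rows, k = M.n_cols, nb = M.n_rows;
  if (k > 12) Rcpp::stop("endmember count too large");
  mat A(nb + 1, k);
  A.rows(0, nb - 1) = M;
  A.row(nb).fill(delta);

  const uword nsub = (1u << k);
  std::vector<mat> solver(nsub);      // pinv of A restricted to subset
  std::vector<uvec> members(nsub);
  for (uword s = 1; s < nsub; ++s) {
    std::vector<uword> mem;
    for (uword j = 0; j < k; ++j) if (s & (1u << j)) mem.push_back(j);
    members[s] = uvec(mem);
    solver[s] = pinv(A.cols(members[s]));
  }

  mat F(n, k);
  vec rmse(n);
  vec b(nb + 1), x(k), w(k), z;
  const double tol = 1e-12;
  const int maxit = 200;
  for (uword i = 0; i < n; ++i) {
    b.subvec(0, nb - 1) = spectra.row(i).t();
    b(nb) = delta;
    x.zeros();
    uword S = 0;  // passive-set bitmask
    vec resid = b;
    w = A.t() * resid;
    for (int outer = 0; outer < maxit; ++outer) {
      int jbest = -1;
      double wbest = tol;
      for (uword j = 0; j < k; ++j)
        if (!(S & (1u << j)) && w(j) > wbest) { wbest = w(j); jbest = (int)j; }
      if (jbest < 0) break;
      S |= (1u << jbest);
      for (int inner = 0; inner < maxit; ++inner) {
        const uvec& P = members[S];
        z = solver[S] * b;
        if (z.min() > tol) {
          x.zeros();
          for (uword q = 0; q < P.n_elem; ++q) x(P(q)) = z(q);
          break;
        }
        double alpha = datum::inf;
        for (uword q = 0; q < P.n_elem; ++q)
          if (z(q) <= tol) {
            double a = x(P(q)) / (x(P(q)) - z(q));
            if (a < alpha) alpha = a;
          }
        for (uword q = 0; q < P.n_elem; ++q)
          x(P(q)) += alpha * (z(q) - x(P(q)));
        for (uword q = 0; q < P.n_elem; ++q)
          if (x(P(q)) <= tol) { x(P(q)) = 0.0; S &= ~(1u << P(q)); }
      }
      resid = b - A * x;
      w = A.t() * resid;
    }
    double s = accu(x);
    vec f = (s > 0) ? vec(x / s) : x;  // delta defect is tiny; snap to simplex
    F.row(i) = f.t();
    vec r = spectra.row(i).t() - M * f;
    rmse(i) = std::sqrt(accu(square(r)) / nb);
  }
  return Rcpp::List::create(Rcpp::Named("fractions") = F,
                            Rcpp::Named("rmse") = rmse);
}
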