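// Lawson-Hanson active-set non-negative least squares, solved independently
// for every sample row of a catalog against a shared signature basis.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve min ||C x - d||_2 s.t. x >= 0 for one right-hand side.
static vec nnls_single(const mat& C, const vec& d) {
    const uword n = C.n_cols;
    vec x(n, fill::zeros);
    std::vector<bool> inP(n, false);
    vec w = C.t() * (d - C * x);
    const double tol = 10.0 * datum::eps * norm(C, 1) * static_cast<double>(C.n_rows);
    const uword maxOuter = 3 * n + 30;

    for (uword outer = 0; outer < maxOuter; ++outer) {
        // most violating coordinate among the zero set
        sword t = -1;
        double wmax = tol;
        for (uword j = 0; j < n; ++j) {
            if (!inP[j] && w(j) > wmax) { wmax = w(j); t = (sword)j; }
        }
        if (t < 0) break;
        inP[(uword)t] = true;

        for (;;) {
            uvec P(n);
            uword np = 0;
            for (uword j = 0; j < n; ++j) if (inP[j]) P(np++) = j;
            P.resize(np);

            vec z;
            if (!solve(z, C.cols(P), d)) {
                // rank-deficient subproblem: fall back to pseudo-inverse
                z = pinv(C.cols(P)) * d;
            }
            if (z.min() > 0) {
                x.zeros();
                x(P) = z;
                break;
            }
            // step back to the feasible boundary, drop exhausted coordinates
            double alpha = datum::inf;
            for (uword i = 0; i < np; ++i) {
                if (z(i) <= 0) {
                    double a = x(P(i)) / (x(P(i)) - z(i));
                    if (a < alpha) alpha = a;
                }
            }
            for (uword i = 0; i < np; ++i)
                x(P(i)) += alpha * (z(i) - x(P(i)));
            for (uword j = 0; j < n; ++j) {
                if (inP[j] && x(j) <= tol) { inP[j] = false; x(j) = 0.0; }
            }
        }
        w = C.t() * (d - C * x);
    }
    return x;
}

// [[Rcpp::export(name = ".nnlsMulti")]]
arma::mat nnlsMulti(const arma::mat& basis, const arma::mat& rhs) {
    // basis: n_t x n_k (transposed signature matrix); rhs: n_g x n_t
    mat W(rhs.n_rows, basis.n_cols);
    for (uword i = 0; i < rhs.n_rows; ++i) {
        W.row(i) = nnls_single(basis, rhs.row(i).t()).t();
    }
    return W;
}
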