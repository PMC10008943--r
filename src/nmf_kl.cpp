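#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Brunet multiplicative updates for KL-divergence NMF.
// One iteration = H update followed by W update; the generalized
// KL divergence D(A || WH) is recorded after every iteration.

// D(A||WH) = sum_a>0 [a log a - a] + sum WH - sum A.*log(WH); the first
// term is constant in (W,H) and precomputed once.
static double kl_const(const arma::mat& A) {
  double c = 0.0;
  for (arma::uword i = 0; i < A.n_elem; ++i) {
    double a = A(i);
    if (a > 0.0) c += a * std::log(a) - a;
  }
  return c;
}

static double kl_divergence(const arma::mat& A, const arma::mat& WH,
                            double cst) {
  return cst + arma::accu(WH) - arma::accu(A % arma::log(WH + 1e-300));
}

// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& A, arma::mat W, arma::mat H,
                      int max_iter, double tol) {
  const double eps = 1e-12;
  arma::mat WH = W * H;
  const double cst = kl_const(A);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  trace.push_back(kl_divergence(A, WH, cst));
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // H_{aj} <- H_{aj} * sum_i W_ia A_ij/(WH)_ij / sum_i W_ia
    arma::mat R = A / (WH + eps);
    H %= (W.t() * R);
    arma::vec wcs = arma::sum(W, 0).t() + eps;
    H.each_col() /= wcs;

    // W_{ia} <- W_{ia} * sum_j H_aj A_ij/(WH)_ij / sum_j H_aj
    WH = W * H;
    R = A / (WH + eps);
    W %= (R * H.t());
    arma::rowvec hrs = arma::sum(H, 1).t() + eps;
    W.each_row() /= hrs;

    WH = W * H;
    double d = kl_divergence(A, WH, cst);
    trace.push_back(d);
    if (it >= 10) {
      double d_old = trace[it - 10];
      double denom = std::max(std::abs(d_old), eps);
      if (std::abs(d_old - d) / denom < tol) { converged = true; break; }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("iterations") = std::min(it, max_iter),
      Rcpp::Named("converged") = converged);
}
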