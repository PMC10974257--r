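#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Frequency-domain ADMM loop for variational mode decomposition.
//
// Operates on the positive half-spectrum of the (mirror-extended) input.
// Each mode is a Wiener-filtered residual centred on its current frequency;
// centre frequencies follow the power-spectrum centroid; an optional dual
// ascent enforces exact reconstruction.  Gauss-Seidel ordering: every mode
// update sees the already-updated versions of the preceding modes.  The
// per-mode update, centroid accumulation and convergence ratio are fused
// into one pass over the spectrum.
//
// fplus : FFT of the signal at bins 0..floor(N/2)
// freqs : bin frequencies, cycles/sample, same length as fplus
// omega : initial centre frequencies (length K)
// [[Rcpp::export]]
Rcpp::List vmd_core(const arma::cx_vec& fplus, const arma::vec& freqs,
                    int K, double alpha, double tau, double tol,
                    int max_iter, arma::vec omega, bool keep_dc) {
  const uword F = fplus.n_elem;
  cx_mat u(F, K, fill::zeros);
  cx_vec lambda(F, fill::zeros), sum_all(F, fill::zeros);
  const double eps = 2.220446049250313e-16;
  const std::complex<double>* fp = fplus.memptr();
  const double* fr = freqs.memptr();
  std::vector<double> mode_norm(K, 0.0);  // ||u_k||^2 from the previous sweep
  int n = 0;
  bool converged = false;

  while (n < max_iter) {
    double ratio = 0.0;
    for (int k = 0; k < K; ++k) {
      std::complex<double>* uk = u.colptr(k);
      std::complex<double>* sa = sum_all.memptr();
      const std::complex<double>* lm = lambda.memptr();
      const double wk = omega(k);
      double ptot = 0.0, pdot = 0.0, dd = 0.0;
      for (uword f = 0; f < F; ++f) {
        const double df = fr[f] - wk;
        const double inv = 1.0 / (1.0 + 2.0 * alpha * df * df);
        const std::complex<double> old = uk[f];
        sa[f] -= old;
        const std::complex<double> nu = (fp[f] - sa[f] + 0.5 * lm[f]) * inv;
        uk[f] = nu;
        sa[f] += nu;
        const double p = std::norm(nu);
        ptot += p;
        pdot += fr[f] * p;
        dd += std::norm(nu - old);
      }
      if (!(keep_dc && k == 0) && ptot > 0.0) omega(k) = pdot / ptot;
      ratio += dd / (mode_norm[k] + eps);
      mode_norm[k] = ptot;
    }
    if (tau > 0.0) lambda += tau * (fplus - sum_all);
    ++n;
    if (ratio < tol) { converged = true; break; }
  }

  return Rcpp::List::create(Rcpp::Named("uhat") = u,
                            Rcpp::Named("omega") = omega,
                            Rcpp::Named("n_iter") = n,
                            Rcpp::Named("converged") = converged);
}
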