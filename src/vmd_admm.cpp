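#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// ADMM iteration for variational mode decomposition, run on the
// nonnegative-frequency half-axis of the (mirrored) input spectrum.
//
// xhat_plus : one-sided FFT of the mirrored signal (bins 0..N/2)
// freqs     : frequency of each bin in cycles/sample, in [0, 0.5]
// omega0    : initial centre frequencies, length K
// alpha     : bandwidth penalty; tau: dual-ascent step for the multiplier
//
// Mode update:   u_k <- (X - sum_{i!=k} u_i + lambda/2) / (1 + 2*alpha*(w - w_k)^2)
// Centre update: w_k <- sum(w |u_k|^2) / sum(|u_k|^2)
// Dual update:   lambda <- lambda + tau * (X - sum_k u_k)
// Stop when sum_k ||u_k^new - u_k^old||^2 / ||u_k^old||^2 < tol.
// [[Rcpp::export(name = ".vmd_admm_cpp")]]
List vmd_admm_cpp(ComplexVector xhat_plus, NumericVector freqs,
                  NumericVector omega0, double alpha, double tau,
                  double tol, int max_iter, bool dc_mode) {
  const int H = xhat_plus.size();
  const int K = omega0.size();
  const double eps = 2.220446e-16;

  std::vector< std::complex<double> > xhat(H);
  for (int j = 0; j < H; ++j)
    xhat[j] = std::complex<double>(xhat_plus[j].r, xhat_plus[j].i);

  std::vector< std::vector< std::complex<double> > > u(
      K, std::vector< std::complex<double> >(H, 0.0));
  std::vector< std::complex<double> > lambda(H, 0.0), sum_u(H, 0.0);
  std::vector<double> omega(omega0.begin(), omega0.end());

  int iter = 0;
  bool converged = false;

  for (iter = 1; iter <= max_iter; ++iter) {
    double diff_total = 0.0;
    for (int k = 0; k < K; ++k) {
      double num = 0.0, den = 0.0, e_num = 0.0, e_den = 0.0;
      const double wk = omega[k];
      for (int j = 0; j < H; ++j) {
        const std::complex<double> u_old = u[k][j];
        const std::complex<double> resid =
            xhat[j] - (sum_u[j] - u_old) + 0.5 * lambda[j];
        const double fd = freqs[j] - wk;
        const std::complex<double> u_new = resid / (1.0 + 2.0 * alpha * fd * fd);
        const std::complex<double> d = u_new - u_old;
        num += std::norm(d);
        den += std::norm(u_old);
        sum_u[j] += d;
        u[k][j] = u_new;
        const double p = std::norm(u_new);
        e_num += freqs[j] * p;
        e_den += p;
      }
      diff_total += num / (den + eps);
      if (!(dc_mode && k == 0) && e_den > eps)
        omega[k] = e_num / e_den;
    }
    if (tau != 0.0)
      for (int j = 0; j < H; ++j)
        lambda[j] += tau * (xhat[j] - sum_u[j]);
    if (diff_total < tol) { converged = true; break; }
  }
  if (!converged) iter = max_iter;

  ComplexMatrix u_hat(K, H);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < H; ++j) {
      u_hat(k, j).r = u[k][j].real();
      u_hat(k, j).i = u[k][j].imag();
    }

  return List::create(_["u_hat"] = u_hat,
                      _["omega"] = NumericVector(omega.begin(), omega.end()),
                      _["n_iterations"] = iter,
                      _["converged"] = converged);
}
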