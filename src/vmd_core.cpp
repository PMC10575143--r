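#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Frequency-domain ADMM inner loop of variational mode decomposition.
//
// Operates on the one-sided spectrum of the (already mirror-extended)
// signal; all updates are pointwise in omega, so the FFTs stay on the R
// side.  Per iteration, for each mode z:
//   u_z(w)   <- (f(w) - sum_{i != z} u_i(w) + lambda(w)/2) /
//               (1 + alpha*(w - w_z)^2)
//   w_z      <- centroid of w over |u_z(w)|^2
// then dual ascent with step tau:
//   lambda(w) <- lambda(w) + tau * (f(w) - sum_z u_z(w)).
// Stops when sum_z ||u^(t+1)-u^t||^2 / ||u^t||^2 < tol.
// [[Rcpp::export]]
List vmd_core_cpp(ComplexVector f_hat, NumericVector freqs, int K,
                  double alpha, double tau, double tol, int max_iter,
                  NumericVector omega_init) {
  const int nf = f_hat.size();
  std::vector<std::complex<double> > f(nf), lambda(nf, 0.0);
  for (int i = 0; i < nf; ++i)
    f[i] = std::complex<double>(f_hat[i].r, f_hat[i].i);

  std::vector<std::vector<std::complex<double> > > u(
      K, std::vector<std::complex<double> >(nf, 0.0));
  std::vector<std::vector<std::complex<double> > > u_prev = u;
  std::vector<double> omega(omega_init.begin(), omega_init.end());
  std::vector<std::complex<double> > sum_all(nf, 0.0);

  int iter = 0;
  bool converged = false;
  double udiff = R_PosInf;
  const double eps = 2.220446e-16;

  while (iter < max_iter) {
    u_prev = u;
    // running sum of all modes so each update costs O(nf); modes with a
    // lower index enter the sum already updated (Gauss-Seidel sweep)
    for (int k = 0; k < K; ++k) {
      double num = 0.0, den = 0.0;
      for (int i = 0; i < nf; ++i) {
        std::complex<double> sum_other = sum_all[i] - u[k][i];
        double dw = freqs[i] - omega[k];
        std::complex<double> unew =
            (f[i] - sum_other + lambda[i] * 0.5) /
            (1.0 + alpha * dw * dw);
        sum_all[i] += unew - u[k][i];
        u[k][i] = unew;
        double p = std::norm(unew);
        num += freqs[i] * p;
        den += p;
      }
      if (den > 0.0) omega[k] = num / den;
    }
    if (tau > 0.0)
      for (int i = 0; i < nf; ++i) lambda[i] += tau * (f[i] - sum_all[i]);
    ++iter;
    udiff = 0.0;
    for (int k = 0; k < K; ++k) {
      double num = 0.0, den = eps;
      for (int i = 0; i < nf; ++i) {
        num += std::norm(u[k][i] - u_prev[k][i]);
        den += std::norm(u_prev[k][i]);
      }
      udiff += num / den;
    }
    if (udiff < tol) {
      converged = true;
      break;
    }
  }

  ComplexMatrix u_out(nf, K);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < nf; ++i) {
      u_out(i, k).r = u[k][i].real();
      u_out(i, k).i = u[k][i].imag();
    }
  ComplexVector lam_out(nf);
  for (int i = 0; i < nf; ++i) {
    lam_out[i].r = lambda[i].real();
    lam_out[i].i = lambda[i].imag();
  }
  return List::create(_["u_hat"] = u_out, _["omega"] = NumericVector(omega.begin(), omega.end()),
                      _["lambda_hat"] = lam_out, _["n_iter"] = iter,
                      _["converged"] = converged, _["rel_change"] = udiff);
}

// Direct-form II transposed IIR filter with initial conditions,
// a[0] assumed 1 (caller normalises).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(na, nb) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(nz, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int i = 0; i < std::min<int>(nz, zi.size()); ++i) z[i] = zi[i];

  NumericVector y(n);
  for (int m = 0; m < n; ++m) {
    double xm = x[m];
    double ym = bb[0] * xm + (nz > 0 ? z[0] : 0.0);
    for (int i = 0; i < nz - 1; ++i)
      z[i] = bb[i + 1] * xm + z[i + 1] - aa[i + 1] * ym;
    if (nz > 0) z[nz - 1] = bb[nz] * xm - aa[nz] * ym;
    y[m] = ym;
  }
  return y;
}
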