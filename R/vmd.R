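# Variational mode decomposition (VMD).
#
# A signal f is decomposed into K band-limited modes p_z with center
# frequencies w_z by minimising the summed bandwidths of the analytic,
# demodulated modes subject to sum_z p_z = f. The saddle point of the
# augmented Lagrangian is found by ADMM in the frequency domain:
# Wiener-filter mode updates, spectral-centroid frequency updates, and
# dual ascent on the reconstruction constraint. The pointwise inner loop
# is compiled (see src/); FFTs and boundary handling live here.

#' VMD parameters
#'
#' @param K number of modes (the pipeline default is 6).
#' @param alpha quadratic penalty factor controlling mode bandwidth; larger
#'   values give narrower modes. Default 2000, the usual literature value.
#' @param tau dual-ascent step (noise tolerance). 0 (default) disables the
#'   multiplier update, which is robust when the signal contains noise.
#' @param tol relative convergence tolerance on the summed squared change
#'   of the mode spectra.
#' @param max_iter iteration cap.
#' @param init center-frequency initialisation: `"uniform"` (evenly spaced
#'   over (0, 0.5) cycles/sample, deterministic default), `"zero"`, or
#'   `"random"` (uses `seed`).
#' @param seed integer seed for `init = "random"`.
#' @return a `vmd_params` list.
#' @export
vmd_params <- function(K = 6L, alpha = 2000, tau = 0, tol = 1e-6,
                       max_iter = 500L, init = c("uniform", "zero", "random"),
                       seed = 1L) {
  init <- match.arg(init)
  stopifnot(K >= 1, alpha > 0, tau >= 0, tol > 0, max_iter >= 1)
  structure(list(K = as.integer(K), alpha = alpha, tau = tau, tol = tol,
                 max_iter = as.integer(max_iter), init = init,
                 seed = as.integer(seed)),
            class = "vmd_params")
}

#' Decompose a signal into band-limited modes
#'
#' Runs frequency-domain ADMM on the mirror-extended signal: per iteration
#' each mode spectrum is updated by a Wiener filter centred on its current
#' frequency, each center frequency moves to the spectral centroid of its
#' mode's power, and (for `tau > 0`) the Lagrange multiplier takes a dual
#' ascent step on the reconstruction residual. Modes are returned in the
#' time domain with the mirror extension cropped off, sorted by ascending
#' center frequency.
#'
#' @param signal numeric vector, single channel.
#' @param fs sampling rate in Hz.
#' @param params a [vmd_params()] object.
#' @return a `vmd_result` with elements `modes` (K x N matrix), `omega`
#'   (cycles/sample, ascending), `omega_hz`, `lambda_hat`, `n_iter`,
#'   `converged`, `rel_change` and `residual` (signal minus mode sum).
#' @export
#' @examples
#' x <- cos(2 * pi * 10 * (0:511) / 256)
#' res <- vmd_decompose(x, fs = 256, vmd_params(K = 1))
#' res$omega_hz  # close to 10
vmd_decompose <- function(signal, fs, params = vmd_params()) {
  signal <- as.numeric(signal)
  assert_finite(signal, "signal")
  n <- length(signal)
  if (n < 2 * params$K)
    stop("signal too short: need at least 2*K samples", call. = FALSE)

  # mirror-extend by half the length on each side to suppress edge ringing
  left <- n %/% 2
  right <- n - left
  f <- c(rev(signal[seq_len(left)]), signal,
         rev(signal[(n - right + 1L):n]))
  t_len <- length(f)                    # = 2n, always even
  nf <- t_len %/% 2L + 1L
  freqs <- (0:(nf - 1L)) / t_len        # cycles/sample, 0 .. 0.5
  f_hat <- stats::fft(f)[seq_len(nf)]

  omega0 <- switch(params$init,
    uniform = (0.5 / params$K) * (seq_len(params$K) - 0.5),
    zero = rep(0, params$K),
    random = with_seed(params$seed, sort(stats::runif(params$K, 0, 0.5))))

  core <- vmd_core_cpp(f_hat, freqs, params$K, params$alpha, params$tau,
                       params$tol, params$max_iter, omega0)

  # invert each one-sided mode spectrum with Hermitian symmetry, crop mirror
  modes <- matrix(0, nrow = params$K, ncol = n)
  for (k in seq_len(params$K)) {
    u <- core$u_hat[, k]
    full <- c(u, Conj(u[(nf - 1L):2L]))
    m <- Re(stats::fft(full, inverse = TRUE)) / t_len
    modes[k, ] <- m[(left + 1L):(left + n)]
  }
  ord <- order(core$omega)
  structure(list(modes = modes[ord, , drop = FALSE],
                 omega = core$omega[ord],
                 omega_hz = core$omega[ord] * fs,
                 lambda_hat = core$lambda_hat,
                 n_iter = core$n_iter,
                 converged = core$converged,
                 rel_change = core$rel_change,
                 residual = signal - colSums(modes),
                 fs = fs, params = params),
            class = "vmd_result")
}

#' @export
print.vmd_result <- function(x, ...) {
  cat(sprintf("<vmd_result> K = %d, %d iterations (%s)\n",
              nrow(x$modes), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat("  center frequencies (Hz):", paste(signif(x$omega_hz, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Energy entropy of decomposed modes
#'
#' For each mode z: energy `E_z = sum p_z(n)^2`, energy fraction
#' `U_z = E_z / sum E_z`, and energy entropy `B_z = -U_z * log10(U_z)`
#' (with `B_z = 0` when `U_z = 0`, the limit convention).
#'
#' @param result a [vmd_decompose()] result, or a K x N mode matrix.
#' @return list with `E`, `U` (sums to 1) and `B` per mode.
#' @export
energy_entropy <- function(result) {
  modes <- if (inherits(result, "vmd_result")) result$modes else as.matrix(result)
  e <- rowSums(modes^2)
  if (sum(e) <= 0)
    stop("all modes have zero energy; energy fractions undefined", call. = FALSE)
  u <- e / sum(e)
  b <- ifelse(u > 0, -u * log10(u), 0)
  list(E = e, U = u, B = b)
}
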