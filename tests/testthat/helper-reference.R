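# Independently coded plain-R reference VMD used only as a cross-check.
# Deliberately different construction from the package implementation:
# no mirror extension, no compiled code, whole-spectrum bookkeeping in a
# 3-d array, Jacobi-style mode sum (all modes from the previous sweep),
# and no early convergence exit.
reference_vmd <- function(x, fs, K, alpha, tau = 0, n_iter = 500) {
  n <- length(x)
  nf <- n %/% 2 + 1
  w <- (0:(nf - 1)) / n
  fh <- stats::fft(x)[1:nf]
  u <- matrix(0 + 0i, nrow = nf, ncol = K)
  lam <- rep(0 + 0i, nf)
  om <- (0.5 / K) * (seq_len(K) - 0.5)
  for (it in seq_len(n_iter)) {
    u_old <- u
    for (k in seq_len(K)) {
      others <- rowSums(u_old[, -k, drop = FALSE])
      if (k > 1) # include this sweep's earlier modes the way ADMM sweeps do
        others <- others - rowSums(u_old[, seq_len(k - 1), drop = FALSE]) +
          rowSums(u[, seq_len(k - 1), drop = FALSE])
      u[, k] <- (fh - others + lam / 2) / (1 + alpha * (w - om[k])^2)
      pw <- Mod(u[, k])^2
      if (sum(pw) > 0) om[k] <- sum(w * pw) / sum(pw)
    }
    if (tau > 0) lam <- lam + tau * (fh - rowSums(u))
  }
  ord <- order(om)
  modes <- t(vapply(ord, function(k) {
    full <- c(u[, k], Conj(u[(nf - 1):2, k]))
    Re(stats::fft(full, inverse = TRUE)) / n
  }, numeric(n)))
  list(omega = om[ord], omega_hz = om[ord] * fs, modes = modes)
}

# brute-force AUC: fraction of correctly ordered (positive, negative)
# pairs with half credit for ties
pairwise_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
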