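test_that("a single mode locks onto a pure tone and reproduces it", {
  fs <- 256
  x <- cos(2 * pi * 10 * (0:511) / fs)
  res <- vmd_decompose(x, fs, vmd_params(K = 1, alpha = 2000))
  expect_equal(res$omega_hz, 10, tolerance = 0.02)
  interior <- 26:486                       # inner 90% of samples
  rel <- sqrt(sum((res$modes[1, interior] - x[interior])^2) /
                sum(x[interior]^2))
  expect_lt(rel, 0.05)
  expect_true(res$converged)
})

test_that("three modes recover the {2, 24, 88} Hz mixture", {
  mix <- make_tone_mixture(c(2, 24, 88), c(1, 0.5, 0.25), 256, 4)
  res <- vmd_decompose(mix, 256, vmd_params(K = 3, alpha = 2000))
  expect_equal(res$omega_hz, c(2, 24, 88), tolerance = 0.05)
  expect_identical(res$omega, sort(res$omega))
  # each mode's own FFT peak sits at its reported center frequency
  for (k in 1:3) {
    m <- res$modes[k, ]
    amp <- Mod(stats::fft(m))[1:513]
    peak_hz <- (which.max(amp) - 1) * 256 / 1024
    expect_equal(peak_hz, res$omega_hz[k], tolerance = 0.05 * res$omega_hz[k])
  }
})

test_that("center frequencies agree with an independent reference VMD", {
  mix <- make_tone_mixture(c(2, 24, 88), c(1, 0.5, 0.25), 256, 4)
  res <- vmd_decompose(mix, 256, vmd_params(K = 3, alpha = 2000))
  ref <- reference_vmd(mix, 256, K = 3, alpha = 2000)
  expect_equal(res$omega_hz, ref$omega_hz, tolerance = 0.02)
})

test_that("mode sums reconstruct band-passed EEG background epochs", {
  ds <- fixture("recon_epochs", function()
    make_dataset(synthetic_spec(n_epochs_per_class = 2, seed = 3)))
  interior <- 26:486
  for (i in 1:2) {                         # interictal epochs
    rec <- eeg_recording(ds$epochs[[i]]$data, fs = 256)
    bp <- preprocess(rec, band = c(1, 60), notch_hz = NULL)
    x <- bp$data[1, ]
    res <- vmd_decompose(x, 256, vmd_params(K = 6, alpha = 2000, tau = 0))
    rel <- sqrt(sum((colSums(res$modes)[interior] - x[interior])^2) /
                  sum(x[interior]^2))
    expect_lt(rel, 0.05)
  }
})

test_that("more iterations never worsen the convergence residual", {
  mix <- make_tone_mixture(c(2, 24, 88), c(1, 0.5, 0.25), 256, 4,
                           noise_sd = 0.1, seed = 5)
  res <- lapply(c(10, 50, 200), function(mi)
    vmd_decompose(mix, 256, vmd_params(K = 3, alpha = 2000,
                                       tol = 1e-14, max_iter = mi)))
  changes <- vapply(res, `[[`, numeric(1), "rel_change")
  expect_true(all(diff(changes) <= 1e-12))
})

test_that("large alpha narrows the recovered modes", {
  mix <- make_tone_mixture(c(2, 24, 88), c(1, 0.5, 0.25), 256, 4,
                           noise_sd = 0.25, seed = 1)
  bw95 <- function(mode) {
    n <- length(mode)
    p <- Mod(stats::fft(mode))[1:(n / 2 + 1)]^2
    f <- (0:(n / 2)) * 256 / n
    cs <- cumsum(p) / sum(p)
    f[which(cs >= 0.975)[1]] - f[which(cs >= 0.025)[1]]
  }
  bw <- function(alpha) {
    r <- vmd_decompose(mix, 256, vmd_params(K = 3, alpha = alpha))
    mean(vapply(1:3, function(k) bw95(r$modes[k, ]), numeric(1)))
  }
  expect_lt(bw(1e5), bw(1e2))
})

test_that("decomposition validates its inputs and reports non-convergence", {
  expect_error(vmd_decompose(c(1, NA, 3, 4), 10, vmd_params(K = 1)),
               "non-finite")
  expect_error(vmd_decompose(rnorm(5), 10, vmd_params(K = 3)), "short")
  mix <- make_tone_mixture(c(2, 24, 88), c(1, 0.5, 0.25), 256, 4,
                           noise_sd = 0.5, seed = 2)
  res <- vmd_decompose(mix, 256,
                       vmd_params(K = 3, tol = 1e-14, max_iter = 3))
  expect_false(res$converged)
  expect_equal(res$n_iter, 3)
})

test_that("energy fractions are normalised and entropies match closed forms", {
  # all energy in one mode: U = (1, 0), B = (0, 0)
  one <- rbind(c(1, 2, 3), c(0, 0, 0))
  ee <- energy_entropy(one)
  expect_equal(ee$U, c(1, 0))
  expect_equal(ee$B, c(0, 0))
  # equal-energy pair: U = 0.5 each, B = -0.5 log10(0.5) each
  eq <- rbind(c(1, 1, 1, 1), c(-1, 1, -1, 1))
  ee2 <- energy_entropy(eq)
  expect_equal(ee2$U, c(0.5, 0.5))
  expect_equal(ee2$B, rep(-0.5 * log10(0.5), 2))
  expect_equal(ee2$B, rep(0.15051, 2), tolerance = 1e-4)
  # normalisation on random decompositions
  set.seed(42)
  for (i in 1:25) {
    r <- vmd_decompose(rnorm(256), 128,
                       vmd_params(K = 3, alpha = 500, max_iter = 40))
    expect_equal(sum(energy_entropy(r)$U), 1, tolerance = 1e-12)
  }
  expect_error(energy_entropy(matrix(0, 2, 4)), "zero energy")
})

test_that("random initialisation is reproducible through its seed", {
  mix <- make_tone_mixture(c(5, 40), c(1, 0.7), 256, 2)
  a <- vmd_decompose(mix, 256, vmd_params(K = 2, init = "random", seed = 3))
  b <- vmd_decompose(mix, 256, vmd_params(K = 2, init = "random", seed = 3))
  expect_identical(a$modes, b$modes)
  expect_identical(a$omega, b$omega)
})
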