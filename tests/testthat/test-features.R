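test_that("differential entropy matches its Gaussian closed form", {
  fs <- 256
  bands <- band_set()
  set.seed(11)
  x <- rnorm(fs * 200)                    # unit-variance white noise, 200 s
  # oracle: analytic band variance of white noise = sigma^2 * width / Nyquist
  true_de <- 0.5 * log(2 * pi * exp(1) *
                         (bands$high_hz - bands$low_hz) / (fs / 2))
  est <- de_bands(x, fs, bands)
  expect_true(all(abs(est - true_de) < 0.1))
})

test_that("DE shifts by exactly ln 2 when amplitude doubles", {
  set.seed(3)
  x <- rnorm(512)
  d1 <- differential_entropy(x, 256)
  d2 <- differential_entropy(2 * x, 256)
  expect_equal(d2 - d1, log(2), tolerance = 1e-9)
})

test_that("a band scaled to variance 1/(2*pi*e) has zero DE", {
  set.seed(5)
  x <- rnorm(256 * 4)
  v_alpha <- de_bands(x, 256)[["alpha"]]
  # rescale so the alpha band's power is exactly 1/(2*pi*e)
  scale <- sqrt((1 / (2 * pi * exp(1))) /
                  exp(2 * v_alpha - log(2 * pi * exp(1))))
  expect_equal(de_bands(scale * x, 256)[["alpha"]], 0, tolerance = 1e-9)
})

test_that("DE is invariant to constant offsets and flags silent bands", {
  set.seed(7)
  x <- rnorm(512)
  expect_equal(differential_entropy(x + 100, 256),
               differential_entropy(x, 256))
  # a pure 10 Hz tone leaves the delta band with zero measured power only
  # if the spectrum is exactly zero there; an all-zero signal is the
  # guaranteed silent case
  expect_error(differential_entropy(rep(0, 512), 256), "silent")
  expect_error(differential_entropy(rnorm(100), 256), "window")
})

test_that("Higuchi FD reproduces the known dimensions", {
  expect_equal(higuchi_fd(make_fd_series("line", 1024)$series),
               1, tolerance = 0.02)
  wn <- vapply(1:20, function(s)
    higuchi_fd(make_fd_series("white_noise", 512, seed = s)$series),
    numeric(1))
  expect_equal(mean(wn), 2, tolerance = 0.1)
  for (h in c(0.2, 0.5, 0.8)) {
    fd <- vapply(1:20, function(s)
      higuchi_fd(make_fd_series("fbm", 1024, hurst = h, seed = s)$series),
      numeric(1))
    expect_equal(mean(fd), 2 - h, tolerance = 0.1)
  }
})

test_that("Higuchi FD decreases monotonically with the Hurst exponent", {
  mean_fd <- vapply(c(0.2, 0.5, 0.8), function(h)
    mean(vapply(1:20, function(s)
      higuchi_fd(make_fd_series("fbm", 1024, hurst = h, seed = s)$series),
      numeric(1))), numeric(1))
  expect_true(all(diff(mean_fd) < 0))
})

test_that("Higuchi FD validates input and honours fit_range", {
  expect_error(higuchi_fd(rep(1, 512)), "constant|degenerate")
  expect_error(higuchi_fd(rnorm(16), higuchi_params(k_max = 8)), "short")
  x <- make_fd_series("fbm", 1024, hurst = 0.5, seed = 1)$series
  full <- higuchi_fd(x, higuchi_params(k_max = 8))
  sub <- higuchi_fd(x, higuchi_params(k_max = 8, fit_range = 2:8))
  expect_false(identical(full, sub))
  expect_true(sub >= 1 && sub <= 2)
})

test_that("the feature matrix has the documented geometry", {
  ep <- epoch(matrix(make_tone_mixture(c(3, 30), c(1, 1), 256, 2,
                                       noise_sd = 0.3, seed = 2), 1),
              label = 0, fs = 256)
  fm <- extract_features(list(ep), vmd = vmd_params(K = 6))
  expect_equal(ncol(fm$values), 12)       # 1 channel x 6 modes x 2
  expect_equal(colnames(fm$values)[1:4],
               c("ch1_m1_de", "ch1_m1_hfd", "ch1_m2_de", "ch1_m2_hfd"))
  expect_equal(length(fm$channel_groups), 1)

  fx <- small_planted_features()
  expect_equal(dim(fx$fm$values), c(80L, 8L * 6L * 2L))
  expect_false(anyNA(fx$fm$values))
  expect_true(all(vapply(fx$fm$channel_groups, length, 0L) == 12L))
})

test_that("feature extraction is deterministic and round-trips CSV", {
  ds <- make_dataset(synthetic_spec(n_channels = 2, informative_channels = 1,
                                    n_epochs_per_class = 3, seed = 13))
  a <- extract_features(ds$epochs, vmd = vmd_params(K = 3))
  b <- extract_features(ds$epochs, vmd = vmd_params(K = 3))
  expect_identical(a$values, b$values)

  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(a, path)
  back <- read_features_csv(path)
  expect_equal(back$values, a$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$labels, a$labels)
  expect_identical(back$channel_groups, a$channel_groups)
})

test_that("raw-signal DE source duplicates DE across a channel's modes", {
  ds <- make_dataset(synthetic_spec(n_channels = 1, informative_channels = 1,
                                    n_epochs_per_class = 2, seed = 19))
  fm <- extract_features(ds$epochs, vmd = vmd_params(K = 3),
                         de_source = "raw")
  de_cols <- which(fm$feature_index$feature == "de")
  expect_true(all(abs(fm$values[, de_cols[1]] - fm$values[, de_cols[2]]) < 1e-12))
})
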