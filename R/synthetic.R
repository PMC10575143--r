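# Synthetic test worlds.
#
# Three generators: tone mixtures with known spectral composition (oracle
# for the decomposition), series of known theoretical fractal dimension
# (oracle for the Higuchi estimator), and labelled multichannel pseudo-EEG
# epochs with a planted set of informative channels (oracle for the whole
# pipeline). Everything is bit-reproducible from its seed.

#' Tone mixture with additive white noise
#'
#' @param freqs tone frequencies in Hz (all below `fs / 2`).
#' @param amps amplitudes, same length as `freqs`.
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param noise_sd standard deviation of added white Gaussian noise.
#' @param seed integer seed.
#' @return numeric vector of length `fs * duration_s`.
#' @export
#' @examples
#' x <- make_tone_mixture(c(2, 24, 88), c(1, 0.5, 0.25), 256, 4)
make_tone_mixture <- function(freqs, amps, fs, duration_s,
                              noise_sd = 0, seed = 1L) {
  if (length(freqs) != length(amps))
    stop("freqs and amps must have the same length", call. = FALSE)
  if (any(freqs >= fs / 2))
    stop("tone frequencies must be below the Nyquist rate fs/2", call. = FALSE)
  n <- as.integer(round(fs * duration_s))
  t <- (seq_len(n) - 1) / fs
  x <- rep(0, n)
  for (i in seq_along(freqs)) x <- x + amps[i] * cos(2 * pi * freqs[i] * t)
  if (noise_sd > 0) x <- x + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  x
}

# fractional Gaussian noise by circulant embedding (Davies-Harte); exact
# when the embedding is non-negative definite, which holds for the H used
# here; tiny negative eigenvalues from rounding are clipped.
fgn_davies_harte <- function(n, hurst) {
  k <- 0:n
  g <- 0.5 * (abs(k - 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                abs(k + 1)^(2 * hurst))
  circ <- c(g, g[n:2])                      # length 2n
  lam <- Re(stats::fft(circ))
  lam[lam < 0] <- 0
  m <- 2L * n
  z0 <- stats::rnorm(1); zn <- stats::rnorm(1)
  a <- stats::rnorm(n - 1); b <- stats::rnorm(n - 1)
  w <- complex(length.out = m)
  w[1] <- sqrt(lam[1]) * z0
  w[n + 1] <- sqrt(lam[n + 1]) * zn
  w[2:n] <- sqrt(lam[2:n] / 2) * complex(real = a, imaginary = b)
  w[m:(n + 2)] <- Conj(w[2:n])
  Re(stats::fft(w))[seq_len(n)] / sqrt(m)
}

#' Series with known theoretical fractal dimension
#'
#' `line` has dimension 1 (smooth curve), Gaussian `white_noise` has
#' dimension 2 under Higuchi's estimator, and fractional Brownian motion
#' with Hurst exponent H has dimension `2 - H` (fBm is synthesised by
#' cumulating Davies-Harte fractional Gaussian noise).
#'
#' @param kind one of `"line"`, `"white_noise"`, `"fbm"`.
#' @param n series length (>= 128).
#' @param hurst Hurst exponent in (0, 1), used for `kind = "fbm"`.
#' @param seed integer seed.
#' @return list with `series` and `fd_true`.
#' @export
make_fd_series <- function(kind = c("line", "white_noise", "fbm"),
                           n = 1024L, hurst = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 128) stop("n must be at least 128", call. = FALSE)
  switch(kind,
    line = list(series = 0.5 + 2 * seq_len(n) / n, fd_true = 1.0),
    white_noise = list(series = with_seed(seed, stats::rnorm(n)), fd_true = 2.0),
    fbm = {
      if (!(hurst > 0 && hurst < 1))
        stop("hurst must lie in (0, 1)", call. = FALSE)
      list(series = with_seed(seed, cumsum(fgn_davies_harte(n, hurst))),
           fd_true = 2 - hurst)
    })
}

# 1/f-shaped ("pink") noise via spectral shaping of white noise,
# normalised to unit standard deviation
pink_noise <- function(n, slope = -1) {
  w <- stats::rnorm(n)
  wh <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                   # symmetric frequency index
  shape <- f^(slope / 2)
  shape[1] <- 0                             # no DC
  x <- Re(stats::fft(wh * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# one period of a 3 Hz-style spike-and-wave complex, unit peak amplitude:
# biphasic sharp transient (~50 ms, within the 20-70 ms spike range typical
# of epileptiform discharges) followed by a slower half-sine wave
spike_wave_cycle <- function(n_cycle, fs) {
  tau <- (seq_len(n_cycle) - 1) / fs
  spike <- exp(-((tau - 0.050) / 0.011)^2) - 0.45 * exp(-((tau - 0.085) / 0.020)^2)
  slow <- ifelse(tau >= 0.12 & tau <= 0.32,
                 0.55 * sin(pi * (tau - 0.12) / 0.20), 0)
  spike + slow
}

#' Specification of a synthetic labelled EEG dataset
#'
#' Defaults state the emulated world: 8 channels at 256 Hz, 2-s epochs,
#' 100 epochs per class (the per-subject layout of CHB-MIT experiments),
#' 5 informative channels, a 3 Hz spike-and-wave ictal pattern at three
#' times the 20 µV background amplitude.
#'
#' @param n_channels channel count.
#' @param informative_channels 1-based indices of channels carrying the
#'   ictal signature (may be empty for a null dataset).
#' @param fs sampling rate (Hz).
#' @param window_s epoch length (s).
#' @param n_epochs_per_class epochs per class.
#' @param ictal_effect spike-and-wave amplitude gain relative to the
#'   background standard deviation (>= 1).
#' @param spike_rate_hz spike-and-wave repetition rate (Hz).
#' @param ictal_fraction probability that an informative channel actually
#'   expresses the ictal pattern in a given ictal epoch (default 1;
#'   values < 1 model the spatial variability of seizure spread, making
#'   single channels insufficient and a channel *subset* the planted
#'   truth).
#' @param noise_sd background standard deviation (µV).
#' @param seed integer seed; output is bit-reproducible.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_channels = 8L, informative_channels = 1:5,
                           fs = 256, window_s = 2, n_epochs_per_class = 100L,
                           ictal_effect = 3, spike_rate_hz = 3,
                           ictal_fraction = 1, noise_sd = 20, seed = 1L) {
  informative_channels <- as.integer(informative_channels)
  if (length(informative_channels) &&
      (min(informative_channels) < 1 || max(informative_channels) > n_channels))
    stop("informative_channels must index existing channels", call. = FALSE)
  stopifnot(n_epochs_per_class > 0, ictal_effect >= 1, noise_sd > 0,
            ictal_fraction > 0, ictal_fraction <= 1)
  structure(list(n_channels = as.integer(n_channels),
                 informative_channels = informative_channels,
                 fs = fs, window_s = window_s,
                 n_epochs_per_class = as.integer(n_epochs_per_class),
                 ictal_effect = ictal_effect, spike_rate_hz = spike_rate_hz,
                 ictal_fraction = ictal_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labelled synthetic EEG dataset with planted channels
#'
#' Interictal epochs carry 1/f-shaped noise under an organised rhythmic
#' background (delta, dominant 10 Hz alpha, weak beta; random phases per
#' epoch) on every channel. On informative channels, ictal epochs replace
#' this with a rhythmic spike-and-wave train (amplitude
#' `0.3 * ictal_effect * noise_sd`), a suppressed 1/f residual and added
#' broadband high-frequency noise — the generator is calibrated so that,
#' on informative channels, mean per-mode differential entropy is lower
#' and mean Higuchi fractal dimension higher in the ictal class, the
#' contrast the pipeline must exploit. Non-informative channels are
#' identically distributed across classes.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `epochs` (interictal first, then ictal) and
#'   `informative` (the planted channel indices).
#' @export
#' @examples
#' ds <- make_dataset(synthetic_spec(n_epochs_per_class = 5))
#' length(ds$epochs)  # 10
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- as.integer(round(spec$fs * spec$window_s))
  t <- (seq_len(n) - 1) / spec$fs
  n_cycle <- as.integer(round(spec$fs / spec$spike_rate_hz))
  cycle <- spike_wave_cycle(n_cycle, spec$fs)
  sw_template <- rep_len(cycle, n + n_cycle)

  # Interictal: 1/f-shaped noise under an organised rhythmic background
  # (slow delta, dominant 10 Hz alpha, weak beta), random phases per epoch.
  # Smooth rhythms keep the per-mode fractal dimension of the interictal
  # class down; see the calibration note in the methods vignette.
  rhythm <- function(amp, freq_hz)
    amp * spec$noise_sd * sin(2 * pi * freq_hz * t + stats::runif(1, 0, 2 * pi))
  background <- function() {
    0.35 * spec$noise_sd * pink_noise(n) +
      rhythm(1.5, 10) + rhythm(0.8, 2.2) + rhythm(0.5, 19)
  }
  # Ictal (informative channels only): rhythmic spike-and-wave replaces the
  # background rhythms (amplitude 0.3 * ictal_effect * noise_sd), residual
  # suppressed 1/f noise, plus broadband high-frequency noise that raises
  # the fractal dimension and flattens band power.
  ictal_channel <- function() {
    shift <- sample.int(n_cycle, 1L)
    sw <- 0.3 * spec$ictal_effect * spec$noise_sd *
      sw_template[shift:(shift + n - 1L)]
    sw + 0.15 * spec$noise_sd * pink_noise(n) +
      0.45 * spec$noise_sd * stats::rnorm(n)
  }

  with_seed(spec$seed, {
    epochs <- vector("list", 2L * spec$n_epochs_per_class)
    idx <- 0L
    for (label in c(0L, 1L)) {
      for (i in seq_len(spec$n_epochs_per_class)) {
        dat <- matrix(0, nrow = spec$n_channels, ncol = n)
        for (ch in seq_len(spec$n_channels)) {
          express <- label == 1L && ch %in% spec$informative_channels &&
            (spec$ictal_fraction >= 1 || stats::runif(1) < spec$ictal_fraction)
          dat[ch, ] <- if (express) ictal_channel() else background()
        }
        idx <- idx + 1L
        epochs[[idx]] <- epoch(dat, label = label, fs = spec$fs,
                               source_id = "synthetic", index = idx)
      }
    }
    list(epochs = epochs, informative = spec$informative_channels)
  })
}
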