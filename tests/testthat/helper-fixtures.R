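# Shared fixtures, built once per test session and cached so the feature
# matrices (the expensive part: VMD of every channel of every epoch) are
# not recomputed across test files.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(builder())
  .fixture_cache[[name]]
}

# reduced default world: same generator settings as the default spec,
# fewer epochs, so rank-sum contrasts are still decisive
small_planted_features <- function() {
  fixture("small_planted", function() {
    ds <- make_dataset(synthetic_spec(n_epochs_per_class = 40, seed = 101))
    list(fm = extract_features(ds$epochs), informative = ds$informative)
  })
}

# 6-channel world with 2 planted channels under partial ictal expression,
# small enough for brute-force subset enumeration
six_channel_features <- function() {
  fixture("six_channel", function() {
    ds <- make_dataset(synthetic_spec(n_channels = 6,
                                      informative_channels = c(2, 5),
                                      ictal_fraction = 0.7,
                                      n_epochs_per_class = 60, seed = 23))
    list(fm = extract_features(ds$epochs), informative = ds$informative)
  })
}

# no informative channels: class-conditional distributions identical
# (enough epochs that chance-level accuracy has a tight sampling band)
null_features <- function() {
  fixture("null_world", function() {
    ds <- make_dataset(synthetic_spec(informative_channels = integer(0),
                                      n_epochs_per_class = 50, seed = 31))
    extract_features(ds$epochs)
  })
}

# a deterministic multi-rhythm test recording
test_recording <- function(n_channels = 3, seconds = 8, fs = 256, seed = 7) {
  t <- (0:(seconds * fs - 1)) / fs
  set.seed(seed)
  dat <- t(vapply(seq_len(n_channels), function(ch)
    30 * sin(2 * pi * (8 + ch) * t) + 10 * sin(2 * pi * 3 * t + ch) +
      5 * rnorm(length(t)), numeric(length(t))))
  eeg_recording(dat, fs = fs,
                channel_labels = paste0("EEG", seq_len(n_channels)))
}

# one-sided FFT amplitude at frequency f (oracle for filter tests)
fft_amplitude <- function(x, f, fs) {
  n <- length(x)
  bin <- round(f * n / fs) + 1L
  2 * Mod(stats::fft(x))[bin] / n
}
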