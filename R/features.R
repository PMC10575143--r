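# Per-mode features: differential entropy (DE) and Higuchi fractal
# dimension (HFD). DE treats each frequency band's content as Gaussian,
# giving 0.5 * ln(2*pi*e*sigma^2) per band from short-time band power;
# HFD estimates the fractal dimension from the scaling of curve lengths
# of delay-decimated subsequences.

#' Frequency band set
#'
#' Defaults to the five canonical EEG bands: delta (1-4), theta (4-8),
#' alpha (8-13), beta (13-30), gamma (30-50 Hz). Band membership of a
#' spectral bin uses half-open `(low, high]` edges so adjacent bands never
#' share a bin.
#'
#' @param bands data.frame with columns `name`, `low_hz`, `high_hz`,
#'   ascending and non-overlapping.
#' @return a `band_set` data.frame.
#' @export
band_set <- function(bands = data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz = c(1, 4, 8, 13, 30),
    high_hz = c(4, 8, 13, 30, 50))) {
  stopifnot(all(c("name", "low_hz", "high_hz") %in% names(bands)))
  if (any(bands$low_hz >= bands$high_hz))
    stop("each band needs low_hz < high_hz", call. = FALSE)
  if (nrow(bands) > 1 && any(bands$low_hz[-1] < bands$high_hz[-nrow(bands)]))
    stop("bands must be ascending and non-overlapping", call. = FALSE)
  structure(bands, class = c("band_set", "data.frame"))
}

#' Higuchi estimator parameters
#'
#' @param k_max largest delay; default 8, a common choice that keeps at
#'   least 64 points in the fastest subsequence of a 512-sample epoch.
#' @param fit_range delays used in the log-log fit (default all of
#'   `2:k_max` plus 1).
#' @return a `higuchi_params` list.
#' @export
higuchi_params <- function(k_max = 8L, fit_range = NULL) {
  stopifnot(k_max >= 2)
  structure(list(k_max = as.integer(k_max), fit_range = fit_range),
            class = "higuchi_params")
}

# one-sided Hamming-window periodogram band variances for one window
band_variances <- function(x, fs, bands) {
  n <- length(x)
  w <- hamming_window(n)
  xf <- stats::fft((x - mean(x)) * w)
  nf <- n %/% 2L + 1L
  psd <- (Mod(xf[seq_len(nf)])^2) / (fs * sum(w^2))
  if (n %% 2L == 0L) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  else psd[2:nf] <- 2 * psd[2:nf]
  freq <- (0:(nf - 1L)) * fs / n
  df <- fs / n
  vapply(seq_len(nrow(bands)), function(b) {
    sel <- freq > bands$low_hz[b] & freq <= bands$high_hz[b]
    sum(psd[sel]) * df
  }, numeric(1))
}

#' Differential entropy of a band-limited series
#'
#' Short-time Fourier analysis with non-overlapping 1-s Hamming windows;
#' in each window and band the band power \eqn{\hat\sigma^2} is integrated
#' from the periodogram and converted to the Gaussian differential entropy
#' \eqn{\tfrac12 \ln(2\pi e \hat\sigma^2)} (nats). The scalar returned is
#' the mean over bands, then over windows. Bands with zero power are
#' skipped with a warning; if every band is silent an error is raised.
#'
#' @param x numeric series (at least one full window).
#' @param fs sampling rate (Hz).
#' @param bands a [band_set()].
#' @param window_s analysis window length in seconds (default 1).
#' @return DE scalar in nats.
#' @seealso [de_bands()] for the per-band estimator.
#' @export
differential_entropy <- function(x, fs, bands = band_set(), window_s = 1) {
  nwin <- floor(length(x) / (fs * window_s))
  if (nwin < 1) stop("series shorter than one analysis window", call. = FALSE)
  wlen <- as.integer(round(fs * window_s))
  skipped <- FALSE
  de_win <- numeric(nwin)
  any_band <- FALSE
  for (w in seq_len(nwin)) {
    seg <- x[((w - 1L) * wlen + 1L):(w * wlen)]
    v <- band_variances(seg, fs, bands)
    ok <- v > 0
    if (any(!ok)) skipped <- TRUE
    if (!any(ok)) { de_win[w] <- NA_real_; next }
    any_band <- TRUE
    de_win[w] <- mean(0.5 * log(2 * pi * exp(1) * v[ok]))
  }
  if (!any_band) stop("all frequency bands are silent; DE undefined", call. = FALSE)
  if (skipped) warning("silent band(s) skipped in differential entropy", call. = FALSE)
  mean(de_win, na.rm = TRUE)
}

#' Per-band differential entropy
#'
#' Band power is averaged across the 1-s windows first and log-transformed
#' once, giving a consistent per-band estimate (the per-window
#' log-then-average of [differential_entropy()] carries a small-sample
#' bias in narrow bands).
#'
#' @inheritParams differential_entropy
#' @return named vector of per-band DE (nats); silent bands are `NA`.
#' @export
de_bands <- function(x, fs, bands = band_set(), window_s = 1) {
  nwin <- floor(length(x) / (fs * window_s))
  if (nwin < 1) stop("series shorter than one analysis window", call. = FALSE)
  wlen <- as.integer(round(fs * window_s))
  acc <- matrix(0, nrow = nwin, ncol = nrow(bands))
  for (w in seq_len(nwin))
    acc[w, ] <- band_variances(x[((w - 1L) * wlen + 1L):(w * wlen)], fs, bands)
  v <- colMeans(acc)
  out <- ifelse(v > 0, 0.5 * log(2 * pi * exp(1) * v), NA_real_)
  names(out) <- bands$name
  out
}

#' Higuchi fractal dimension
#'
#' For each delay k the mean normalised curve length of the k
#' delay-decimated subsequences is computed,
#' \eqn{L(k) = \frac1k \sum_w L_w(k)}, and the dimension is the negative
#' slope of the least-squares fit of \eqn{\ln L(k)} on \eqn{\ln k}.
#' Values are clamped to `[1, 2]`, with a warning when the raw estimate
#' falls outside by more than 0.05.
#'
#' @param x numeric series, length at least `4 * k_max`.
#' @param params a [higuchi_params()].
#' @return fractal dimension in `[1, 2]`.
#' @export
#' @examples
#' higuchi_fd(cumsum(rnorm(512)))  # Brownian motion, about 1.5
higuchi_fd <- function(x, params = higuchi_params()) {
  n <- length(x)
  k_max <- params$k_max
  if (n < 4 * k_max)
    stop("series too short for k_max = ", k_max, call. = FALSE)
  ks <- seq_len(k_max)
  if (!is.null(params$fit_range)) ks <- intersect(ks, params$fit_range)
  lk <- vapply(ks, function(k) {
    lw <- vapply(seq_len(k), function(w) {
      m <- (n - w) %/% k
      if (m < 1) return(NA_real_)
      idx <- w + (0:m) * k
      sum(abs(diff(x[idx]))) * (n - 1) / (m * k)
    }, numeric(1))
    mean(lw, na.rm = TRUE) / k
  }, numeric(1))
  if (any(lk <= 0) || !all(is.finite(log(lk))))
    stop("constant or degenerate series: zero curve length", call. = FALSE)
  fd <- -unname(stats::coef(stats::lm(log(lk) ~ log(ks)))[2])
  if (fd < 1 - 0.05 || fd > 2 + 0.05)
    warning(sprintf("Higuchi FD %.3f outside [1, 2]; clamped", fd), call. = FALSE)
  clamp(fd, 1, 2)
}

#' Extract the per-epoch feature matrix
#'
#' Each channel of each epoch is decomposed by [vmd_decompose()] into K
#' modes (ascending center frequency); DE and HFD of every mode form the
#' features. Column order is deterministic: channel-major, mode-minor, DE
#' before HFD (`ch<c>_m<k>_de`, `ch<c>_m<k>_hfd`).
#'
#' @param epochs list of [epoch()] objects with equal channel count and fs.
#' @param vmd a [vmd_params()].
#' @param bands a [band_set()] for DE.
#' @param hig a [higuchi_params()].
#' @param de_source `"vmf"` (default) computes DE per mode; `"raw"`
#'   computes it from the raw channel signal instead (the DE column is
#'   then identical across a channel's modes).
#' @return a `feature_matrix`: list with `values` (epochs x features),
#'   `feature_index`, `labels`, `channel_groups`.
#' @export
extract_features <- function(epochs, vmd = vmd_params(), bands = band_set(),
                             hig = higuchi_params(),
                             de_source = c("vmf", "raw")) {
  de_source <- match.arg(de_source)
  stopifnot(length(epochs) >= 1)
  n_ch <- nrow(epochs[[1]]$data)
  fs <- epochs[[1]]$fs
  for (e in epochs)
    if (nrow(e$data) != n_ch || e$fs != fs)
      stop("all epochs must share channel count and sampling rate", call. = FALSE)

  k <- vmd$K
  n_feat <- n_ch * k * 2L
  values <- matrix(NA_real_, nrow = length(epochs), ncol = n_feat)
  fi <- data.frame(channel = rep(seq_len(n_ch), each = 2L * k),
                   mode = rep(rep(seq_len(k), each = 2L), n_ch),
                   feature = rep(c("de", "hfd"), n_ch * k))
  colnames(values) <- paste0("ch", fi$channel, "_m", fi$mode, "_", fi$feature)

  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    col <- 0L
    for (ch in seq_len(n_ch)) {
      res <- tryCatch(
        vmd_decompose(ep$data[ch, ], fs, vmd),
        error = function(e) stop("VMD failed at epoch ", i, ", channel ", ch,
                                 ": ", conditionMessage(e), call. = FALSE))
      for (m in seq_len(k)) {
        src <- if (de_source == "vmf") res$modes[m, ] else ep$data[ch, ]
        de <- suppressWarnings(differential_entropy(src, fs, bands))
        hfd <- suppressWarnings(higuchi_fd(res$modes[m, ], hig))
        values[i, col + 1L] <- de
        values[i, col + 2L] <- hfd
        col <- col + 2L
      }
    }
  }
  channel_groups <- split(seq_len(n_feat), fi$channel)
  names(channel_groups) <- paste0("ch", seq_len(n_ch))
  structure(list(values = values, feature_index = fi,
                 labels = epoch_labels(epochs),
                 channel_groups = channel_groups, fs = fs, K = k),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (%d channels x %d modes x 2)\n",
              nrow(x$values), ncol(x$values), length(x$channel_groups), x$K))
  cat("  labels:", sum(x$labels == 0), "interictal /", sum(x$labels == 1), "ictal\n")
  invisible(x)
}

#' Restrict a feature matrix to selected channels
#'
#' @param features a `feature_matrix`.
#' @param mask binary vector over channels (1 = keep).
#' @return numeric matrix of the retained columns.
#' @export
mask_columns <- function(features, mask) {
  stopifnot(inherits(features, "feature_matrix"),
            length(mask) == length(features$channel_groups))
  cols <- unlist(features$channel_groups[which(mask == 1)], use.names = FALSE)
  features$values[, cols, drop = FALSE]
}

#' Write a feature matrix to CSV
#'
#' Columns `ch<c>_m<k>_{de|hfd}` plus a final `label` column.
#'
#' @param features a `feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- as.data.frame(features$values)
  df$label <- features$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Inverse of [write_features_csv()]; channel/mode structure is recovered
#' from the column names.
#'
#' @param path CSV path.
#' @return a `feature_matrix`.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path)
  labels <- df$label
  df$label <- NULL
  m <- regmatches(names(df), regexec("^ch(\\d+)_m(\\d+)_(de|hfd)$", names(df)))
  if (any(vapply(m, length, 0L) != 4L))
    stop("unrecognised feature column names", call. = FALSE)
  fi <- data.frame(channel = as.integer(vapply(m, `[`, "", 2L)),
                   mode = as.integer(vapply(m, `[`, "", 3L)),
                   feature = vapply(m, `[`, "", 4L))
  channel_groups <- split(seq_len(ncol(df)), fi$channel)
  names(channel_groups) <- paste0("ch", sort(unique(fi$channel)))
  structure(list(values = as.matrix(df), feature_index = fi,
                 labels = as.integer(labels), channel_groups = channel_groups,
                 fs = NA_real_, K = max(fi$mode)),
            class = "feature_matrix")
}
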