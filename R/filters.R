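# Zero-phase IIR preprocessing. The Butterworth band-pass is designed from
# the analog prototype (zpk form) through the band transform and bilinear
# transform; filtering runs forward-backward with steady-state initial
# conditions and odd-reflection padding, so pass-band phase is exactly zero
# and edge transients are suppressed.

poly_from_roots <- function(r) {
  p <- as.complex(1)
  for (root in r) p <- c(p, 0) - c(0, p * root)
  p
}

#' Design a zero-phase Butterworth band-pass filter
#'
#' @param low_hz,high_hz pass-band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order analog prototype order (the band-pass has `2 * order` poles).
#' @return list with numerator `b` and denominator `a` coefficients.
#' @keywords internal
#' @export
butter_bandpass <- function(low_hz, high_hz, fs, order = 4L) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  n <- as.integer(order)
  fs2 <- 2                                   # normalised bilinear rate
  wn <- c(low_hz, high_hz) / (fs / 2)
  warped <- 2 * fs2 * tan(pi * wn / fs2)
  wo <- sqrt(prod(warped)); bw <- diff(warped)

  # analog Butterworth prototype poles on the unit circle
  k_idx <- seq_len(n)
  p <- exp(1i * pi * (2 * k_idx + n - 1) / (2 * n))

  # low-pass -> band-pass: n poles become 2n, n zeros at s = 0
  p_lp <- p * bw / 2
  p_bp <- c(p_lp + sqrt(p_lp^2 - wo^2), p_lp - sqrt(p_lp^2 - wo^2))
  z_bp <- rep(0 + 0i, n)
  k_bp <- bw^n

  # bilinear transform to the z-plane
  fs4 <- 2 * fs2
  z_d <- (fs4 + z_bp) / (fs4 - z_bp)
  p_d <- (fs4 + p_bp) / (fs4 - p_bp)
  k_d <- k_bp * Re(prod(fs4 - z_bp) / prod(fs4 - p_bp))
  z_d <- c(z_d, rep(-1 + 0i, length(p_bp) - length(z_bp)))

  b <- Re(poly_from_roots(z_d)) * k_d
  a <- Re(poly_from_roots(p_d))
  list(b = b, a = a)
}

#' Design a power-line notch filter
#'
#' Second-order IIR notch (constrained biquad) at `f0_hz` with quality
#' factor `q`.
#'
#' @param f0_hz notch frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param q quality factor; bandwidth is `f0_hz / q`.
#' @return list with `b` and `a` coefficients.
#' @keywords internal
#' @export
iir_notch <- function(f0_hz, fs, q = 30) {
  if (f0_hz <= 0 || f0_hz >= fs / 2)
    stop("notch frequency must lie inside (0, fs/2)", call. = FALSE)
  w0 <- 2 * pi * f0_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# steady-state initial state of the direct-form II transposed filter,
# scaled by the first input sample in filtfilt
lfilter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  if (n == 1) return(numeric(0))
  comp <- rbind(-a[-1], cbind(diag(1, n - 2), 0))   # companion matrix of a
  iminusa <- diag(1, n - 1) - t(comp)
  solve(iminusa, b[-1] - a[-1] * b[1])
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies the IIR filter `b`, `a` forward then backward with
#' odd-reflection padding and steady-state initial conditions, matching the
#' usual `filtfilt` contract: zero phase, squared magnitude response.
#'
#' @param b,a filter coefficients.
#' @param x numeric vector to filter.
#' @return filtered vector, same length as `x`.
#' @keywords internal
#' @export
filt_filt <- function(b, a, x) {
  n <- length(x)
  ntaps <- max(length(a), length(b))
  padlen <- min(3L * (ntaps - 1L), n - 1L)
  if (padlen > 0) {
    ext <- c(2 * x[1] - x[(padlen + 1):2],
             x,
             2 * x[n] - x[(n - 1):(n - padlen)])
  } else ext <- x
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b / a[1], a / a[1], ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter_cpp(b / a[1], a / a[1], y, zi * y[1])
  y <- rev(y)
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}

#' Band-pass and notch preprocessing of an EEG recording
#'
#' Applies a zero-phase 4th-order Butterworth band-pass (default 1-60 Hz,
#' where most scalp-EEG information lives) and an optional power-line notch
#' (default 60 Hz, the North American mains frequency used by CHB-MIT;
#' set 50 for European recordings or `NULL` to skip) to every channel.
#'
#' @param rec an [eeg_recording()].
#' @param band numeric length-2, pass-band edges in Hz.
#' @param notch_hz notch frequency in Hz, or `NULL` for none.
#' @param order Butterworth prototype order.
#' @return the filtered [eeg_recording()], same shape.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(1024), 1), fs = 256)
#' filtered <- preprocess(rec, band = c(1, 60), notch_hz = 60)
preprocess <- function(rec, band = c(1, 60), notch_hz = 60, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(band) != 2L || !(band[1] > 0 && band[1] < band[2] && band[2] < rec$fs / 2))
    stop("band must satisfy 0 < low < high < fs/2 (fs = ", rec$fs, ")", call. = FALSE)
  bp <- butter_bandpass(band[1], band[2], rec$fs, order = order)
  nt <- if (!is.null(notch_hz)) iir_notch(notch_hz, rec$fs) else NULL
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    y <- filt_filt(bp$b, bp$a, out[ch, ])
    if (!is.null(nt)) y <- filt_filt(nt$b, nt$a, y)
    out[ch, ] <- y
  }
  rec$data <- out
  rec
}

#' Cut a recording into labelled fixed-length epochs
#'
#' Non-overlapping consecutive windows, left-aligned to the start of each
#' annotated interval; windows that would straddle an interval boundary are
#' discarded. Interval semantics are half-open `[start_s, end_s)` with
#' 0-based sample indexing.
#'
#' @param rec an [eeg_recording()].
#' @param ann an [annotation_table()].
#' @param window_s window length in seconds; `window_s * fs` must be an
#'   integer.
#' @param source_id identifier stored on each epoch.
#' @return list of [epoch()] objects (empty if `ann` has no rows).
#' @export
segment <- function(rec, ann, window_s = 2, source_id = "rec") {
  stopifnot(inherits(rec, "eeg_recording"))
  nsamp <- window_s * rec$fs
  if (abs(nsamp - round(nsamp)) > 1e-9)
    stop("window_s * fs must be an integer number of samples", call. = FALSE)
  nsamp <- as.integer(round(nsamp))
  epochs <- list()
  idx <- 0L
  total <- ncol(rec$data)
  for (r in seq_len(nrow(ann))) {
    first <- as.integer(round(ann$start_s[r] * rec$fs))          # 0-based
    last <- min(as.integer(round(ann$end_s[r] * rec$fs)), total) # exclusive
    n_win <- max(0L, (last - first) %/% nsamp)
    for (w in seq_len(n_win)) {
      a <- first + (w - 1L) * nsamp
      idx <- idx + 1L
      epochs[[idx]] <- epoch(rec$data[, (a + 1L):(a + nsamp), drop = FALSE],
                             label = ann$label[r], fs = rec$fs,
                             source_id = source_id, index = idx)
    }
  }
  epochs
}
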