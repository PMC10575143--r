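test_that("EDF round trip preserves channels, rate and amplitudes", {
  rec <- test_recording(n_channels = 3, seconds = 4)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)

  expect_equal(nrow(back$data), 3)
  expect_equal(back$fs, 256)
  expect_equal(back$channel_labels, rec$channel_labels)
  # 16-bit quantisation over the observed range bounds the error
  qstep <- (max(rec$data) - min(rec$data)) / 65535
  expect_lt(max(abs(back$data - rec$data)), 2 * qstep)
})

test_that("a 23-channel 256 Hz file reads back with that geometry", {
  rec <- test_recording(n_channels = 23, seconds = 2)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(nrow(back$data), 23)
  expect_equal(back$fs, 256)
})

test_that("unreadable EDF files raise I/O errors", {
  expect_error(read_edf(file.path(tempdir(), "absent.edf")), "not found")
  rec <- test_recording(n_channels = 2, seconds = 2)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  full <- readBin(path, "raw", file.size(path))
  trunc_path <- withr::local_tempfile(fileext = ".edf")
  writeBin(full[1:300], trunc_path)               # cuts inside the header
  expect_error(read_edf(trunc_path), "truncated")
  trunc2 <- withr::local_tempfile(fileext = ".edf")
  writeBin(full[1:(length(full) - 64)], trunc2)   # cuts inside the records
  expect_error(read_edf(trunc2), "truncated")
})

test_that("band-pass keeps the passband and rejects out-of-band tones", {
  fs <- 256
  t <- (0:2047) / fs
  mk <- function(f) eeg_recording(matrix(sin(2 * pi * f * t), 1), fs)

  in_band <- preprocess(mk(10), band = c(1, 60), notch_hz = NULL)
  expect_equal(fft_amplitude(in_band$data[1, ], 10, fs), 1, tolerance = 0.01)

  out_band <- preprocess(mk(80), band = c(1, 60), notch_hz = NULL)
  atten_db <- 20 * log10(fft_amplitude(out_band$data[1, ], 80, fs))
  expect_lt(atten_db, -20)

  notched <- preprocess(mk(50), band = c(1, 60), notch_hz = 50)
  notch_db <- 20 * log10(fft_amplitude(notched$data[1, ], 50, fs))
  expect_lt(notch_db, -20)

  expect_identical(dim(in_band$data), dim(mk(10)$data))
  expect_error(preprocess(mk(10), band = c(1, 200)), "fs/2")
  expect_error(preprocess(mk(10), band = c(0, 60)), "fs/2")
})

test_that("preprocessing is idempotent on passband content", {
  fs <- 256
  t <- (0:(8 * fs - 1)) / fs
  # passband tones well inside 1-60 Hz
  x <- sin(2 * pi * 3 * t) + 0.8 * sin(2 * pi * 11 * t) +
    0.5 * sin(2 * pi * 25 * t)
  rec <- eeg_recording(matrix(x, 1), fs)
  once <- preprocess(rec, band = c(1, 60), notch_hz = 60)
  twice <- preprocess(once, band = c(1, 60), notch_hz = 60)
  for (f in c(3, 11, 25)) {
    a1 <- fft_amplitude(once$data[1, ], f, fs)
    a2 <- fft_amplitude(twice$data[1, ], f, fs)
    expect_equal(a2 / a1, 1, tolerance = 0.01)
  }
})

test_that("segmentation yields the epoch layout of a 200 s + 200 s record", {
  fs <- 256
  rec <- eeg_recording(matrix(rnorm(400 * fs), 1), fs)
  ann <- annotation_table(c(0, 200), c(200, 400), c(0, 1))
  eps <- segment(rec, ann, window_s = 2)
  labs <- vapply(eps, function(e) e$label, integer(1))
  expect_length(eps, 200)
  expect_equal(sum(labs == 0), 100)
  expect_equal(sum(labs == 1), 100)
})

test_that("segmentation floors to whole windows and handles empty input", {
  fs <- 128
  rec <- eeg_recording(matrix(rnorm(10 * fs), 1), fs)
  expect_length(segment(rec, annotation_table(0, 3, 1), window_s = 2), 1)
  expect_length(segment(rec, annotation_table(0, 1, 1), window_s = 2), 0)
  empty <- annotation_table(numeric(0), numeric(0), integer(0))
  expect_length(segment(rec, empty, window_s = 2), 0)
  expect_error(segment(rec, annotation_table(0, 3, 1), window_s = 1/3),
               "integer")
})

test_that("epochs partition each interval prefix without gap or overlap", {
  fs <- 64
  x <- seq_len(20 * fs)                 # sample index as the signal value
  rec <- eeg_recording(matrix(x, 1), fs)
  ann <- annotation_table(c(1, 11.5), c(8.2, 17), c(0, 1))
  eps <- segment(rec, ann, window_s = 2)
  for (r in seq_len(nrow(ann))) {
    first <- round(ann$start_s[r] * fs)  # 0-based
    in_int <- Filter(function(e)
      e$data[1, 1] > first & e$data[1, 1] <= round(ann$end_s[r] * fs), eps)
    got <- unlist(lapply(in_int, function(e) e$data[1, ]))
    n_win <- length(got) / (2 * fs)
    expect_identical(got, x[(first + 1):(first + n_win * 2 * fs)])
  }
})

test_that("annotation tables validate their invariants", {
  expect_error(annotation_table(5, 5, 1), "start_s < end_s")
  expect_error(annotation_table(c(0, 5), c(10, 15), c(1, 1)), "overlap")
  expect_error(annotation_table(0, 1, 2), "0 .*or 1")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("start_s,end_s,label\n0,10,0\n10,20,1", path)
  ann <- read_annotations(path)
  expect_s3_class(ann, "annotation_table")
  expect_equal(nrow(ann), 2)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_annotations(bad), "start_s")
})
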