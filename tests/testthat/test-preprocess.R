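sine_recording <- function(freq, fs = 10, dur_s = 400, amp = 1) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  make_recording(matrix(amp * sin(2 * pi * freq * t), nrow = 1), fs = fs)
}

test_that("band-pass removes DC and out-of-band components", {
  fs <- 10
  # DC
  rec <- make_recording(matrix(1, nrow = 1, ncol = 4000), fs = fs)
  out <- nirs_bandpass(rec)
  core <- out$data[1, 1001:3000]
  expect_lt(max(abs(core)), 0.01)
  # 0.1 Hz passband
  out1 <- nirs_bandpass(sine_recording(0.1))
  amp1 <- max(abs(out1$data[1, 1501:2500]))
  expect_gt(amp1, 0.9)
  expect_lt(amp1, 1.1)
  # 1 Hz stopband
  out2 <- nirs_bandpass(sine_recording(1))
  expect_lt(max(abs(out2$data[1, 1501:2500])), 0.1)
})

test_that("measured attenuation matches the analytic frequency response", {
  for (freq in c(0.05, 0.1, 0.2)) {
    out <- nirs_bandpass(sine_recording(freq))
    amp <- max(abs(out$data[1, 1501:2500]))
    expect_equal(amp, nirsnet:::bandpass_gain(freq, 10), tolerance = 0.02)
  }
})

test_that("filtering is linear", {
  set.seed(42)
  x <- matrix(rnorm(2000), nrow = 1)
  y <- matrix(rnorm(2000), nrow = 1)
  f <- function(m) nirs_bandpass(make_recording(m))$data
  lhs <- f(2 * x - 3 * y)
  rhs <- 2 * f(x) - 3 * f(y)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("band edge validation", {
  rec <- make_recording(matrix(rnorm(1000), nrow = 1))
  expect_error(nirs_bandpass(rec, low = 0), "band edges")
  expect_error(nirs_bandpass(rec, low = 0.4, high = 0.3), "band edges")
  expect_error(nirs_bandpass(rec, high = 6), "band edges")
  expect_error(nirs_bandpass(make_recording(matrix(1, 1, 10))), "too short")
})

test_that("segmentation aligns epochs on the marker onset", {
  data <- matrix(seq_len(300), nrow = 1)
  rec <- make_recording(data, markers = tibble::tibble(onset = 81L,
                                                       case = "win-win"))
  eps <- segment(rec, "win-win")
  expect_equal(dim(eps$epochs), c(1, 1, 130))
  # 2 s before the onset through 11 s after: samples 61..190
  expect_equal(as.numeric(eps$epochs[1, 1, ]), 61:190)
  # onset sits at sample pre_samples + 1
  expect_equal(unname(eps$epochs[1, 1, eps$pre_samples + 1]), 81)
})

test_that("one epoch per marker; boundary trials dropped with a warning", {
  onsets <- as.integer(seq(40, 850, by = 90))
  rec <- make_recording(matrix(rnorm(2000), nrow = 2, ncol = 1000),
                        markers = tibble::tibble(onset = onsets,
                                                 case = "lose-win"))
  eps <- segment(rec, "lose-win")
  expect_equal(dim(eps$epochs)[1], 10)
  # onset 5 leaves no room for the 2-s pre-stimulus window
  rec2 <- make_recording(matrix(rnorm(2000), nrow = 2, ncol = 1000),
                         markers = tibble::tibble(onset = c(5L, onsets),
                                                  case = "lose-win"))
  expect_warning(eps2 <- segment(rec2, "lose-win"), "boundary")
  expect_equal(dim(eps2$epochs)[1], 10)
  expect_error(segment(rec, "win-win"), "no markers")
})

test_that("normalization: degenerate and exact cases", {
  # constant signal: baseline SD is 0, scaling skipped, all zeros remain
  rec <- make_recording(matrix(5, nrow = 1, ncol = 400),
                        markers = tibble::tibble(onset = 100L,
                                                 case = "win-win"))
  eps <- normalize_and_average(segment(rec, "win-win"))
  expect_true(all(eps$epochs == 0))
  expect_true(all(eps$averaged == 0))

  # two identical epochs: average equals either normalized epoch
  x <- rnorm(1000)
  rec2 <- make_recording(matrix(c(x, x), nrow = 1, ncol = 2000),
                         markers = tibble::tibble(onset = c(300L, 1300L),
                                                  case = "win-win"))
  eps2 <- normalize_and_average(segment(rec2, "win-win"))
  expect_equal(eps2$averaged[1, ], eps2$epochs[1, 1, ])
  expect_equal(eps2$epochs[1, 1, ], eps2$epochs[2, 1, ])
})

test_that("averaged pre-stimulus mean is zero per channel", {
  cfg <- tiny_config()
  rec <- simulate_recording(cfg, "S01", "spontaneous")
  eps <- normalize_and_average(segment(nirs_bandpass(rec), "win-win"))
  pre <- seq_len(eps$pre_samples)
  expect_lt(max(abs(rowMeans(eps$averaged[, pre]))), 1e-10)
  # also with a constructed linear trend
  trend <- matrix(rep(seq_len(600), each = 2), nrow = 2, byrow = FALSE)
  rec2 <- make_recording(trend,
                         markers = tibble::tibble(onset = c(100L, 300L),
                                                  case = "lose-lose"))
  eps2 <- normalize_and_average(segment(rec2, "lose-lose"),
                                method = "baseline")
  expect_lt(max(abs(rowMeans(eps2$averaged[, seq_len(20)]))), 1e-10)
})
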