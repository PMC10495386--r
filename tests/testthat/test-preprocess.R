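test_that("low-pass filter preserves DC and attenuates tones as designed", {
  rate <- 1000
  expect_equal(lowpass_filter(rep(5, 500), rate), rep(5, 500))

  tone_gain <- function(f, spec = filter_spec()) {
    t <- seq(0, 20, by = 1 / rate)
    y <- lowpass_filter(sin(2 * pi * f * t), rate, spec)
    core <- seq(length(y) %/% 4, 3 * length(y) %/% 4)
    A <- cbind(sin(2 * pi * f * t[core]), cos(2 * pi * f * t[core]))
    sqrt(sum(qr.solve(A, y[core])^2))
  }
  # 0.5 Hz passes essentially unchanged; 30 Hz is crushed
  expect_equal(tone_gain(0.5), 1, tolerance = 0.01)
  expect_lt(tone_gain(30, filter_spec(zero_phase = FALSE)), 0.05)
  expect_equal(tone_gain(30), butterworth_gain(30, rate = rate),
               tolerance = 0.01)
})

test_that("filter configuration errors are caught", {
  expect_error(lowpass_filter(rnorm(100), 10, filter_spec(cutoff_hz = 6)),
               "Nyquist")
  expect_error(lowpass_filter(c(1, 2, 3), 1000), "too short")
  expect_error(filter_spec(cutoff_hz = 0), "positive")
})

test_that("zero-phase filtering introduces no lag", {
  rate <- 1000
  t <- seq(0, 10, by = 1 / rate)
  x <- sin(2 * pi * 1.5 * t) + 0.5 * sin(2 * pi * 3 * t)
  y <- lowpass_filter(x, rate)
  cc <- ccf(y, x, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("tone gain never exceeds unity and DC filtering is idempotent", {
  rate <- 200
  t <- seq(0, 30, by = 1 / rate)
  for (f in c(0.2, 1, 3, 6, 12)) {
    y <- lowpass_filter(sin(2 * pi * f * t), rate)
    core <- seq(length(y) %/% 4, 3 * length(y) %/% 4)
    expect_lte(max(abs(y[core])), 1 + 1e-6)
  }
  dc <- rep(2.5, 400)
  expect_equal(lowpass_filter(lowpass_filter(dc, rate), rate), dc)
})

test_that("filter_with_gaps leaves NA spans alone and filters the rest", {
  rate <- 60
  x <- c(rep(4, 100), rep(NA, 20), rep(7, 100))
  y <- filter_with_gaps(x, rate)
  expect_true(all(is.na(y[101:120])))
  expect_equal(y[1:100], rep(4, 100))
  expect_equal(y[121:220], rep(7, 100))
})

test_that("resampling preserves constants, identity and duration", {
  x <- rep(3, 120)
  y <- resample_series(x, 60, 1000)
  expect_equal(length(y), round(120 * 1000 / 60), tolerance = 1)
  # polyphase FIR passband ripple bounds the DC error
  expect_equal(y[100:(length(y) - 100)], rep(3, length(y) - 199),
               tolerance = 1e-3)
  expect_identical(resample_series(x, 60, 60), x)
  expect_error(resample_series(1, 60, 1000), "2 samples")
})

test_that("band-limited upsampling reconstructs a 2 Hz tone within 2% RMS", {
  t60 <- seq(0, 10, by = 1 / 60)
  x <- sin(2 * pi * 2 * t60)
  y <- resample_series(x, 60, 1000)
  t1000 <- (seq_along(y) - 1) / 1000
  ref <- sin(2 * pi * 2 * t1000)
  core <- seq(500, length(y) - 500)
  expect_lt(sqrt(mean((y[core] - ref[core])^2)), 0.02)
})

test_that("gap-aware resampling interpolates linearly and keeps gaps", {
  x <- c(0, 1, 2, NA, 4, 5)
  y <- resample_with_gaps(x, 1, 2)
  expect_equal(y[1:5], c(0, 0.5, 1, 1.5, 2))
  expect_true(is.na(y[6]) && is.na(y[7]) && is.na(y[8]))
  expect_equal(y[9:11], c(4, 4.5, 5))
})

test_that("cropping to anchors honours the closed interval and tolerance", {
  g <- tiny_grid()
  ts <- seq(0, by = 17, length.out = 60)
  rec <- insole_recording(g, ts, matrix(10, 60, 9))
  full <- crop_to_anchors(rec, sync_anchor(ts[1], ts[60]))
  expect_equal(full$timestamp_ms, rec$timestamp_ms)

  inner <- crop_to_anchors(rec, sync_anchor(ts[10], ts[20]))
  expect_equal(length(inner$timestamp_ms), 11)
  expect_equal(inner$timestamp_ms[1], ts[10])

  # idempotence
  again <- crop_to_anchors(inner, sync_anchor(ts[10], ts[20]))
  expect_equal(again$timestamp_ms, inner$timestamp_ms)

  # nearest-match within tolerance, with a logged offset
  expect_message(
    near <- crop_to_anchors(rec, sync_anchor(ts[10] + 5, ts[20])),
    "offset"
  )
  expect_equal(near$timestamp_ms[1], ts[10])

  expect_error(crop_to_anchors(rec, sync_anchor(ts[60] + 1000, ts[60] + 2000)),
               "does not overlap")
  expect_error(crop_to_anchors(rec, sync_anchor(ts[10] + 8, ts[20]),
                               tolerance_ms = 5), "no frame timestamp")
})

test_that("synchronized noiseless pairs agree and misdurations error", {
  cfg <- noiseless_config(seed = 9, vgrf_scale_bias = 1, cop_ml_shrink = 1,
                          n_cycles = 5)
  tr <- simulate_trial("squat", cfg)
  sy <- synchronize_pair(tr$insole, tr$plate, tr$anchor, activity = "squat")
  expect_equal(nrow(sy$insole), nrow(sy$plate))
  peak <- max(sy$plate$vgrf_n)
  core <- seq(200, nrow(sy$insole) - 200)
  rms <- sqrt(mean((sy$insole$vgrf_n[core] - sy$plate$vgrf_n[core])^2))
  expect_lt(rms / peak, 0.01)
  # cross-correlation peak at zero lag (+/- 2 samples)
  cc <- ccf(sy$insole$vgrf_n, sy$plate$vgrf_n, lag.max = 30, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 2)

  short_plate <- force_plate_recording(tr$plate$vgrf_n[1:1000],
                                       tr$plate$cop_ml_cm[1:1000],
                                       tr$plate$cop_ap_cm[1:1000])
  expect_error(synchronize_pair(tr$insole, short_plate, tr$anchor),
               "differs from anchor window")
})
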