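test_that("frame_channels computes load, peak pressure and COP from one frame", {
  g <- sensel_grid(c(2, 5), c(10, 20), c(1, 1), side = "right")
  # single loaded sensel: 100 kPa over 1 cm^2 = 1e5 Pa x 1e-4 m^2 = 10 N
  fc <- frame_channels(c(100, 0), g, load_floor_n = 0)
  expect_equal(fc$vgrf_n, 10)
  expect_equal(fc$peak_pressure_kpa, 100)
  expect_equal(fc$cop_ml_cm, 2)
  expect_equal(fc$cop_ap_cm, 10)

  # uniform pressure over 235 sensels of 1 cm^2: vGRF = 235 N,
  # COP at the grid centroid
  lat <- expand.grid(x = 1:10, z = 1:24)[1:235, ]
  g235 <- sensel_grid(lat$x, lat$z, rep(1, 235), side = "right")
  fc2 <- frame_channels(rep(10, 235), g235)
  expect_equal(fc2$vgrf_n, 235)
  expect_equal(fc2$cop_ml_cm, mean(g235$x_cm))
  expect_equal(fc2$cop_ap_cm, mean(g235$z_cm))

  # no load: COP undefined
  fc3 <- frame_channels(rep(0, 235), g235)
  expect_equal(fc3$vgrf_n, 0)
  expect_true(is.na(fc3$cop_ml_cm) && is.na(fc3$cop_ap_cm))

  expect_error(frame_channels(1:4, g), "sensels")
})

test_that("vGRF equals the sum of per-sensel loads (conservation)", {
  set.seed(71)
  g <- default_sensel_grid("right")
  p <- runif(235, 0, 400)
  fc <- frame_channels(p, g)
  oracle <- sum(p * 1000 * g$area_cm2 * 1e-4)
  expect_equal(fc$vgrf_n, oracle, tolerance = 1e-9)
})

test_that("COP is scale-invariant and translation-equivariant", {
  set.seed(72)
  g <- tiny_grid()
  p <- runif(9, 10, 100)
  fc <- frame_channels(p, g, load_floor_n = 0)
  fc_scaled <- frame_channels(3 * p, g, load_floor_n = 0)
  expect_equal(fc_scaled$vgrf_n, 3 * fc$vgrf_n)
  expect_equal(fc_scaled$cop_ml_cm, fc$cop_ml_cm)
  expect_equal(fc_scaled$cop_ap_cm, fc$cop_ap_cm)

  g2 <- sensel_grid(g$x_cm + 1.5, g$z_cm - 2.25, g$area_cm2, side = "right")
  fc_shift <- frame_channels(p, g2, load_floor_n = 0)
  expect_equal(fc_shift$cop_ml_cm, fc$cop_ml_cm + 1.5)
  expect_equal(fc_shift$cop_ap_cm, fc$cop_ap_cm - 2.25)
})

test_that("COP lies within the hull of loaded sensels", {
  set.seed(73)
  g <- default_sensel_grid("right")
  for (i in 1:20) {
    p <- rexp(235, 1 / 50)
    fc <- frame_channels(p, g)
    loaded <- p > 0
    expect_gte(fc$cop_ml_cm, min(g$x_cm[loaded]))
    expect_lte(fc$cop_ml_cm, max(g$x_cm[loaded]))
    expect_gte(fc$cop_ap_cm, min(g$z_cm[loaded]))
    expect_lte(fc$cop_ap_cm, max(g$z_cm[loaded]))
  }
})

test_that("insole recordings validate pressures and timestamps", {
  g <- tiny_grid()
  p <- matrix(10, nrow = 2, ncol = 9)
  expect_error(insole_recording(g, c(0, 0), p), "strictly increasing")
  p_neg <- p; p_neg[1, 1] <- -1
  expect_error(insole_recording(g, c(0, 17), p_neg), "non-negative")
  p_hot <- p; p_hot[2, 3] <- 950
  expect_warning(rec <- insole_recording(g, c(0, 17), p_hot), "clamped")
  expect_equal(max(rec$pressure_kpa), 883)
})

test_that("derive_channels is time-invariant on identical frames", {
  g <- tiny_grid()
  p <- matrix(rep(runif(9, 20, 80), each = 10), nrow = 10)
  rec <- insole_recording(g, seq(0, by = 17, length.out = 10), p)
  ch <- derive_channels(rec, load_floor_n = 0)
  expect_equal(diff(range(ch$vgrf_n)), 0)
  expect_equal(diff(range(ch$cop_ml_cm)), 0)
  expect_equal(ch$t_s[1], 0)
})

test_that("left and right mirrored grids agree after ML canonicalization", {
  gr <- tiny_grid("right")
  refl <- min(gr$x_cm) + max(gr$x_cm)
  gl <- sensel_grid(refl - gr$x_cm, gr$z_cm, gr$area_cm2, side = "left")
  p <- matrix(c(50, 100, 30, 5, 80, 20, 10, 60, 40), nrow = 1)
  ch_r <- derive_channels(insole_recording(gr, 1, p), load_floor_n = 0)
  ch_l <- derive_channels(insole_recording(gl, 1, p), load_floor_n = 0)
  expect_equal(ch_l$cop_ml_cm, ch_r$cop_ml_cm)
  expect_equal(ch_l$cop_ap_cm, ch_r$cop_ap_cm)
  expect_equal(ch_l$vgrf_n, ch_r$vgrf_n)
})

test_that("vGRF is linear in a uniform pressure ramp", {
  g <- tiny_grid()
  ramp <- seq(10, 100, length.out = 10)
  p <- matrix(rep(ramp, 9), nrow = 10)
  rec <- insole_recording(g, seq(0, by = 17, length.out = 10), p)
  ch <- derive_channels(rec, load_floor_n = 0)
  fit <- lm(ch$vgrf_n ~ ramp)
  expect_equal(unname(residuals(fit)), rep(0, 10), tolerance = 1e-10)
})

test_that("insole and channel CSVs round-trip", {
  g <- tiny_grid()
  p <- matrix(runif(27, 0, 100), nrow = 3)
  rec <- insole_recording(g, c(0, 17, 33), p)
  f <- withr::local_tempfile(fileext = ".csv")
  write_insole_csv(rec, f)
  rec2 <- read_insole_csv(f, g)
  expect_equal(rec2$pressure_kpa, rec$pressure_kpa, ignore_attr = TRUE)
  expect_equal(rec2$timestamp_ms, rec$timestamp_ms)

  ch <- derive_channels(rec, load_floor_n = 1e9) # force undefined COP
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_channels_csv(ch, f2)
  ch2 <- read_channels_csv(f2)
  expect_true(all(is.na(ch2$cop_ml_cm)))
  expect_equal(ch2$vgrf_n, ch$vgrf_n)
})
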