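test_that("truth waveforms satisfy their structural invariants", {
  cfg <- noiseless_config(seed = 51, n_cycles = 8)
  for (act in ACTIVITIES) {
    tw <- make_truth_waveform(act, cfg)
    expect_true(all(tw$vgrf_n >= 0))
    expect_true(all(diff(tw$cycle_marks) > 0))
    expect_equal(length(tw$cycle_marks), 9) # n_cycles + 1 boundaries
  }
  expect_error(make_truth_waveform("squat", noiseless_config(n_cycles = 2)),
               "n_cycles >= 3")
  expect_error(make_truth_waveform("crawl", cfg), "should be one of")
})

test_that("jump flight spans carry exactly zero force and undefined COP", {
  tw <- make_truth_waveform("jump", noiseless_config(seed = 52))
  flight <- tw$vgrf_n == 0
  expect_gt(sum(flight), 0)
  expect_true(all(is.na(tw$cop_ml_cm[flight])))
  expect_true(all(is.na(tw$cop_ap_cm[flight])))
  # flight fraction below the per-cycle COP gap budget
  expect_lt(mean(flight), 0.2)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 53)
  t1 <- simulate_trial("squat", cfg)
  t2 <- simulate_trial("squat", cfg)
  expect_identical(t1$insole$pressure_kpa, t2$insole$pressure_kpa)
  expect_identical(t1$plate$vgrf_n, t2$plate$vgrf_n)
  expect_identical(simulate_paired(20, 1, 1, seed = 7)$a,
                   simulate_paired(20, 1, 1, seed = 7)$a)
  expect_identical(simulate_test_retest(10, 2, seed = 8),
                   simulate_test_retest(10, 2, seed = 8))
})

test_that("noise-free plate rendering equals the decimated truth", {
  cfg <- noiseless_config(seed = 54)
  tw <- make_truth_waveform("walk", cfg)
  pl <- render_plate(tw, cfg)
  tp <- truth_at_plate_rate(tw)
  expect_equal(pl$vgrf_n, tp$vgrf, tolerance = 1e-12)
})

test_that("plate noise has the configured magnitude", {
  cfg <- simulation_config(seed = 55, n_cycles = 8, noise_sd_plate_n = 5,
                           noise_sd_cop_cm = 0)
  tw <- make_truth_waveform("squat", cfg) # 16 s of signal, load well above zero
  pl <- render_plate(tw, cfg)
  resid <- pl$vgrf_n - truth_at_plate_rate(tw)$vgrf
  expect_gt(sd(resid), 4)
  expect_lt(sd(resid), 6)
})

test_that("insole rendering inverts through derive_channels (no bias, no noise)", {
  cfg <- noiseless_config(seed = 56, vgrf_scale_bias = 1, cop_ml_shrink = 1)
  for (act in c("squat", "jump", "walk")) {
    tr <- simulate_trial(act, cfg)
    ch <- derive_channels(tr$insole)
    n <- nrow(ch)
    tv <- resample_with_gaps(tr$truth$vgrf_n, 2000, 60)[1:n]
    tml <- resample_with_gaps(tr$truth$cop_ml_cm, 2000, 60)[1:n]
    tap <- resample_with_gaps(tr$truth$cop_ap_cm, 2000, 60)[1:n]
    expect_lt(sqrt(mean((ch$vgrf_n - tv)^2)) / max(tv), 0.01)
    ok <- is.finite(ch$cop_ml_cm) & is.finite(tml)
    expect_lt(sqrt(mean((ch$cop_ml_cm[ok] - tml[ok])^2)), 0.2)
    expect_lt(sqrt(mean((ch$cop_ap_cm[ok] - tap[ok])^2)), 0.2)
  }
})

test_that("configured insole biases are recovered from the rendering", {
  cfg <- noiseless_config(seed = 57, vgrf_scale_bias = 0.85, cop_ml_shrink = 0.6)
  tr <- simulate_trial("squat", cfg)
  ch <- derive_channels(tr$insole)
  n <- nrow(ch)
  tv <- resample_with_gaps(tr$truth$vgrf_n, 2000, 60)[1:n]
  ratio <- ch$vgrf_n / tv
  expect_lt(abs(mean(ratio) - 0.85), 0.02)

  tml <- resample_with_gaps(tr$truth$cop_ml_cm, 2000, 60)[1:n]
  shrink <- diff(range(ch$cop_ml_cm, na.rm = TRUE)) / diff(range(tml, na.rm = TRUE))
  expect_lt(abs(shrink / 0.6 - 1), 0.1)
})

test_that("test-retest simulation matches its variance-component metadata", {
  m0 <- simulate_test_retest(50, 2, var_between = 4, var_within = 0, seed = 58)
  expect_equal(attr(m0, "true_icc"), 1)
  expect_equal(icc_consistency(m0)$icc, 1)

  m_half <- simulate_test_retest(10, 2, var_between = 2, var_within = 2, seed = 59)
  expect_equal(attr(m_half, "true_icc"), 0.5)

  m_null <- simulate_test_retest(1000, 2, var_between = 0, var_within = 1, seed = 60)
  expect_lt(abs(suppressWarnings(icc_consistency(m_null)$icc)), 0.1)
})

test_that("paired simulation honours its bias and noise parameters", {
  ps0 <- simulate_paired(30, bias = -4, sd = 0, seed = 61)
  expect_equal(ps0$a - ps0$b, rep(-4, 30))
  ps <- simulate_paired(500, bias = -4, sd = 2, seed = 62)
  expect_lt(abs(mean(ps$a - ps$b) + 4), 3 * 2 / sqrt(500))
})

test_that("trial files round-trip through the plain-text formats", {
  cfg <- simulation_config(seed = 63, n_cycles = 3)
  tr <- simulate_trial("squat", cfg)
  dir <- withr::local_tempdir()
  paths <- write_trial_files(tr, dir)
  expect_true(all(file.exists(paths)))
  grid <- read_grid_csv(paths["grid"])
  ins <- read_insole_csv(paths["insole"], grid)
  expect_equal(ins$pressure_kpa, tr$insole$pressure_kpa,
               ignore_attr = TRUE, tolerance = 1e-6)
  pl <- read_plate_csv(paths["plate"])
  expect_equal(pl$vgrf_n, tr$plate$vgrf_n, tolerance = 1e-6)
  an <- read_anchor_csv(paths["anchor"])
  expect_equal(an$start_ms, tr$anchor$start_ms)
  truth_meta <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth_meta$cycle_marks, tr$truth$cycle_marks)
})
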