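test_that("extrema of a pure sinusoid are found at the analytic positions", {
  rate <- 100
  t <- seq(0, 5, by = 1 / rate) # 5 full periods at 1 Hz
  x <- sin(2 * pi * t)
  ex <- find_local_extrema(x, rate)
  expect_equal(length(ex$maxima), 5)
  expect_equal(length(ex$minima), 5)
  expect_equal(ex$maxima, round((0:4 + 0.25) * rate) + 1, tolerance = 1)
  expect_equal(diff(ex$maxima), rep(rate, 4), tolerance = 1)
})

test_that("a monotone ramp has no interior extrema", {
  ex <- find_local_extrema(seq(0, 1, length.out = 200), 100)
  expect_length(ex$maxima, 0)
  expect_length(ex$minima, 0)
})

test_that("low-prominence ripple is suppressed", {
  rate <- 100
  t <- seq(0, 5, by = 1 / rate)
  x <- sin(2 * pi * t) + 0.05 * sin(2 * pi * 11 * t) # ripple ~5% of range
  ex <- find_local_extrema(x, rate, min_prominence = 0.1)
  expect_equal(length(ex$maxima), 5)
  expect_equal(length(ex$minima), 5)
})

test_that("plateau extrema resolve to the plateau midpoint", {
  x <- c(0, 0, 5, 5, 5, 5, 0, 0)
  ex <- find_local_extrema(x, 1, min_separation_s = 0)
  expect_equal(ex$maxima, 4L) # floor midpoint of samples 3..6
})

test_that("cycle detection respects activity polarity and the one-opposite rule", {
  rate <- 100
  t <- seq(0, 8.6, by = 1 / rate) # 8 full dips plus margins
  dips <- 600 - 100 * sin(pi * t)^2 # squat-like: boundaries at maxima
  b_squat <- detect_cycles(dips, "squat", rate)
  expect_equal(nrow(b_squat), 7) # 8 interior boundary maxima
  b_walk <- detect_cycles(-dips + 700, "walk", rate)
  expect_equal(nrow(b_walk), 7) # polarity duality under negation
  expect_equal(b_walk$start_idx, b_squat$start_idx)
  expect_error(detect_cycles(rep(5, 500), "walk", rate), "segmentation failed")
})

test_that("cycle bounds are shift-equivariant", {
  rate <- 100
  t <- seq(0, 8.6, by = 1 / rate)
  x <- 600 - 100 * sin(pi * t)^2
  b0 <- detect_cycles(x, "squat", rate)
  s <- 37
  b1 <- detect_cycles(c(rep(x[1], s), x), "squat", rate)
  expect_equal(b1$start_idx, b0$start_idx + s)
  expect_equal(b1$end_idx, b0$end_idx + s)
})

test_that("edge-cycle trimming drops exactly the first and last cycles", {
  mk <- function(n) data.frame(start_idx = seq_len(n), end_idx = seq_len(n) + 1)
  expect_equal(nrow(trim_edge_cycles(mk(8))), 6)
  expect_equal(trim_edge_cycles(mk(8))$start_idx, 2:7)
  expect_equal(nrow(trim_edge_cycles(mk(3))), 1)
  expect_warning(out <- trim_edge_cycles(mk(2)), "fewer than 3")
  expect_equal(nrow(out), 0)
})

test_that("time normalization hits 101 points with exact endpoints", {
  ch <- derived_channels(
    t_s = seq(0, 1, length.out = 1001),
    vgrf_n = seq(100, 300, length.out = 1001),
    cop_ml_cm = rep(2, 1001), cop_ap_cm = rep(3, 1001)
  )
  cy <- normalize_cycle(ch, 1, 1001)
  expect_equal(nrow(cy), 101)
  expect_equal(cy$vgrf_n[1], 100)
  expect_equal(cy$vgrf_n[101], 300)
  expect_equal(cy$vgrf_n, seq(100, 300, length.out = 101)) # linear preserved

  # identity grid: a 101-sample segment passes through unchanged
  ch101 <- derived_channels(
    t_s = seq_len(101), vgrf_n = runif(101, 0, 10) + 1,
    cop_ml_cm = runif(101), cop_ap_cm = runif(101)
  )
  cy101 <- normalize_cycle(ch101, 1, 101)
  expect_equal(cy101$vgrf_n, ch101$vgrf_n)

  # half-sine reference: interpolation error below 0.1%
  n <- 1000
  hs <- sin(pi * seq(0, 1, length.out = n))
  chs <- derived_channels(t_s = seq_len(n), vgrf_n = hs + 1,
                          cop_ml_cm = hs, cop_ap_cm = hs)
  cys <- normalize_cycle(chs, 1, n)
  ref <- sin(pi * seq(0, 1, length.out = 101))
  expect_lt(max(abs(cys$cop_ml_cm - ref)), 1e-3)
})

test_that("undefined COP spans flag the cycle when they exceed the gap budget", {
  v <- rep(1, 100)
  cop <- v
  cop[40:70] <- NA # 31% undefined
  ch <- derived_channels(t_s = seq_len(100), vgrf_n = v * 100,
                         cop_ml_cm = cop, cop_ap_cm = v)
  cy <- normalize_cycle(ch, 1, 100, max_gap_fraction = 0.2)
  ok <- attr(cy, "channel_ok")
  expect_false(ok[["cop_ml_cm"]])
  expect_true(ok[["cop_ap_cm"]])
  expect_true(any(is.na(cy$cop_ml_cm)))
  cy2 <- normalize_cycle(ch, 1, 100, max_gap_fraction = 0.5)
  expect_true(attr(cy2, "channel_ok")[["cop_ml_cm"]])
})

test_that("cycle_range is max minus min over defined samples", {
  ch <- derived_channels(t_s = seq_len(101), vgrf_n = rep(7, 101),
                         cop_ml_cm = sin(2 * pi * seq(0, 1, length.out = 101)) * 3,
                         cop_ap_cm = rep(NA_real_, 101))
  cy <- normalize_cycle(ch, 1, 101)
  expect_equal(cycle_range(cy, "vgrf_n"), 0)
  expect_equal(cycle_range(cy, "cop_ml_cm"), 6, tolerance = 1e-3)
  expect_true(is.na(cycle_range(cy, "cop_ap_cm")))
  expect_error(cycle_range(cy, "nope"), "not present")

  ch5 <- derived_channels(t_s = 1:5, vgrf_n = c(1, 2, 3, 4, 5),
                          cop_ml_cm = 1:5, cop_ap_cm = 1:5)
  expect_equal(cycle_range(normalize_cycle(ch5, 1, 5), "vgrf_n"), 4)
})

test_that("cycle averaging returns pointwise mean and sd", {
  base <- sin(pi * seq(0, 1, length.out = 101))
  mk <- function(y) {
    ch <- derived_channels(t_s = seq_len(101), vgrf_n = y + 2,
                           cop_ml_cm = y, cop_ap_cm = y)
    normalize_cycle(ch, 1, 101)
  }
  one <- average_cycles(list(mk(base)))
  expect_equal(one$mean$cop_ml_cm, base)
  expect_equal(one$sd$cop_ml_cm, rep(0, 101))

  # two mirror-image cycles around a constant average to the constant
  two <- average_cycles(list(mk(1 + base), mk(1 - base)))
  expect_equal(two$mean$cop_ml_cm, rep(1, 101))

  same <- average_cycles(list(mk(base), mk(base), mk(base)))
  expect_equal(same$sd$cop_ml_cm, rep(0, 101))
  expect_error(average_cycles(list()), "no cycles")
})

test_that("participant outcomes average per-cycle ranges", {
  rate <- 100
  t <- seq(0, 8.6, by = 1 / rate)
  v <- 600 - 100 * sin(pi * t)^2
  ch <- derived_channels(t_s = t, vgrf_n = v,
                         cop_ml_cm = 2 + 0.5 * sin(pi * t)^2,
                         cop_ap_cm = 10 + 3 * sin(pi * t)^2, rate = rate)
  out <- participant_outcomes(ch, "squat", rate)
  expect_equal(unname(out$ranges["vgrf_n"]), 100, tolerance = 1e-3)
  expect_equal(unname(out$ranges["cop_ap_cm"]), 3, tolerance = 1e-3)
  expect_equal(unname(out$n_cycles_used["vgrf_n"]), 5) # 7 detected, trim 2
})

test_that("detection on generator truth matches the true marks exactly", {
  for (act in c("squat", "jump", "walk")) {
    cfg <- noiseless_config(seed = 21, n_cycles = 6)
    truth <- make_truth_waveform(act, cfg)
    tp <- truth_at_plate_rate(truth)
    b <- suppressMessages(detect_cycles(tp$vgrf, act, 1000))
    expect_equal(nrow(b), 5) # c - 1
    expect_equal(nrow(trim_edge_cycles(b)), 3) # c - 3
    expect_lte(max(abs(attr(b, "boundary_idx") - tp$marks[-1])), 2)
  }
})
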