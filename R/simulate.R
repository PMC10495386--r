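#' Simulation configuration
#'
#' Parameters of the synthetic ground-truth generator and its two
#' renderers. The defaults emulate the validation-study conditions:
#' a 60 Hz full-surface pressure insole and a 1000 Hz force plate
#' observing the same movement, with the insole under-reading vGRF by a
#' multiplicative factor and compressing medial-lateral COP excursions.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_cycles Number of movement cycles per trial (default 8, the
#'   repetition count used for squats and jumps).
#' @param cadence_hz Cycle rate, Hz; `NULL` picks a per-activity
#'   default (squat 0.5, jump 0.4, sit-to-stand 0.5, walk 0.8,
#'   stairs 0.625).
#' @param body_weight_n Body weight, N (default 700).
#' @param vgrf_scale_bias Multiplicative insole vGRF bias (default
#'   0.85, i.e. the insole under-reads force by 15%).
#' @param cop_ml_shrink Multiplicative shrinkage of insole COP-ML
#'   excursions about the grid midline (default 0.6).
#' @param noise_sd_plate_n Additive white-noise SD on plate vGRF, N.
#' @param noise_sd_cop_cm Additive white-noise SD on plate COP, cm.
#' @param noise_sd_insole_kpa Additive per-sensel pressure noise SD, kPa.
#' @param blob_sd_cm SD of the Gaussian pressure footprint, cm
#'   (default 1.2: pressure concentrates under the heel and metatarsal
#'   heads, and a footprint much wider than this is visibly truncated
#'   at the insole edge, biasing the recovered COP toward the midline).
#' @param master_rate_hz Ground-truth sampling rate, Hz (default 2000,
#'   above both device rates so each rendering is a downsampling).
#' @param insole_rate_hz,plate_rate_hz Device rates, Hz.
#' @param cop_center_cm Length-2 `(ml, ap)` centre of the COP
#'   trajectories, cm, in the canonical (right-foot) grid frame.
#' @param epoch_ms Timestamp of the first insole frame, ms.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_cycles = 8L, cadence_hz = NULL,
                              body_weight_n = 700,
                              vgrf_scale_bias = 0.85, cop_ml_shrink = 0.6,
                              noise_sd_plate_n = 2, noise_sd_cop_cm = 0.05,
                              noise_sd_insole_kpa = 0.5,
                              blob_sd_cm = 1.2, master_rate_hz = 2000,
                              insole_rate_hz = 60, plate_rate_hz = 1000,
                              cop_center_cm = c(5, 13),
                              epoch_ms = 1e6) {
  if (vgrf_scale_bias <= 0 || vgrf_scale_bias > 1.5) {
    stop("vgrf_scale_bias must be in (0, 1.5]", call. = FALSE)
  }
  if (any(c(noise_sd_plate_n, noise_sd_cop_cm, noise_sd_insole_kpa) < 0)) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_cycles = n_cycles, cadence_hz = cadence_hz,
         body_weight_n = body_weight_n,
         vgrf_scale_bias = vgrf_scale_bias, cop_ml_shrink = cop_ml_shrink,
         noise_sd_plate_n = noise_sd_plate_n, noise_sd_cop_cm = noise_sd_cop_cm,
         noise_sd_insole_kpa = noise_sd_insole_kpa,
         blob_sd_cm = blob_sd_cm, master_rate_hz = master_rate_hz,
         insole_rate_hz = insole_rate_hz, plate_rate_hz = plate_rate_hz,
         cop_center_cm = cop_center_cm, epoch_ms = epoch_ms),
    class = "simulation_config"
  )
}

# Per-activity waveform parameters, scaled to body weight (single foot).
# Gait stance profiles are symmetric about mid-stance so that cycle
# boundaries (swing/flight midpoints) stay put under zero-phase
# filtering.
.activity_profile <- function(activity, bw) {
  switch(
    activity,
    squat = list(cadence = 0.5, base = bw / 2, depth = 0.5,
                 ap_amp = 6.5, ml_amp = 1.2),
    sit_to_stand = list(cadence = 0.5, low = 0.10 * bw, high = 0.45 * bw,
                        ap_amp = 6, ml_amp = 1.5),
    jump = list(cadence = 0.4, amp = 0.8 * bw, stance_frac = 0.85,
                ap_range = 10, ml_amp = 1.6),
    walk = list(cadence = 0.8, amp = 0.8 * bw, stance_frac = 0.65,
                second_bump = 0.08, ap_range = 12, ml_amp = 3.2),
    stair_ascent = list(cadence = 0.625, amp = 0.75 * bw, stance_frac = 0.7,
                        second_bump = 0.05, ap_range = 8, ml_amp = 2.6),
    stair_descent = list(cadence = 0.625, amp = 0.85 * bw, stance_frac = 0.7,
                         second_bump = 0.05, ap_range = 7.5, ml_amp = 2.9),
    stop("unknown activity `", activity, "`", call. = FALSE)
  )
}

#' Ground-truth activity waveform
#'
#' Deterministically constructs a noise-free single-foot vGRF + COP
#' waveform for one activity at the master rate, with the true cycle
#' boundaries recorded as sample indices. Shapes follow the defining
#' features of each activity: squats dip below the standing load
#' (cycle boundaries at load maxima); jumps are stance bumps separated
#' by exact-zero flight spans; walking and stair ambulation are
#' double-bump stance profiles separated by zero-load swing; the
#' sit-to-stand test alternates a seated low load with a standing high
#' load (boundaries at load minima for all of these). COP channels are
#' `NA` wherever the foot is unloaded.
#'
#' The waveform runs from the first cycle boundary through the last
#' plus a half-cycle margin, so every boundary except the very first
#' is a detectable interior extremum: an ideal detector finds
#' `n_cycles + 1` true marks, `n_cycles` usable boundaries, hence
#' `n_cycles - 1` cycles, and edge trimming retains `n_cycles - 3`.
#'
#' @param activity See [activity_polarity()].
#' @param cfg A [simulation_config()].
#' @return A list of class `truth_waveform`: `t_s`, `vgrf_n`,
#'   `cop_ml_cm`, `cop_ap_cm`, `cycle_marks` (1-based indices of the
#'   `n_cycles + 1` boundary extrema), `rate`, `activity`, `profile`.
#' @export
make_truth_waveform <- function(activity, cfg = simulation_config()) {
  activity <- match.arg(activity, ACTIVITIES)
  if (cfg$n_cycles < 3) stop("need n_cycles >= 3", call. = FALSE)
  prof <- .activity_profile(activity, cfg$body_weight_n)
  cadence <- cfg$cadence_hz %||% prof$cadence
  n_per <- round(cfg$master_rate_hz / cadence)
  c <- cfg$n_cycles
  n <- c * n_per + round(n_per / 2) + 1L
  i <- seq_len(n) - 1L
  tau <- (i %% n_per) / n_per # phase within cycle, 0 at boundary
  ml_c <- cfg$cop_center_cm[1]
  ap_c <- cfg$cop_center_cm[2]

  if (activity == "squat") {
    vgrf <- prof$base * (1 - prof$depth * sin(pi * tau)^2)
    cop_ap <- ap_c + prof$ap_amp / 2 * sin(2 * pi * tau)
    cop_ml <- ml_c + prof$ml_amp / 2 * sin(2 * pi * tau + 1)
  } else if (activity == "sit_to_stand") {
    vgrf <- prof$low + (prof$high - prof$low) * sin(pi * tau)^2
    cop_ap <- ap_c + prof$ap_amp / 2 * sin(2 * pi * tau)
    cop_ml <- ml_c + prof$ml_amp / 2 * sin(2 * pi * tau + 1)
  } else {
    sf <- prof$stance_frac
    pad <- (1 - sf) / 2
    ts <- (tau - pad) / sf # stance phase in [0, 1]
    on <- ts >= 0 & ts <= 1
    vgrf <- numeric(n)
    if (activity == "jump") {
      vgrf[on] <- prof$amp * sin(pi * ts[on])^2
      cop_ap <- cop_ml <- rep(NA_real_, n)
      cop_ap[on] <- ap_c + prof$ap_range * (ts[on] - 0.5)
      cop_ml[on] <- ml_c + prof$ml_amp * sin(2 * pi * ts[on])
    } else {
      shape <- sin(pi * ts[on]) + prof$second_bump * sin(3 * pi * ts[on])
      vgrf[on] <- prof$amp * shape
      cop_ap <- cop_ml <- rep(NA_real_, n)
      cop_ap[on] <- ap_c + prof$ap_range * (ts[on] - 0.5)
      cop_ml[on] <- ml_c + prof$ml_amp * (sin(pi * ts[on]) - 0.5)
    }
    cop_ap[vgrf == 0] <- NA_real_
    cop_ml[vgrf == 0] <- NA_real_
  }
  structure(
    list(
      t_s = i / cfg$master_rate_hz,
      vgrf_n = vgrf,
      cop_ml_cm = cop_ml,
      cop_ap_cm = cop_ap,
      cycle_marks = as.integer(seq(0, c) * n_per + 1L),
      rate = cfg$master_rate_hz,
      activity = activity,
      profile = prof
    ),
    class = "truth_waveform"
  )
}

#' @export
print.truth_waveform <- function(x, ...) {
  cat(sprintf("<truth_waveform> %s, %d samples @ %g Hz, %d cycle marks\n",
              x$activity, length(x$vgrf_n), x$rate, length(x$cycle_marks)))
  invisible(x)
}

#' Render a truth waveform as a force-plate recording
#'
#' Downsamples the master-rate truth to the plate rate and adds white
#' measurement noise (vGRF clipped at zero). Deterministic given the
#' configuration seed.
#'
#' @param truth A [make_truth_waveform()] result.
#' @param cfg A [simulation_config()].
#' @param plate_id `"left"` or `"right"`.
#' @return A [force_plate_recording()].
#' @export
render_plate <- function(truth, cfg = simulation_config(),
                         plate_id = c("right", "left")) {
  plate_id <- match.arg(plate_id)
  set.seed(cfg$seed + 104729L) # offset decorrelates plate and insole noise
  step <- truth$rate / cfg$plate_rate_hz
  if (abs(step - round(step)) < 1e-9) {
    idx <- seq(1L, length(truth$vgrf_n), by = round(step))
    vgrf <- truth$vgrf_n[idx]
    ml <- truth$cop_ml_cm[idx]
    ap <- truth$cop_ap_cm[idx]
  } else {
    vgrf <- resample_with_gaps(truth$vgrf_n, truth$rate, cfg$plate_rate_hz)
    ml <- resample_with_gaps(truth$cop_ml_cm, truth$rate, cfg$plate_rate_hz)
    ap <- resample_with_gaps(truth$cop_ap_cm, truth$rate, cfg$plate_rate_hz)
  }
  n <- length(vgrf)
  if (cfg$noise_sd_plate_n > 0) {
    vgrf <- pmax(vgrf + stats::rnorm(n, 0, cfg$noise_sd_plate_n), 0)
  }
  if (cfg$noise_sd_cop_cm > 0) {
    ml <- ml + stats::rnorm(n, 0, cfg$noise_sd_cop_cm)
    ap <- ap + stats::rnorm(n, 0, cfg$noise_sd_cop_cm)
  }
  force_plate_recording(vgrf, ml, ap, rate = cfg$plate_rate_hz,
                        plate_id = plate_id)
}

#' Render a truth waveform as a raw insole recording
#'
#' Samples the truth at the insole rate and, frame by frame, deposits a
#' bivariate-Gaussian pressure footprint on the sensel grid, centred at
#' the (bias-adjusted) COP and scaled so the summed sensel load equals
#' `vgrf * vgrf_scale_bias` exactly. COP-ML excursions are shrunk about
#' the grid midline by `cop_ml_shrink`, emulating the insole's
#' compressed medial-lateral picture. Per-sensel noise is added and
#' pressures are clamped to the device range. Frames where the foot is
#' unloaded (or the COP undefined) are all-zero.
#'
#' @param truth A [make_truth_waveform()] result.
#' @param grid A [sensel_grid()].
#' @param cfg A [simulation_config()].
#' @return An [insole_recording()].
#' @export
render_insole <- function(truth, grid, cfg = simulation_config()) {
  set.seed(cfg$seed + 224737L)
  dur <- truth$t_s[length(truth$t_s)]
  n_frames <- floor(dur * cfg$insole_rate_hz) + 1L
  t60 <- (seq_len(n_frames) - 1) / cfg$insole_rate_hz
  vgrf <- resample_with_gaps(truth$vgrf_n, truth$rate, cfg$insole_rate_hz)[1:n_frames]
  ml <- resample_with_gaps(truth$cop_ml_cm, truth$rate, cfg$insole_rate_hz)[1:n_frames]
  ap <- resample_with_gaps(truth$cop_ap_cm, truth$rate, cfg$insole_rate_hz)[1:n_frames]

  x <- grid$x_cm
  z <- grid$z_cm
  xc_grid <- (min(x) + max(x)) / 2
  left <- identical(grid_side(grid), "left")
  two_s2 <- 2 * cfg$blob_sd_cm^2
  press <- matrix(0, nrow = n_frames, ncol = nrow(grid))
  for (f in seq_len(n_frames)) {
    target <- vgrf[f] * cfg$vgrf_scale_bias
    if (!is.finite(target) || target <= 0 || !is.finite(ml[f])) next
    cx <- xc_grid + (ml[f] - xc_grid) * cfg$cop_ml_shrink
    if (left) cx <- (min(x) + max(x)) - cx # canonical -> device frame
    cz <- ap[f]
    w <- exp(-((x - cx)^2 + (z - cz)^2) / two_s2)
    s <- 0.1 * sum(w * grid$area_cm2)
    if (s <= 0) {
      warning("pressure footprint misses the grid at frame ", f, call. = FALSE)
      next
    }
    press[f, ] <- w * (target / s)
  }
  if (cfg$noise_sd_insole_kpa > 0) {
    press <- pmax(press + matrix(stats::rnorm(length(press), 0,
                                              cfg$noise_sd_insole_kpa),
                                 nrow = n_frames), 0)
  }
  press <- pmin(press, 883)
  insole_recording(grid, cfg$epoch_ms + round(t60 * 1000), press,
                   nominal_rate = cfg$insole_rate_hz)
}

#' Paired insole/plate rendering of one trial
#'
#' Convenience wrapper: builds the truth waveform and renders both
#' systems plus the sync anchor spanning the trial.
#'
#' @param activity See [activity_polarity()].
#' @param cfg A [simulation_config()].
#' @param grid A [sensel_grid()] (default right-foot
#'   [default_sensel_grid()]).
#' @return A list with `truth`, `insole`, `plate`, `anchor`, `grid`,
#'   `activity`.
#' @export
simulate_trial <- function(activity, cfg = simulation_config(),
                           grid = default_sensel_grid("right")) {
  truth <- make_truth_waveform(activity, cfg)
  insole <- render_insole(truth, grid, cfg)
  plate <- render_plate(truth, cfg,
                        plate_id = grid_side(grid))
  anchor <- sync_anchor(insole$timestamp_ms[1],
                        insole$timestamp_ms[length(insole$timestamp_ms)])
  list(truth = truth, insole = insole, plate = plate, anchor = anchor,
       grid = grid, activity = activity)
}

#' Write one simulated trial to plain-text files
#'
#' Writes the insole CSV, grid CSV, plate CSV, anchor CSV and a truth
#' JSON (cycle marks, rates, activity) into a directory.
#'
#' @param trial A [simulate_trial()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_trial_files <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    insole = file.path(dir, "insole.csv"),
    grid = file.path(dir, "grid.csv"),
    plate = file.path(dir, "plate.csv"),
    anchor = file.path(dir, "anchor.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_insole_csv(trial$insole, paths["insole"])
  write_grid_csv(trial$grid, paths["grid"])
  write_plate_csv(trial$plate, paths["plate"])
  write_anchor_csv(trial$anchor, paths["anchor"])
  jsonlite::write_json(
    list(activity = trial$activity,
         cycle_marks = trial$truth$cycle_marks,
         truth_rate_hz = trial$truth$rate),
    paths["truth"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Simulate a two-session test-retest dataset
#'
#' Draws a subjects-by-sessions matrix from the compound-symmetry model
#' `y_ij = mu + b_i + e_ij`, `b_i ~ N(0, var_between)`,
#' `e_ij ~ N(0, var_within)`, whose population consistency ICC is
#' `var_between / (var_between + var_within)` (attached as attribute
#' `true_icc`).
#'
#' @param n_subjects,k_sessions Matrix dimensions.
#' @param mu Grand mean.
#' @param var_between,var_within Variance components (>= 0).
#' @param seed Integer seed.
#' @return Numeric matrix with attribute `true_icc`.
#' @export
simulate_test_retest <- function(n_subjects, k_sessions = 2, mu = 0,
                                 var_between = 1, var_within = 1, seed = 1L) {
  if (var_between < 0 || var_within < 0) {
    stop("variances must be non-negative", call. = FALSE)
  }
  set.seed(seed)
  b <- stats::rnorm(n_subjects, 0, sqrt(var_between))
  e <- matrix(stats::rnorm(n_subjects * k_sessions, 0, sqrt(var_within)),
              nrow = n_subjects)
  m <- mu + b + e
  attr(m, "true_icc") <- if (var_between + var_within > 0) {
    var_between / (var_between + var_within)
  } else NA_real_
  m
}

#' Simulate paired two-system measurements
#'
#' Draws a baseline value per participant and adds a fixed bias plus
#' noise to produce the second system's reading:
#' `b_i ~ N(baseline_mean, baseline_sd^2)`,
#' `a_i = b_i + bias + eps_i`, `eps_i ~ N(0, sd^2)`.
#'
#' @param n Number of pairs (>= 4).
#' @param bias Fixed between-system bias (a minus b).
#' @param sd Noise SD of the differences.
#' @param seed Integer seed.
#' @param baseline_mean,baseline_sd Baseline distribution parameters.
#' @return A [paired_samples()] object with attribute `true_bias`.
#' @export
simulate_paired <- function(n, bias = 0, sd = 1, seed = 1L,
                            baseline_mean = 500, baseline_sd = 100) {
  if (n < 4) stop("need n >= 4 pairs", call. = FALSE)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  set.seed(seed)
  b <- stats::rnorm(n, baseline_mean, baseline_sd)
  a <- b + bias + stats::rnorm(n, 0, sd)
  out <- paired_samples(a, b)
  attr(out, "true_bias") <- bias
  out
}
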