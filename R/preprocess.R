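#' Low-pass Butterworth filtering
#'
#' Biomechanical force and COP signals are conventionally smoothed with
#' a low-order zero-phase Butterworth low-pass filter. `filter_spec()`
#' captures the design (default: 6 Hz cutoff, order 2, zero-phase).
#' With `zero_phase = TRUE` the filter is applied forward and backward
#' ([signal::filtfilt()]), which removes phase lag and squares the
#' magnitude response (the effective roll-off doubles).
#'
#' @param cutoff_hz Cutoff frequency, Hz.
#' @param order Filter order of the underlying one-pass design.
#' @param zero_phase Apply forward-backward (no phase lag)?
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 6, order = 2, zero_phase = TRUE) {
  if (cutoff_hz <= 0) stop("cutoff must be positive", call. = FALSE)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  structure(
    list(cutoff_hz = cutoff_hz, order = order, zero_phase = zero_phase),
    class = "filter_spec"
  )
}

#' @rdname filter_spec
#' @param series Uniformly sampled numeric vector.
#' @param rate Sampling rate, Hz.
#' @param spec A `filter_spec`.
#' @export
lowpass_filter <- function(series, rate, spec = filter_spec()) {
  if (spec$cutoff_hz >= rate / 2) {
    stop("cutoff ", spec$cutoff_hz, " Hz is at or above the Nyquist frequency (",
         rate / 2, " Hz)", call. = FALSE)
  }
  if (length(series) < 3 * spec$order) {
    stop("series too short to filter (need at least ", 3 * spec$order,
         " samples)", call. = FALSE)
  }
  if (any(!is.finite(series))) {
    stop("series must be finite; use filter_with_gaps() for NA-flagged channels",
         call. = FALSE)
  }
  bf <- signal::butter(spec$order, spec$cutoff_hz / (rate / 2), type = "low")
  # Edge padding long enough for the zero-state filter transient to
  # decay to numerical noise (pole time constant ~ rate / (2 pi cutoff);
  # five cutoff periods is ~30 time constants): odd reflection next to
  # the data, constant extension beyond it when the series is short.
  n <- length(series)
  pad <- ceiling(5 * rate / spec$cutoff_hz)
  pr <- min(n - 1L, pad)
  left <- 2 * series[1] - series[(pr + 1):2]
  right <- 2 * series[n] - series[(n - 1):(n - pr)]
  fill <- pad - pr
  xp <- c(rep(left[1], fill), left, series, right, rep(right[pr], fill))
  y <- as.numeric(signal::filter(bf, xp))
  if (spec$zero_phase) {
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
  }
  y[(pad + 1):(pad + n)]
}

#' @rdname filter_spec
#' @details `filter_with_gaps()` filters each contiguous run of defined
#'   (finite) samples independently and leaves `NA` spans untouched, so
#'   undefined COP samples are bridged by exclusion rather than by
#'   interpolation. Runs too short to filter are passed through
#'   unfiltered.
#' @export
filter_with_gaps <- function(series, rate, spec = filter_spec()) {
  out <- series
  ok <- is.finite(series)
  if (!any(ok)) return(out)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_len <- max(3 * spec$order, 3 * (spec$order + 1))
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    if (length(idx) >= min_len) {
      out[idx] <- lowpass_filter(series[idx], rate, spec)
    }
  }
  out
}

#' Analytic gain of the configured Butterworth low-pass
#'
#' Returns the magnitude gain the filter applies to a pure tone at
#' frequency `f_hz`. With `rate` supplied, the exact response of the
#' discrete (bilinear-transform) design is returned; without it, the
#' ideal analog prototype `(1 + (f/fc)^(2 order))^(-1/2)` is used. For
#' a zero-phase (forward-backward) filter the gain is squared.
#'
#' @param f_hz Tone frequency, Hz.
#' @param spec A [filter_spec()].
#' @param rate Sampling rate, Hz, or `NULL` for the analog prototype.
#' @return Gain in (0, 1].
#' @export
butterworth_gain <- function(f_hz, spec = filter_spec(), rate = NULL) {
  if (is.null(rate)) {
    ratio <- f_hz / spec$cutoff_hz
  } else {
    # bilinear transform warps frequency as tan(pi f / fs)
    ratio <- tan(pi * f_hz / rate) / tan(pi * spec$cutoff_hz / rate)
  }
  g1 <- 1 / sqrt(1 + ratio^(2 * spec$order))
  if (spec$zero_phase) g1^2 else g1
}

#' Rational resampling of a uniformly sampled series
#'
#' Band-limited rate conversion using polyphase FIR resampling
#' ([signal::resample()]) at the rational ratio `rate_out / rate_in`
#' (reduced with an exact integer gcd). Identity when the rates are
#' equal.
#'
#' @param series Numeric vector, uniformly sampled at `rate_in`.
#' @param rate_in,rate_out Input and output sampling rates, Hz.
#' @return Numeric vector at `rate_out`; duration is preserved to
#'   within one output sample.
#' @export
resample_series <- function(series, rate_in, rate_out) {
  if (rate_in <= 0 || rate_out <= 0) stop("rates must be positive", call. = FALSE)
  if (length(series) < 2) stop("series must have at least 2 samples", call. = FALSE)
  if (rate_in == rate_out) return(series)
  scale <- 1e6 # tolerate non-integer rates to micro-hertz resolution
  p <- round(rate_out * scale)
  q <- round(rate_in * scale)
  g <- .gcd(p, q)
  as.numeric(signal::resample(series, p / g, q / g))
}

.gcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' @rdname resample_series
#' @details `resample_with_gaps()` converts a channel that may carry
#'   `NA`-flagged (undefined) spans by linear interpolation on the new
#'   time base; output samples whose bracketing input samples are not
#'   both defined are `NA`. Used for COP channels, where band-limited
#'   resampling across undefined spans would manufacture data.
#' @export
resample_with_gaps <- function(series, rate_in, rate_out) {
  if (length(series) < 2) stop("series must have at least 2 samples", call. = FALSE)
  n_out <- floor((length(series) - 1) * rate_out / rate_in) + 1
  # fractional position on the input index axis
  pos <- (seq_len(n_out) - 1) * rate_in / rate_out + 1
  lo <- pmin(floor(pos), length(series))
  hi <- pmin(lo + 1, length(series))
  w <- pos - lo
  v <- series[lo] * (1 - w) + series[hi] * w
  v[w == 0] <- series[lo][w == 0] # exact grid points keep their value
  v
}

#' Crop an insole recording to sync anchors
#'
#' Keeps frames with `start_ms <= timestamp <= end_ms` (closed
#' interval). Anchors that do not coincide with a frame timestamp are
#' matched to the nearest timestamp within `tolerance_ms`; beyond that
#' the trial cannot be synchronized and an error is raised (recordings
#' with broken timestamps are excluded rather than silently shifted).
#'
#' @param rec An [insole_recording()].
#' @param anchor A [sync_anchor()].
#' @param tolerance_ms Maximum anchor-to-frame mismatch, ms.
#' @return A cropped [insole_recording()].
#' @export
crop_to_anchors <- function(rec, anchor, tolerance_ms = 50) {
  stopifnot(inherits(rec, "insole_recording"), inherits(anchor, "sync_anchor"))
  ts <- rec$timestamp_ms
  if (anchor$end_ms < ts[1] || anchor$start_ms > ts[length(ts)]) {
    stop("sync window [", anchor$start_ms, ", ", anchor$end_ms,
         "] ms does not overlap recording span [", ts[1], ", ",
         ts[length(ts)], "] ms", call. = FALSE)
  }
  snap <- function(target) {
    i <- which.min(abs(ts - target))
    off <- abs(ts[i] - target)
    if (off > tolerance_ms) {
      stop("no frame timestamp within ", tolerance_ms, " ms of anchor ",
           target, " ms (nearest offset ", off, " ms)", call. = FALSE)
    }
    if (off > 0) {
      message("anchor ", target, " ms matched to nearest frame at ", ts[i],
              " ms (offset ", off, " ms)")
    }
    i
  }
  i0 <- snap(anchor$start_ms)
  i1 <- snap(anchor$end_ms)
  keep <- i0:i1
  insole_recording(rec$grid, ts[keep],
                   rec$pressure_kpa[keep, , drop = FALSE],
                   nominal_rate = rec$nominal_rate)
}

#' Synchronize an insole recording with a force-plate recording
#'
#' Implements the timestamp-matching alignment used when the two
#' systems cannot share a hardware trigger: the free-running insole
#' stream is cropped to the plate trial's start/end anchors, outcome
#' channels are derived per frame, both systems are low-pass filtered
#' at their native rates, the insole channels are resampled up to the
#' plate rate, and both are truncated to the common length.
#'
#' @param insole An [insole_recording()].
#' @param plate A [force_plate_recording()].
#' @param anchor A [sync_anchor()] marking the plate trial in insole time.
#' @param spec A [filter_spec()].
#' @param activity Activity label carried through to segmentation.
#' @param duration_tol Maximum relative mismatch between plate duration
#'   and the anchor window (default 0.05).
#' @param load_floor_n Passed to [derive_channels()].
#' @param tolerance_ms Passed to [crop_to_anchors()].
#' @return A list of class `synced_trial` with elements `rate`,
#'   `insole` and `plate` ([derived_channels()] on a common time base)
#'   and `activity`.
#' @export
synchronize_pair <- function(insole, plate, anchor, spec = filter_spec(),
                             activity = "unknown", duration_tol = 0.05,
                             load_floor_n = 10, tolerance_ms = 50) {
  window_s <- (anchor$end_ms - anchor$start_ms) / 1000
  plate_s <- (length(plate$vgrf_n) - 1) / plate$rate
  if (abs(plate_s - window_s) > duration_tol * window_s) {
    stop("plate duration ", round(plate_s, 3), " s differs from anchor window ",
         round(window_s, 3), " s by more than ", 100 * duration_tol, "%",
         call. = FALSE)
  }
  cropped <- crop_to_anchors(insole, anchor, tolerance_ms = tolerance_ms)
  ins <- derive_channels(cropped, load_floor_n = load_floor_n)
  rate_in <- insole$nominal_rate
  rate_out <- plate$rate

  f_vgrf <- pmax(lowpass_filter(ins$vgrf_n, rate_in, spec), 0)
  f_peak <- lowpass_filter(ins$peak_pressure_kpa, rate_in, spec)
  f_ml <- filter_with_gaps(ins$cop_ml_cm, rate_in, spec)
  f_ap <- filter_with_gaps(ins$cop_ap_cm, rate_in, spec)

  up_vgrf <- pmax(resample_series(f_vgrf, rate_in, rate_out), 0)
  up_peak <- resample_series(f_peak, rate_in, rate_out)
  up_ml <- resample_with_gaps(f_ml, rate_in, rate_out)
  up_ap <- resample_with_gaps(f_ap, rate_in, rate_out)

  p_vgrf <- pmax(lowpass_filter(plate$vgrf_n, rate_out, spec), 0)
  p_ml <- filter_with_gaps(plate$cop_ml_cm, rate_out, spec)
  p_ap <- filter_with_gaps(plate$cop_ap_cm, rate_out, spec)

  n <- min(length(up_vgrf), length(p_vgrf))
  t_s <- (seq_len(n) - 1) / rate_out
  structure(
    list(
      rate = rate_out,
      insole = derived_channels(t_s, up_vgrf[1:n], up_peak[1:n],
                                up_ml[1:n], up_ap[1:n], rate = rate_out),
      plate = derived_channels(t_s, p_vgrf[1:n], NULL,
                               p_ml[1:n], p_ap[1:n], rate = rate_out),
      activity = activity
    ),
    class = "synced_trial"
  )
}

#' @export
print.synced_trial <- function(x, ...) {
  cat(sprintf("<synced_trial> activity=%s, %d samples @ %g Hz (%.1f s)\n",
              x$activity, nrow(x$insole), x$rate, nrow(x$insole) / x$rate))
  invisible(x)
}
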