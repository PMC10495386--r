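#' Raw insole recording
#'
#' An `insole_recording` bundles a [sensel_grid()] with a sequence of
#' timestamped pressure frames. Pressures are in kPa; timestamps in
#' integer milliseconds and strictly increasing. Pressures above the
#' device ceiling (default 883 kPa, the upper end of the sensor's rated
#' range) are clamped with a warning; negative pressures are rejected.
#'
#' @param grid A [sensel_grid()].
#' @param timestamp_ms Integer-valued vector of frame timestamps, ms.
#' @param pressure_kpa Numeric matrix, frames x sensels, kPa.
#' @param nominal_rate Nominal sampling rate, Hz (default 60).
#' @param pressure_ceiling_kpa Saturation ceiling, kPa (default 883).
#'
#' @return A list of class `insole_recording` with elements `grid`,
#'   `timestamp_ms`, `pressure_kpa`, `nominal_rate`.
#' @export
insole_recording <- function(grid, timestamp_ms, pressure_kpa,
                             nominal_rate = 60, pressure_ceiling_kpa = 883) {
  stopifnot(inherits(grid, "sensel_grid"))
  pressure_kpa <- as.matrix(pressure_kpa)
  if (ncol(pressure_kpa) != nrow(grid)) {
    stop("pressure matrix has ", ncol(pressure_kpa),
         " columns but grid has ", nrow(grid), " sensels", call. = FALSE)
  }
  if (length(timestamp_ms) != nrow(pressure_kpa)) {
    stop("one timestamp per frame required", call. = FALSE)
  }
  if (any(!is.finite(timestamp_ms)) || any(diff(timestamp_ms) <= 0)) {
    stop("timestamps must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(pressure_kpa))) {
    stop("pressures must be finite", call. = FALSE)
  }
  if (any(pressure_kpa < 0)) {
    stop("pressures must be non-negative", call. = FALSE)
  }
  n_over <- sum(pressure_kpa > pressure_ceiling_kpa)
  if (n_over > 0) {
    warning(n_over, " pressure sample(s) above the ", pressure_ceiling_kpa,
            " kPa ceiling were clamped", call. = FALSE)
    pressure_kpa[pressure_kpa > pressure_ceiling_kpa] <- pressure_ceiling_kpa
  }
  structure(
    list(
      grid = grid,
      timestamp_ms = as.numeric(timestamp_ms),
      pressure_kpa = pressure_kpa,
      nominal_rate = nominal_rate
    ),
    class = "insole_recording"
  )
}

#' @export
print.insole_recording <- function(x, ...) {
  dur <- (x$timestamp_ms[length(x$timestamp_ms)] - x$timestamp_ms[1]) / 1000
  cat(sprintf(
    "<insole_recording> %d frames @ %g Hz nominal (%.1f s), %d sensels, side=%s\n",
    length(x$timestamp_ms), x$nominal_rate, dur, nrow(x$grid), grid_side(x$grid)
  ))
  invisible(x)
}

#' Force-plate recording
#'
#' Uniformly sampled force-plate channels: vertical ground-reaction
#' force (N) and centre-of-pressure coordinates (cm), at a fixed rate
#' (default 1000 Hz).
#'
#' @param vgrf_n,cop_ml_cm,cop_ap_cm Equal-length channel vectors.
#' @param rate Sampling rate, Hz.
#' @param plate_id `"left"` or `"right"`.
#' @return A list of class `force_plate_recording`.
#' @export
force_plate_recording <- function(vgrf_n, cop_ml_cm, cop_ap_cm,
                                  rate = 1000, plate_id = c("left", "right")) {
  plate_id <- match.arg(plate_id)
  n <- length(vgrf_n)
  if (length(cop_ml_cm) != n || length(cop_ap_cm) != n) {
    stop("all plate channels must share one length", call. = FALSE)
  }
  if (any(is.finite(vgrf_n) & vgrf_n < 0)) {
    stop("plate vGRF must be non-negative after baseline handling", call. = FALSE)
  }
  structure(
    list(
      rate = rate,
      vgrf_n = as.numeric(vgrf_n),
      cop_ml_cm = as.numeric(cop_ml_cm),
      cop_ap_cm = as.numeric(cop_ap_cm),
      plate_id = plate_id
    ),
    class = "force_plate_recording"
  )
}

#' @export
print.force_plate_recording <- function(x, ...) {
  cat(sprintf(
    "<force_plate_recording> %d samples @ %g Hz (%.1f s), plate=%s\n",
    length(x$vgrf_n), x$rate, length(x$vgrf_n) / x$rate, x$plate_id
  ))
  invisible(x)
}

#' Read / write insole and force-plate CSV files
#'
#' Insole CSV is wide: header `timestamp_ms,p000,...,pNNN`, one row per
#' frame, pressures in kPa. Force-plate CSV has columns
#' `t_s,vgrf_n,cop_ml_cm,cop_ap_cm`. Sync-anchor files are two-column
#' `role,timestamp_ms` with roles `start` and `end`.
#'
#' @param path File path.
#' @param grid A [sensel_grid()] for the insole reader.
#' @param rec Recording object to write.
#' @param rate,plate_id Passed to [force_plate_recording()] when reading.
#' @name recording-io
NULL

#' @rdname recording-io
#' @export
read_insole_csv <- function(path, grid) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (names(d)[1] != "timestamp_ms") {
    stop("insole CSV must start with a timestamp_ms column", call. = FALSE)
  }
  insole_recording(grid, d$timestamp_ms, as.matrix(d[, -1, drop = FALSE]))
}

#' @rdname recording-io
#' @export
write_insole_csv <- function(rec, path) {
  stopifnot(inherits(rec, "insole_recording"))
  p <- rec$pressure_kpa
  colnames(p) <- sprintf("p%03d", seq_len(ncol(p)) - 1L)
  d <- data.frame(timestamp_ms = rec$timestamp_ms, p, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname recording-io
#' @export
read_plate_csv <- function(path, rate = 1000, plate_id = "right") {
  d <- utils::read.csv(path)
  req <- c("t_s", "vgrf_n", "cop_ml_cm", "cop_ap_cm")
  if (!all(req %in% names(d))) {
    stop("plate CSV must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  force_plate_recording(d$vgrf_n, d$cop_ml_cm, d$cop_ap_cm,
                        rate = rate, plate_id = plate_id)
}

#' @rdname recording-io
#' @export
write_plate_csv <- function(rec, path) {
  stopifnot(inherits(rec, "force_plate_recording"))
  d <- data.frame(
    t_s = (seq_along(rec$vgrf_n) - 1) / rec$rate,
    vgrf_n = rec$vgrf_n,
    cop_ml_cm = rec$cop_ml_cm,
    cop_ap_cm = rec$cop_ap_cm
  )
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sync anchors
#'
#' Start/end timestamps (ms) used to crop a free-running insole
#' recording to the span of one force-plate trial.
#'
#' @param start_ms,end_ms Anchor timestamps in ms, `start_ms < end_ms`.
#' @return A list of class `sync_anchor`.
#' @export
sync_anchor <- function(start_ms, end_ms) {
  if (!is.finite(start_ms) || !is.finite(end_ms) || start_ms >= end_ms) {
    stop("anchor requires finite start_ms < end_ms", call. = FALSE)
  }
  structure(list(start_ms = start_ms, end_ms = end_ms), class = "sync_anchor")
}

#' @rdname sync_anchor
#' @param path Anchor CSV path (`role,timestamp_ms` rows).
#' @export
read_anchor_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("role", "timestamp_ms") %in% names(d)) ||
      !all(c("start", "end") %in% d$role)) {
    stop("anchor file needs role,timestamp_ms rows with roles start and end",
         call. = FALSE)
  }
  sync_anchor(d$timestamp_ms[d$role == "start"][1],
              d$timestamp_ms[d$role == "end"][1])
}

#' @rdname sync_anchor
#' @param anchor A `sync_anchor` to write.
#' @export
write_anchor_csv <- function(anchor, path) {
  utils::write.csv(
    data.frame(role = c("start", "end"),
               timestamp_ms = c(anchor$start_ms, anchor$end_ms)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
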