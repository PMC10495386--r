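#' Frame-level force, pressure and centre-of-pressure computation
#'
#' The load carried by one sensel is its pressure times its sensing
#' area: with pressure in kPa and area in cm^2,
#' `f_i = p_i * 1000 * A_i * 1e-4` newtons, i.e. `0.1 * p_i * A_i`.
#' The vertical ground-reaction force is the sum of sensel loads, peak
#' pressure is the maximum sensel pressure, and the centre of pressure
#' is the load-weighted mean of the sensel coordinates. Load weighting
#' (pressure x area) coincides with pressure weighting on uniform-area
#' grids and remains physically correct when areas differ.
#'
#' Below a configurable total-load floor the COP is numerically
#' meaningless (e.g. the flight phase of a jump), so COP components are
#' returned as `NA`.
#'
#' @param pressure_kpa Per-sensel pressure vector, kPa.
#' @param grid A [sensel_grid()] with the same sensel count.
#' @param load_floor_n Total load (N) below which COP is undefined
#'   (default 10).
#'
#' @return A list with `vgrf_n`, `peak_pressure_kpa`, `cop_ml_cm`,
#'   `cop_ap_cm` (the COP components `NA` when total load is at or
#'   below the floor).
#' @export
frame_channels <- function(pressure_kpa, grid, load_floor_n = 10) {
  if (length(pressure_kpa) != nrow(grid)) {
    stop("frame has ", length(pressure_kpa), " pressures but grid has ",
         nrow(grid), " sensels", call. = FALSE)
  }
  load_n <- 0.1 * pressure_kpa * grid$area_cm2
  vgrf <- sum(load_n)
  if (vgrf > load_floor_n) {
    cop_ml <- sum(load_n * grid$x_cm) / vgrf
    cop_ap <- sum(load_n * grid$z_cm) / vgrf
  } else {
    cop_ml <- NA_real_
    cop_ap <- NA_real_
  }
  list(
    vgrf_n = vgrf,
    peak_pressure_kpa = max(pressure_kpa),
    cop_ml_cm = cop_ml,
    cop_ap_cm = cop_ap
  )
}

#' Derived channel time series
#'
#' Container for the per-frame outcome channels of one recording:
#' time (s, from the first frame), vGRF (N), peak pressure (kPa) and
#' COP medial-lateral / anterior-posterior coordinates (cm, `NA` where
#' the total load was at or below the load floor).
#'
#' @param t_s,vgrf_n,peak_pressure_kpa,cop_ml_cm,cop_ap_cm Equal-length
#'   channel vectors (`peak_pressure_kpa` may be `NULL` for systems
#'   that do not measure pressure).
#' @param rate Sampling rate in Hz, if uniform.
#' @return A data frame of class `derived_channels`.
#' @export
derived_channels <- function(t_s, vgrf_n, peak_pressure_kpa = NULL,
                             cop_ml_cm, cop_ap_cm, rate = NULL) {
  n <- length(t_s)
  if (length(vgrf_n) != n || length(cop_ml_cm) != n || length(cop_ap_cm) != n ||
      (!is.null(peak_pressure_kpa) && length(peak_pressure_kpa) != n)) {
    stop("all channels must share one length", call. = FALSE)
  }
  if (any(is.finite(vgrf_n) & vgrf_n < 0)) {
    stop("vGRF must be non-negative", call. = FALSE)
  }
  d <- data.frame(t_s = t_s, vgrf_n = vgrf_n)
  if (!is.null(peak_pressure_kpa)) d$peak_pressure_kpa <- peak_pressure_kpa
  d$cop_ml_cm <- cop_ml_cm
  d$cop_ap_cm <- cop_ap_cm
  attr(d, "rate") <- rate
  class(d) <- c("derived_channels", "data.frame")
  d
}

#' Derive outcome channels from a raw insole recording
#'
#' Applies [frame_channels()] to every frame and converts timestamps to
#' seconds from the first frame. The medial-lateral axis is
#' canonicalized across feet: left-foot COP-ML is reflected about the
#' grid's ML midline so that the same physical excursion produces the
#' same `cop_ml_cm` trace for either foot.
#'
#' @param rec An [insole_recording()].
#' @param load_floor_n Passed to [frame_channels()].
#' @return A [derived_channels()] data frame.
#' @export
derive_channels <- function(rec, load_floor_n = 10) {
  stopifnot(inherits(rec, "insole_recording"))
  n <- length(rec$timestamp_ms)
  if (n == 0L) stop("empty recording", call. = FALSE)
  grid <- rec$grid
  load <- 0.1 * sweep(rec$pressure_kpa, 2, grid$area_cm2, `*`)
  vgrf <- rowSums(load)
  peak <- apply(rec$pressure_kpa, 1, max)
  cop_ml <- rowSums(sweep(load, 2, grid$x_cm, `*`)) / vgrf
  cop_ap <- rowSums(sweep(load, 2, grid$z_cm, `*`)) / vgrf
  undef <- vgrf <= load_floor_n
  cop_ml[undef] <- NA_real_
  cop_ap[undef] <- NA_real_
  if (identical(grid_side(grid), "left")) {
    cop_ml <- (min(grid$x_cm) + max(grid$x_cm)) - cop_ml
  }
  derived_channels(
    t_s = (rec$timestamp_ms - rec$timestamp_ms[1]) / 1000,
    vgrf_n = vgrf,
    peak_pressure_kpa = peak,
    cop_ml_cm = cop_ml,
    cop_ap_cm = cop_ap,
    rate = rec$nominal_rate
  )
}

#' @rdname derive_channels
#' @param plate A [force_plate_recording()].
#' @export
plate_channels <- function(plate) {
  stopifnot(inherits(plate, "force_plate_recording"))
  derived_channels(
    t_s = (seq_along(plate$vgrf_n) - 1) / plate$rate,
    vgrf_n = plate$vgrf_n,
    cop_ml_cm = plate$cop_ml_cm,
    cop_ap_cm = plate$cop_ap_cm,
    rate = plate$rate
  )
}

#' Read / write derived-channel CSV
#'
#' Columns `t_s,vgrf_n,peak_pressure_kpa,cop_ml_cm,cop_ap_cm`; empty
#' cells encode undefined COP samples.
#'
#' @param ch A [derived_channels()] data frame.
#' @param path File path.
#' @export
write_channels_csv <- function(ch, path) {
  utils::write.csv(as.data.frame(ch), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_channels_csv
#' @export
read_channels_csv <- function(path) {
  d <- utils::read.csv(path)
  derived_channels(
    t_s = d$t_s, vgrf_n = d$vgrf_n,
    peak_pressure_kpa = if ("peak_pressure_kpa" %in% names(d)) d$peak_pressure_kpa,
    cop_ml_cm = d$cop_ml_cm, cop_ap_cm = d$cop_ap_cm
  )
}
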