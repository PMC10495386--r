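#' Activities and their segmentation polarity
#'
#' Movement cycles are delimited by local extrema of the vGRF signal.
#' For squats the load dips below quiet standing, so cycle boundaries
#' are the local *maxima* flanking each dip; for jumps, the
#' sit-to-stand test, walking and stair ambulation the load rises from
#' a low baseline, so boundaries are the local *minima* flanking each
#' load peak.
#'
#' @param activity One of `"squat"`, `"jump"`, `"sit_to_stand"`,
#'   `"walk"`, `"stair_ascent"`, `"stair_descent"`.
#' @return `"max"` or `"min"`: the extremum type that bounds a cycle.
#' @export
activity_polarity <- function(activity) {
  activity <- match.arg(activity, ACTIVITIES)
  if (activity == "squat") "max" else "min"
}

#' @rdname activity_polarity
#' @export
ACTIVITIES <- c("squat", "jump", "sit_to_stand", "walk",
                "stair_ascent", "stair_descent")

#' Local extrema with prominence and separation thresholds
#'
#' Finds strictly interior local maxima and minima. Plateaus (runs of
#' equal values) count as a single extremum at the plateau midpoint.
#' Candidates are filtered by topographic prominence (relative to the
#' signal's overall max-min range) and then thinned greedily by
#' descending prominence so that retained extrema of the same type are
#' at least `min_separation_s` apart.
#'
#' @param series Numeric vector (finite).
#' @param rate Sampling rate, Hz.
#' @param min_prominence Minimum prominence as a fraction of the signal
#'   range (default 0.1).
#' @param min_separation_s Minimum spacing between retained extrema of
#'   one type, seconds (default 0.4).
#' @return A list with integer index vectors `maxima` and `minima`
#'   (sorted ascending; possibly empty) and parallel prominence vectors
#'   `max_prominence`, `min_prominence`.
#' @export
find_local_extrema <- function(series, rate, min_prominence = 0.1,
                               min_separation_s = 0.4) {
  if (length(series) < 3) stop("series must have at least 3 samples", call. = FALSE)
  if (any(!is.finite(series))) stop("series must be finite", call. = FALSE)
  rng <- max(series) - min(series)
  if (rng == 0) {
    return(list(maxima = integer(0), minima = integer(0),
                max_prominence = numeric(0), min_prominence = numeric(0)))
  }
  sep <- max(1L, round(min_separation_s * rate))
  mx <- .peaks(series, rng * min_prominence, sep)
  mn <- .peaks(-series, rng * min_prominence, sep)
  list(maxima = mx$idx, minima = mn$idx,
       max_prominence = mx$prom, min_prominence = mn$prom)
}

# Candidate peaks of x (plateau-aware), prominence-filtered, then thinned
# greedily by descending prominence with a minimum index separation.
.peaks <- function(x, min_prom, min_sep) {
  r <- rle(x)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (j in seq_len(k)) {
    if (j == 1L || j == k) next # strictly interior
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
      cand <- c(cand, (starts[j] + ends[j]) %/% 2L)
    }
  }
  if (length(cand) == 0L) return(list(idx = integer(0), prom = numeric(0)))
  prom <- vapply(cand, .prominence, numeric(1), x = x, peaks = cand)
  keep <- prom >= min_prom
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0L) return(list(idx = integer(0), prom = numeric(0)))
  ord <- order(-prom, cand)
  sel <- logical(length(cand))
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(cand[i] - taken) >= min_sep)) {
      sel[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  o <- order(cand[sel])
  list(idx = cand[sel][o], prom = prom[sel][o])
}

# Topographic prominence of the peak at index i: height above the higher
# of the two key saddles (the lowest point between the peak and the
# nearest strictly higher ground on each side, or the signal end).
.prominence <- function(i, x, peaks) {
  h <- x[i]
  left <- x[seq_len(i - 1L)]
  higher_l <- which(left > h)
  base_l <- if (length(higher_l)) min(left[(max(higher_l)):(i - 1L)]) else min(left)
  right <- x[(i + 1L):length(x)]
  higher_r <- which(right > h)
  base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
  h - max(base_l, base_r)
}

#' Detect movement cycles from a vGRF signal
#'
#' Cycle boundaries are qualifying extrema of the activity's boundary
#' polarity ([activity_polarity()]); a valid cycle runs from one
#' boundary extremum to the next and contains exactly one qualifying
#' extremum of the opposite polarity. Candidate cycles containing none
#' are merged with the following cycle (the shared boundary is
#' dropped); cycles containing several opposite extrema are accepted
#' with the most prominent treated as the defining one (a message
#' records the repair). Adjacent cycles share their boundary sample
#' (closed intervals).
#'
#' @param series Filtered vGRF vector.
#' @param activity See [activity_polarity()].
#' @param rate Sampling rate, Hz.
#' @param min_prominence,min_separation_s Passed to
#'   [find_local_extrema()].
#' @return A data frame with columns `start_idx`, `end_idx` (1-based,
#'   closed) — one row per detected cycle, and attribute
#'   `boundary_idx` (the retained boundary extrema).
#' @export
detect_cycles <- function(series, activity, rate, min_prominence = 0.1,
                          min_separation_s = 0.4) {
  polarity <- activity_polarity(activity)
  ex <- find_local_extrema(series, rate, min_prominence, min_separation_s)
  if (polarity == "max") {
    bnd <- ex$maxima
    opp <- ex$minima
    opp_prom <- ex$min_prominence
  } else {
    bnd <- ex$minima
    opp <- ex$maxima
    opp_prom <- ex$max_prominence
  }
  if (length(bnd) < 2L || length(opp) < 1L) {
    stop("segmentation failed: found ", length(bnd), " boundary and ",
         length(opp), " opposite extrema; need at least one complete cycle",
         call. = FALSE)
  }
  bounds <- bnd
  i <- 1L
  while (i < length(bounds)) {
    inside <- which(opp > bounds[i] & opp < bounds[i + 1L])
    if (length(inside) == 0L) {
      if (i + 1L == length(bounds)) {
        bounds <- bounds[-length(bounds)] # trailing empty cycle: drop
      } else {
        message("cycle without opposite extremum merged with its successor")
        bounds <- bounds[-(i + 1L)]
      }
    } else {
      if (length(inside) > 1L) {
        message("cycle with ", length(inside),
                " opposite extrema: keeping the most prominent")
      }
      i <- i + 1L
    }
  }
  if (length(bounds) < 2L) {
    stop("segmentation failed: no complete cycle after repair", call. = FALSE)
  }
  out <- data.frame(start_idx = bounds[-length(bounds)], end_idx = bounds[-1L])
  attr(out, "boundary_idx") <- bounds
  out
}

#' Discard first and last movement cycles
#'
#' Edge cycles are contaminated by movement initiation and termination,
#' so the first and last detected cycle are removed before analysis.
#'
#' @param bounds Cycle data frame from [detect_cycles()].
#' @return The interior cycles; empty (with a warning) when fewer than
#'   3 cycles were supplied.
#' @export
trim_edge_cycles <- function(bounds) {
  n <- nrow(bounds)
  if (n < 3L) {
    warning("fewer than 3 cycles: none retained after edge trimming",
            call. = FALSE)
    return(bounds[integer(0), , drop = FALSE])
  }
  bounds[2:(n - 1L), , drop = FALSE]
}

#' Time-normalize one movement cycle to 101 points
#'
#' Each channel of the segment `[start_idx, end_idx]` is linearly
#' interpolated onto 101 equally spaced points spanning 0-100% of the
#' cycle, endpoints included. Undefined (`NA`) COP samples propagate:
#' an output point is `NA` whenever either bracketing input sample is
#' undefined. A channel whose undefined fraction exceeds
#' `max_gap_fraction` is flagged for exclusion from aggregation.
#'
#' @param channels A [derived_channels()] data frame.
#' @param start_idx,end_idx Cycle bounds (1-based, closed); the segment
#'   must contain at least 2 samples.
#' @param n_points Number of normalized points (default 101).
#' @param max_gap_fraction Maximum tolerated fraction of undefined
#'   samples per channel (default 0.2).
#' @return A data frame of class `normalized_cycle` with column
#'   `percent_cycle` plus one column per channel; attribute
#'   `channel_ok` is a named logical vector of the gap check.
#' @export
normalize_cycle <- function(channels, start_idx, end_idx, n_points = 101L,
                            max_gap_fraction = 0.2) {
  if (start_idx >= end_idx || start_idx < 1L || end_idx > nrow(channels)) {
    stop("invalid cycle bounds [", start_idx, ", ", end_idx, "]", call. = FALSE)
  }
  chans <- setdiff(names(channels), "t_s")
  pos <- seq(start_idx, end_idx, length.out = n_points)
  lo <- floor(pos)
  hi <- ceiling(pos)
  w <- pos - lo
  out <- data.frame(percent_cycle = seq(0, 100, length.out = n_points))
  ok <- logical(length(chans))
  names(ok) <- chans
  for (ch in chans) {
    v <- channels[[ch]]
    y <- v[lo] * (1 - w) + v[hi] * w
    exact <- w == 0
    y[exact] <- v[lo][exact]
    out[[ch]] <- y
    gap <- mean(!is.finite(v[start_idx:end_idx]))
    ok[ch] <- gap <= max_gap_fraction
  }
  attr(out, "channel_ok") <- ok
  class(out) <- c("normalized_cycle", "data.frame")
  out
}

#' Range of one channel over a normalized cycle
#'
#' The per-cycle summary statistic: maximum minus minimum of the
#' channel across the 101 normalized points, ignoring undefined
#' samples. `NA` when every sample is undefined.
#'
#' @param cycle A [normalize_cycle()] result.
#' @param channel Channel column name.
#' @return Non-negative scalar range (or `NA`).
#' @export
cycle_range <- function(cycle, channel) {
  if (!channel %in% names(cycle)) {
    stop("channel `", channel, "` not present", call. = FALSE)
  }
  v <- cycle[[channel]]
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(NA_real_)
  max(v) - min(v)
}

#' Pointwise mean and dispersion of normalized cycles
#'
#' Averages a set of 101-point cycles channel by channel, returning the
#' pointwise mean waveform and standard deviation (for ensemble
#' waveform plots).
#'
#' @param cycles Non-empty list of [normalize_cycle()] results sharing
#'   channels.
#' @return A list with data frames `mean` and `sd`, each with
#'   `percent_cycle` plus channel columns.
#' @export
average_cycles <- function(cycles) {
  if (length(cycles) == 0L) stop("no cycles to average", call. = FALSE)
  chans <- setdiff(names(cycles[[1]]), "percent_cycle")
  pc <- cycles[[1]]$percent_cycle
  mu <- data.frame(percent_cycle = pc)
  sdev <- data.frame(percent_cycle = pc)
  for (ch in chans) {
    m <- vapply(cycles, function(cy) cy[[ch]], numeric(length(pc)))
    m <- matrix(m, nrow = length(pc))
    mu[[ch]] <- rowMeans(m, na.rm = TRUE)
    sdev[[ch]] <- apply(m, 1, function(row) {
      row <- row[is.finite(row)]
      if (length(row) < 2L) 0 else stats::sd(row)
    })
  }
  list(mean = mu, sd = sdev)
}

#' Per-trial range outcomes
#'
#' Runs the full per-trial segmentation chain on one system's derived
#' channels: detect cycles on the vGRF signal, discard the edge cycles,
#' time-normalize each retained cycle, take each channel's per-cycle
#' range, and average ranges across cycles. COP channels exclude cycles
#' whose undefined fraction exceeds `max_gap_fraction`.
#'
#' @param channels A [derived_channels()] data frame (already filtered).
#' @param activity See [activity_polarity()].
#' @param rate Sampling rate, Hz (defaults to the channels' `rate`
#'   attribute).
#' @param min_prominence,min_separation_s Passed to [detect_cycles()].
#' @param max_gap_fraction Passed to [normalize_cycle()]; gait
#'   activities legitimately unload the foot for about a third of each
#'   cycle, so pipelines raise this for walking and stairs.
#' @return A list of class `range_outcome`: `activity`, `ranges`
#'   (named per-channel mean range), `n_cycles_used` (named per-channel
#'   count), `cycles` (list of normalized cycles).
#' @export
participant_outcomes <- function(channels, activity, rate = attr(channels, "rate"),
                                 min_prominence = 0.1, min_separation_s = 0.4,
                                 max_gap_fraction = 0.2) {
  if (is.null(rate)) stop("sampling rate unknown; pass `rate`", call. = FALSE)
  bounds <- detect_cycles(channels$vgrf_n, activity, rate,
                          min_prominence, min_separation_s)
  kept <- trim_edge_cycles(bounds)
  if (nrow(kept) == 0L) {
    stop("no cycles retained after edge trimming", call. = FALSE)
  }
  cycles <- lapply(seq_len(nrow(kept)), function(i) {
    normalize_cycle(channels, kept$start_idx[i], kept$end_idx[i],
                    max_gap_fraction = max_gap_fraction)
  })
  chans <- setdiff(names(channels), "t_s")
  ranges <- numeric(length(chans))
  used <- integer(length(chans))
  names(ranges) <- names(used) <- chans
  for (ch in chans) {
    ok <- vapply(cycles, function(cy) attr(cy, "channel_ok")[[ch]], logical(1))
    r <- vapply(cycles[ok], cycle_range, numeric(1), channel = ch)
    r <- r[is.finite(r)]
    used[ch] <- length(r)
    ranges[ch] <- if (length(r)) mean(r) else NA_real_
  }
  structure(
    list(activity = activity, ranges = ranges, n_cycles_used = used,
         cycles = cycles),
    class = "range_outcome"
  )
}

#' @export
print.range_outcome <- function(x, ...) {
  cat(sprintf("<range_outcome> activity=%s, %d cycle(s)\n",
              x$activity, length(x$cycles)))
  for (ch in names(x$ranges)) {
    cat(sprintf("  %-18s %8.3f  (n=%d)\n", ch, x$ranges[ch], x$n_cycles_used[ch]))
  }
  invisible(x)
}
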