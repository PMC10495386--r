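#' Sensel grid geometry
#'
#' A `sensel_grid` describes the planar geometry of one instrumented
#' insole: the medial-lateral (`x_cm`) and anterior-posterior (`z_cm`)
#' coordinate of each pressure-sensing element (sensel) and its sensing
#' area in cm^2. Coordinates are stored in the device frame with the
#' origin at the posterior-lateral corner of the bounding box, `x`
#' increasing medially for a right foot and laterally for a left foot;
#' [derive_channels()] canonicalizes the medial-lateral axis so both
#' feet share one orientation.
#'
#' @param x_cm,z_cm Numeric vectors of sensel centre coordinates, cm.
#' @param area_cm2 Numeric vector of sensel areas, cm^2 (all > 0).
#' @param side `"left"` or `"right"`.
#'
#' @return A data frame of class `sensel_grid` with columns `sensel`
#'   (0-based index), `x_cm`, `z_cm`, `area_cm2` and attribute `side`.
#' @export
sensel_grid <- function(x_cm, z_cm, area_cm2, side = c("left", "right")) {
  side <- match.arg(side)
  n <- length(x_cm)
  if (length(z_cm) != n || length(area_cm2) != n) {
    stop("coordinate and area vectors must share one length", call. = FALSE)
  }
  if (n < 1L) stop("a sensel grid needs at least one sensel", call. = FALSE)
  if (any(!is.finite(x_cm)) || any(!is.finite(z_cm)) || any(!is.finite(area_cm2))) {
    stop("grid coordinates and areas must be finite", call. = FALSE)
  }
  if (any(area_cm2 <= 0)) stop("all sensel areas must be strictly positive", call. = FALSE)
  if (anyDuplicated(cbind(x_cm, z_cm))) {
    stop("no two sensels may share identical (x, z) coordinates", call. = FALSE)
  }
  g <- data.frame(
    sensel = seq_len(n) - 1L,
    x_cm = as.numeric(x_cm),
    z_cm = as.numeric(z_cm),
    area_cm2 = as.numeric(area_cm2)
  )
  attr(g, "side") <- side
  class(g) <- c("sensel_grid", "data.frame")
  g
}

#' @export
print.sensel_grid <- function(x, ...) {
  cat(sprintf(
    "<sensel_grid> %d sensels, side=%s, x [%.1f, %.1f] cm, z [%.1f, %.1f] cm\n",
    nrow(x), grid_side(x), min(x$x_cm), max(x$x_cm), min(x$z_cm), max(x$z_cm)
  ))
  invisible(x)
}

#' @rdname sensel_grid
#' @param grid A `sensel_grid`.
#' @export
grid_side <- function(grid) attr(grid, "side")

# Half-width of the insole outline (cm) at anterior-posterior position z,
# measured from the long axis. Piecewise-smooth: rounded heel, waisted
# midfoot, broad forefoot, tapered toe cap.
.insole_half_width <- function(z, length_cm = 27) {
  zz <- pmin(pmax(z, 0), length_cm)
  w <- numeric(length(zz))
  heel_end <- 6
  mid_end <- 15
  fore_end <- 23
  for (i in seq_along(zz)) {
    z0 <- zz[i]
    if (z0 < heel_end) {
      w[i] <- 4.2 * sqrt(pmax(0, 1 - ((heel_end - z0) / heel_end)^2))
    } else if (z0 <= mid_end) {
      w[i] <- 4.2 - 0.4 * sin(pi * (z0 - heel_end) / (mid_end - heel_end))
    } else if (z0 <= fore_end) {
      w[i] <- 4.2 + 0.8 * sin(pi * (z0 - mid_end) / (2 * (fore_end - mid_end)))
    } else {
      w[i] <- 5.0 * sqrt(pmax(0, 1 - ((z0 - fore_end) / (length_cm - fore_end))^2))
    }
  }
  w
}

#' Default synthetic insole grid
#'
#' Builds a deterministic foot-shaped lattice of sensels on a regular
#' pitch, emulating a full-surface pressure insole (default 235 sensels
#' of 9 x 9 mm on a 9.5 mm pitch, i.e. about a 1 mm inter-sensel gap).
#' The device this pipeline targets does not publish its sensel
#' coordinates, so analyses always load geometry from a grid object or
#' CSV file rather than assuming any layout; this constructor provides a
#' realistic stand-in.
#'
#' Candidate lattice sites inside the insole outline are ranked by their
#' margin to the outline and the innermost `n_sensels` are kept, so the
#' result is independent of floating-point traversal order.
#'
#' @param side `"left"` or `"right"`.
#' @param n_sensels Number of sensels to keep (default 235).
#' @param pitch_cm Lattice pitch, cm.
#' @param sensel_side_cm Side length of the square sensing element, cm.
#' @return A [sensel_grid()].
#' @export
default_sensel_grid <- function(side = c("left", "right"), n_sensels = 235L,
                                pitch_cm = 0.95, sensel_side_cm = 0.9) {
  side <- match.arg(side)
  length_cm <- 27
  axis_x <- 5.0
  xs <- seq(0.25, 9.75, by = pitch_cm)
  zs <- seq(0.5, length_cm - 0.25, by = pitch_cm)
  cand <- expand.grid(x = xs, z = zs)
  margin <- .insole_half_width(cand$z, length_cm) - abs(cand$x - axis_x)
  keep <- margin > 0
  cand <- cand[keep, , drop = FALSE]
  margin <- margin[keep]
  if (nrow(cand) < n_sensels) {
    stop("outline too small for ", n_sensels, " sensels", call. = FALSE)
  }
  ord <- order(-margin, cand$z, cand$x)
  sel <- cand[ord[seq_len(n_sensels)], , drop = FALSE]
  ord2 <- order(sel$z, sel$x)
  sel <- sel[ord2, , drop = FALSE]
  sensel_grid(sel$x, sel$z, rep(sensel_side_cm^2, n_sensels), side = side)
}

#' Read / write a sensel grid CSV
#'
#' Plain-text grid exchange format: a `# side=left|right` comment line
#' followed by a header `sensel,x_cm,z_cm,area_cm2` and one row per
#' sensel.
#'
#' @param path File path.
#' @param grid A [sensel_grid()] (for writing).
#' @return `read_grid_csv()` returns a [sensel_grid()];
#'   `write_grid_csv()` returns `path` invisibly.
#' @export
read_grid_csv <- function(path) {
  first <- readLines(path, n = 1L)
  side <- "right"
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("side\\s*=\\s*(left|right)", first))[[1]]
    if (length(m) == 2L) side <- m[2]
  }
  d <- utils::read.csv(path, comment.char = "#")
  req <- c("sensel", "x_cm", "z_cm", "area_cm2")
  if (!all(req %in% names(d))) {
    stop("grid CSV must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  d <- d[order(d$sensel), , drop = FALSE]
  sensel_grid(d$x_cm, d$z_cm, d$area_cm2, side = side)
}

#' @rdname read_grid_csv
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "sensel_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# side=%s", grid_side(grid)), con)
  writeLines("# device-frame coordinates: x medial-lateral, z anterior-posterior (cm)", con)
  utils::write.csv(as.data.frame(grid), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
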