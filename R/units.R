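#' Unit conversions for insole-reported quantities
#'
#' Pressure-insole vendor software commonly reports load in pound-force
#' (lbf) and peak pressure in pounds per square inch (PSI). Force plates
#' and the rest of this pipeline work in newtons (N) and kilopascals
#' (kPa), so these helpers convert between the two conventions.
#'
#' @param x Numeric vector of values to convert. Must be finite.
#'
#' @return Numeric vector of the same length in the target unit.
#'
#' @examples
#' lbf_to_newtons(1)      # 4.44822
#' psi_to_kpa(10)         # 68.9476
#' newtons_to_lbf(lbf_to_newtons(100))  # 100
#' @name unit-conversions
NULL

LBF_PER_N <- 4.44822
KPA_PER_PSI <- 6.89476

.check_finite <- function(x, what) {
  if (!is.numeric(x)) {
    stop("`", what, "` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("`", what, "` contains non-finite values", call. = FALSE)
  }
  invisible(x)
}

#' @rdname unit-conversions
#' @export
lbf_to_newtons <- function(x) {
  .check_finite(x, "x")
  x * LBF_PER_N
}

#' @rdname unit-conversions
#' @export
newtons_to_lbf <- function(x) {
  .check_finite(x, "x")
  x / LBF_PER_N
}

#' @rdname unit-conversions
#' @export
psi_to_kpa <- function(x) {
  .check_finite(x, "x")
  x * KPA_PER_PSI
}

#' @rdname unit-conversions
#' @export
kpa_to_psi <- function(x) {
  .check_finite(x, "x")
  x / KPA_PER_PSI
}
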