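#' Paired samples from two measurement systems
#'
#' Pairs one value per participant from system A (insoles) and system B
#' (force plates) for a single outcome. Participants missing either
#' value are dropped (pairwise-complete deletion), mirroring the
#' per-activity attrition typical of synchronization failures.
#'
#' @param a,b Numeric vectors, one value per participant.
#' @param labels Optional participant identifiers.
#' @param unit Unit string for reporting.
#' @return A data frame of class `paired_samples` with columns `label`,
#'   `a`, `b`.
#' @export
paired_samples <- function(a, b, labels = NULL, unit = "") {
  if (length(a) != length(b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  if (is.null(labels)) labels <- as.character(seq_along(a))
  ok <- is.finite(a) & is.finite(b)
  d <- data.frame(label = labels[ok], a = a[ok], b = b[ok])
  if (nrow(d) < 2L) {
    stop("need at least 2 complete pairs after deletion", call. = FALSE)
  }
  attr(d, "unit") <- unit
  class(d) <- c("paired_samples", "data.frame")
  d
}

#' Kolmogorov-Smirnov normality check
#'
#' Tests whether a vector of differences is compatible with a normal
#' distribution. Because the mean and SD are estimated from the sample,
#' the default applies the Lilliefors correction
#' ([nortest::lillie.test()]); `method = "ks"` gives the plain
#' one-sample KS test against the fitted normal for strict replication
#' of software that ignores the estimation effect.
#'
#' @param x Numeric vector, `n >= 4`, non-constant.
#' @param method `"lilliefors"` (default) or `"ks"`. The Lilliefors
#'   correction is tabulated for `n >= 5`; at `n = 4` the plain KS test
#'   is used regardless.
#' @return A list with `stat`, `p` and `method`.
#' @export
ks_normality <- function(x, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("normality check needs n >= 4", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate (constant) differences: normality undefined", call. = FALSE)
  }
  if (method == "lilliefors" && length(x) < 5L) method <- "ks"
  if (method == "lilliefors") {
    h <- nortest::lillie.test(x)
  } else {
    h <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  list(stat = unname(h$statistic), p = unname(h$p.value), method = method)
}

#' One-sample t-test of paired differences against zero
#'
#' Detects fixed bias between two systems: a small p-value indicates
#' the mean difference deviates from 0.
#'
#' @param diffs Numeric vector of paired differences, `n >= 2`,
#'   non-constant.
#' @return A list with `t`, `df`, `p`.
#' @export
paired_t <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  if (length(diffs) < 2L) stop("t-test needs n >= 2", call. = FALSE)
  if (stats::sd(diffs) == 0) {
    stop("degenerate (zero-variance) differences", call. = FALSE)
  }
  h <- stats::t.test(diffs, mu = 0)
  list(t = unname(h$statistic), df = unname(h$parameter),
       p = unname(h$p.value))
}

#' Bland-Altman agreement analysis
#'
#' Computes differences `d = a - b` (insole minus force plate), checks
#' their normality, and reports the bias and 95% limits of agreement:
#'
#' * normal differences: `mean(d) +/- 1.96 * SD(d)`;
#' * non-normal differences: `median(d) +/- 1.45 * IQR(d)`, with
#'   quartiles from the linear-interpolation convention
#'   (`stats::quantile()` type 7).
#'
#' A paired t-test p-value for fixed bias is always reported. When all
#' pairs agree exactly the result degenerates to zero bias with zero
#' width and the tests are reported as `NA`.
#'
#' @param pairs A [paired_samples()] object, `n >= 4`.
#' @param alpha_norm Significance level of the normality branch
#'   (default 0.05).
#' @param normality_method Passed to [ks_normality()].
#' @return A list of class `bland_altman` with `variant`
#'   (`"normal"`/`"nonnormal"`), `center`, `dispersion` (SD or IQR of
#'   d), `loa_lower`, `loa_upper`, `t_p`, `ks_p`, `n`, `unit`, and
#'   `plot_data` (`mean_ab`, `diff` per pair).
#' @export
bland_altman <- function(pairs, alpha_norm = 0.05,
                         normality_method = c("lilliefors", "ks")) {
  stopifnot(inherits(pairs, "paired_samples"))
  normality_method <- match.arg(normality_method)
  if (nrow(pairs) < 4L) stop("Bland-Altman needs n >= 4 pairs", call. = FALSE)
  d <- pairs$a - pairs$b
  n <- length(d)
  plot_data <- data.frame(mean_ab = (pairs$a + pairs$b) / 2, diff = d)
  if (stats::sd(d) == 0) {
    center <- mean(d)
    return(structure(
      list(variant = "normal", center = center, dispersion = 0,
           loa_lower = center, loa_upper = center,
           t_p = NA_real_, ks_p = NA_real_, n = n,
           unit = attr(pairs, "unit"), plot_data = plot_data),
      class = "bland_altman"
    ))
  }
  ks <- ks_normality(d, method = normality_method)
  tt <- paired_t(d)
  if (ks$p >= alpha_norm) {
    center <- mean(d)
    disp <- stats::sd(d)
    loa <- center + c(-1, 1) * 1.96 * disp
    variant <- "normal"
  } else {
    center <- stats::median(d)
    disp <- unname(diff(stats::quantile(d, c(0.25, 0.75), type = 7)))
    loa <- center + c(-1, 1) * 1.45 * disp
    variant <- "nonnormal"
  }
  structure(
    list(variant = variant, center = center, dispersion = disp,
         loa_lower = loa[1], loa_upper = loa[2],
         t_p = tt$p, ks_p = ks$p, n = n,
         unit = attr(pairs, "unit"), plot_data = plot_data),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n=%d, variant=%s\n  bias %.4g [%.4g, %.4g] %s, t p=%.3g, normality p=%.3g\n",
    x$n, x$variant, x$center, x$loa_lower, x$loa_upper,
    x$unit %||% "", x$t_p, x$ks_p
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine left- and right-foot values per participant
#'
#' Agreement outcomes pool both feet: the per-participant value is the
#' mean of the available feet. Participants with neither foot are
#' excluded (`NA`).
#'
#' @param left,right Numeric vectors of per-participant values (use
#'   `NA` for a missing foot).
#' @return A list with `value` (per-participant mean) and
#'   `single_foot` (logical flag where only one foot contributed).
#' @export
combine_feet <- function(left, right) {
  if (length(left) != length(right)) {
    stop("left and right must have equal length", call. = FALSE)
  }
  m <- cbind(left, right)
  k <- rowSums(is.finite(m))
  value <- rowSums(m, na.rm = TRUE) / k
  value[k == 0] <- NA_real_
  list(value = unname(value), single_foot = unname(k == 1))
}
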