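#' Two-way ANOVA mean squares for a subjects-by-sessions matrix
#'
#' Standard two-way decomposition without replication:
#' `SS_total = SS_rows + SS_cols + SS_error` with degrees of freedom
#' `n-1`, `k-1`, `(n-1)(k-1)`. Rows are subjects, columns sessions.
#'
#' @param m Numeric matrix, `n >= 3` subjects by `k >= 2` sessions, no
#'   missing cells.
#' @return A list with `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`.
#' @export
two_way_anova_ms <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3L || k < 2L) {
    stop("need at least 3 subjects and 2 sessions", call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop("matrix has missing cells; apply listwise deletion first", call. = FALSE)
  }
  grand <- mean(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0) stop("degenerate matrix: zero total variance", call. = FALSE)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  list(
    ms_rows = ss_rows / (n - 1),
    ms_cols = ss_cols / (k - 1),
    ms_error = max(ss_error, 0) / ((n - 1) * (k - 1)),
    n = n, k = k
  )
}

#' Consistency intraclass correlation (two-way random effects)
#'
#' Single-measures consistency ICC from the subjects-by-sessions ANOVA:
#' `ICC = (MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)`.
#' Insensitive to a uniform session offset (a systematic learning or
#' placement effect shifts `MS_cols`, not the ICC). The 95% confidence
#' interval is the exact F-based interval: with
#' `F = MS_rows / MS_error` on `(n-1, (n-1)(k-1))` degrees of freedom,
#' the bounds are `(F/Fu - 1)/(F/Fu + k - 1)` and
#' `(F*Fl - 1)/(F*Fl + k - 1)` where `Fu`, `Fl` are the upper
#' `alpha/2` F quantiles on the direct and swapped degrees of freedom.
#'
#' Negative estimates (possible when within-subject noise dominates)
#' are reported as computed, with a warning.
#'
#' @param m Numeric matrix, subjects x sessions.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `icc_result`: `icc`, `ci_lower`, `ci_upper`,
#'   `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`, `label`.
#' @export
icc_consistency <- function(m, conf_level = 0.95) {
  ms <- two_way_anova_ms(m)
  n <- ms$n
  k <- ms$k
  denom <- ms$ms_rows + (k - 1) * ms$ms_error
  if (denom == 0) stop("degenerate ICC denominator", call. = FALSE)
  icc <- (ms$ms_rows - ms$ms_error) / denom
  if (icc < 0) {
    warning("negative ICC estimate (", signif(icc, 3),
            "): within-subject variability exceeds between-subject variability",
            call. = FALSE)
  }
  alpha <- 1 - conf_level
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  if (ms$ms_error > 0) {
    fobs <- ms$ms_rows / ms$ms_error
    fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci_lower <- (fl - 1) / (fl + k - 1)
    ci_upper <- (fu - 1) / (fu + k - 1)
  } else {
    ci_lower <- icc
    ci_upper <- icc
  }
  structure(
    list(icc = icc, ci_lower = ci_lower, ci_upper = ci_upper,
         ms_rows = ms$ms_rows, ms_cols = ms$ms_cols, ms_error = ms$ms_error,
         n = n, k = k, label = classify_icc(icc)),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(C,1) = %.3f [%.3f, %.3f], n=%d, k=%d, %s\n",
              x$icc, x$ci_lower, x$ci_upper, x$n, x$k, x$label))
  invisible(x)
}

#' Qualitative ICC classification
#'
#' The conventional reliability bands: `>= 0.75` excellent, `0.4` to
#' `< 0.75` fair-to-high, below `0.4` poor. The published bands leave
#' (0.39, 0.4) unassigned; the boundary is placed at 0.4, which
#' preserves both printed boundary cases (0.4 is fair-to-high, 0.39 is
#' poor).
#'
#' @param icc Finite ICC estimate.
#' @return `"excellent"`, `"fair_to_high"` or `"poor"`.
#' @export
classify_icc <- function(icc) {
  if (!is.finite(icc)) stop("icc must be finite", call. = FALSE)
  if (icc >= 0.75) "excellent"
  else if (icc >= 0.4) "fair_to_high"
  else "poor"
}

#' Standard error of measurement
#'
#' Absolute reliability in the measurement's own unit:
#' `SEM = SD * sqrt(1 - ICC)`, where SD is the standard deviation over
#' subjects of each subject's across-session mean.
#'
#' @param m Subjects-by-sessions matrix.
#' @param icc ICC estimate to plug in; values outside `[0, 1]` are
#'   accepted with a warning (the formula is still applied).
#' @return A list of class `sem_result`: `sem`, `sd_used`, `icc_used`.
#' @export
sem_from <- function(m, icc) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (!is.finite(icc)) stop("icc must be finite", call. = FALSE)
  if (icc < 0 || icc > 1) {
    warning("icc = ", signif(icc, 3), " outside [0, 1]; SEM formula applied as-is",
            call. = FALSE)
  }
  sd_used <- stats::sd(rowMeans(m))
  structure(
    list(sem = sd_used * sqrt(max(1 - icc, 0)),
         sd_used = sd_used, icc_used = icc),
    class = "sem_result"
  )
}

#' Sample size for a reliability study
#'
#' Number of subjects needed to show that the ICC exceeds a minimally
#' acceptable level `p0` when the expected level is `p1`, with `k`
#' sessions per subject, using the Walter-Eliasziw-Donner variance
#' approximation: with `C0 = (1 + k p0/(1-p0)) / (1 + k p1/(1-p1))`,
#'
#' `n = 1 + 2 k (z_alpha + z_beta)^2 / ((k - 1) ln(C0)^2)`,
#'
#' rounded up. `z_alpha` is one-sided by default (the hypothesis
#' `rho > p0` is directional); set `one_sided = FALSE` for a two-sided
#' significance level.
#'
#' @param alpha Significance level (default 0.05).
#' @param beta Type II error (default 0.2, i.e. 80% power).
#' @param k Sessions (ratings) per subject, `>= 2`.
#' @param p0 Minimally acceptable ICC, in (0, 1).
#' @param p1 Expected ICC, in (p0, 1).
#' @param one_sided Use a one-sided `z_alpha`?
#' @return Integer subject count, with attribute `meta` recording the
#'   formula variant and inputs.
#' @export
reliability_sample_size <- function(alpha = 0.05, beta = 0.2, k = 2,
                                    p0 = 0.4, p1 = 0.7, one_sided = TRUE) {
  if (!(p0 > 0 && p0 < p1 && p1 < 1)) {
    stop("need 0 < p0 < p1 < 1", call. = FALSE)
  }
  if (k < 2) stop("need k >= 2 sessions", call. = FALSE)
  za <- stats::qnorm(1 - if (one_sided) alpha else alpha / 2)
  zb <- stats::qnorm(1 - beta)
  c0 <- (1 + k * p0 / (1 - p0)) / (1 + k * p1 / (1 - p1))
  n <- 1 + 2 * k * (za + zb)^2 / ((k - 1) * log(c0)^2)
  out <- as.integer(ceiling(n))
  attr(out, "meta") <- list(
    method = "Walter-Eliasziw-Donner variance approximation",
    sided = if (one_sided) "one-sided" else "two-sided",
    alpha = alpha, beta = beta, k = k, p0 = p0, p1 = p1, n_exact = n
  )
  out
}
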