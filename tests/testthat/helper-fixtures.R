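# Shared fixtures: tiny grids and noise-free simulation configs.

tiny_grid <- function(side = "right") {
  # 3 x 3 lattice, unit areas
  g <- expand.grid(x = 1:3, z = 10:12)
  sensel_grid(g$x, g$z, rep(1, 9), side = side)
}

noiseless_config <- function(seed = 1, ...) {
  simulation_config(
    seed = seed,
    noise_sd_plate_n = 0, noise_sd_cop_cm = 0, noise_sd_insole_kpa = 0,
    ...
  )
}

# Truth waveform decimated to the plate rate (integer factor).
truth_at_plate_rate <- function(truth, plate_rate = 1000) {
  step <- truth$rate / plate_rate
  idx <- seq(1, length(truth$vgrf_n), by = step)
  list(
    vgrf = truth$vgrf_n[idx],
    marks = (truth$cycle_marks - 1) / step + 1
  )
}

# Double-loop sums-of-squares oracle for the two-way ANOVA, kept
# deliberately naive and independent of the package implementation.
anova_ms_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (m[i, j] - grand)^2
  list(
    ms_rows = ss_rows / (n - 1),
    ms_cols = ss_cols / (k - 1),
    ms_error = (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  )
}

icc_oracle <- function(m) {
  ms <- anova_ms_oracle(m)
  k <- ncol(m)
  (ms$ms_rows - ms$ms_error) / (ms$ms_rows + (k - 1) * ms$ms_error)
}
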