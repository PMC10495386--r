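#' Per-activity segmentation parameters
#'
#' Extremum-detector settings used by the pipelines. Defaults:
#' prominence threshold 10% of the signal range, 0.4 s minimum
#' extremum separation. The tolerated fraction of undefined COP
#' samples per cycle is 20% for ground-contact activities; walking and
#' stair ambulation legitimately unload the foot for roughly a third
#' of every cycle (swing), so their COP gap allowance is raised to
#' 45% rather than discarding every gait cycle.
#'
#' @param activity See [activity_polarity()].
#' @param min_prominence,min_separation_s,max_gap_fraction Overrides.
#' @return A list with the three settings.
#' @export
segmentation_params <- function(activity, min_prominence = 0.1,
                                min_separation_s = 0.4,
                                max_gap_fraction = NULL) {
  activity <- match.arg(activity, ACTIVITIES)
  if (is.null(max_gap_fraction)) {
    max_gap_fraction <-
      if (activity %in% c("walk", "stair_ascent", "stair_descent")) 0.45 else 0.2
  }
  list(min_prominence = min_prominence, min_separation_s = min_separation_s,
       max_gap_fraction = max_gap_fraction)
}

.provenance <- function(spec, alpha_norm = 0.05) {
  list(
    package = "insoleval",
    version = as.character(utils::packageVersion("insoleval")),
    filter = list(cutoff_hz = spec$cutoff_hz, order = spec$order,
                  zero_phase = spec$zero_phase),
    resampling = "polyphase FIR (signal::resample); COP channels linear with gap exclusion",
    quantile_rule = "type 7 (linear interpolation)",
    icc_model = "two-way random effects, consistency, single measures",
    loa_multipliers = c(normal = 1.96, nonnormal_iqr = 1.45),
    icc_bands = c(excellent = 0.75, fair_to_high = 0.4),
    alpha_norm = alpha_norm
  )
}

#' Agreement experiment: insoles vs force plates
#'
#' Runs the full between-system comparison over a batch of paired
#' trials: each trial is synchronized ([synchronize_pair()]), segmented
#' into movement cycles, and summarized as per-channel range values
#' ([participant_outcomes()]); per participant the available feet are
#' averaged ([combine_feet()]); and per activity and channel the two
#' systems are compared with [bland_altman()]. Individual trial
#' failures are logged and excluded, never fatal to the batch.
#'
#' @param trials List of trials; each a list with elements
#'   `participant`, `foot` (`"left"`/`"right"`), `activity`, `insole`
#'   (an [insole_recording()]), `plate` (a [force_plate_recording()])
#'   and `anchor` (a [sync_anchor()]).
#' @param spec A [filter_spec()].
#' @param alpha_norm Normality-branch significance level.
#' @param load_floor_n COP load floor, N.
#' @param min_pairs Minimum complete pairs per outcome (default 4).
#' @return A list of class `run_report` with data frames `outcomes`
#'   (participant-level ranges), `agreement` (one row per activity x
#'   channel), `exclusions`, and a `provenance` list.
#' @export
run_agreement <- function(trials, spec = filter_spec(), alpha_norm = 0.05,
                          load_floor_n = 10, min_pairs = 4) {
  rows <- list()
  excl <- list()
  for (tr in trials) {
    res <- tryCatch({
      synced <- synchronize_pair(tr$insole, tr$plate, tr$anchor, spec,
                                 activity = tr$activity,
                                 load_floor_n = load_floor_n)
      sp <- segmentation_params(tr$activity)
      out_i <- participant_outcomes(synced$insole, tr$activity, synced$rate,
                                    sp$min_prominence, sp$min_separation_s,
                                    sp$max_gap_fraction)
      out_p <- participant_outcomes(synced$plate, tr$activity, synced$rate,
                                    sp$min_prominence, sp$min_separation_s,
                                    sp$max_gap_fraction)
      list(insole = out_i, plate = out_p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        participant = tr$participant, activity = tr$activity, foot = tr$foot,
        code = .exclusion_code(conditionMessage(res)),
        reason = conditionMessage(res)
      )
      next
    }
    for (sys in names(res)) {
      o <- res[[sys]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant = tr$participant, activity = tr$activity, foot = tr$foot,
        system = sys, channel = names(o$ranges), range = unname(o$ranges),
        n_cycles = unname(o$n_cycles_used), row.names = NULL
      )
    }
  }
  outcomes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant = character(0), activity = character(0),
               foot = character(0), system = character(0),
               channel = character(0), range = numeric(0),
               n_cycles = integer(0))
  agreement <- .agreement_table(outcomes, alpha_norm, min_pairs)
  structure(
    list(outcomes = outcomes, agreement = agreement,
         exclusions = if (length(excl)) do.call(rbind, excl) else
           data.frame(participant = character(0), activity = character(0),
                      foot = character(0), code = character(0),
                      reason = character(0)),
         provenance = .provenance(spec, alpha_norm)),
    class = "run_report"
  )
}

.exclusion_code <- function(msg) {
  if (grepl("sync|anchor|duration|overlap", msg, ignore.case = TRUE)) "sync_fail"
  else if (grepl("cycle|segmentation", msg, ignore.case = TRUE)) "too_few_cycles"
  else "no_fit"
}

# Per activity x channel: combine feet per participant and system, then
# Bland-Altman of insole vs plate.
.agreement_table <- function(outcomes, alpha_norm, min_pairs) {
  res <- list()
  channels <- c("vgrf_n", "cop_ml_cm", "cop_ap_cm")
  for (act in unique(outcomes$activity)) {
    for (ch in channels) {
      sub <- outcomes[outcomes$activity == act & outcomes$channel == ch, ]
      if (nrow(sub) == 0L) next
      ids <- sort(unique(sub$participant))
      per_system <- lapply(c("insole", "plate"), function(sys) {
        vapply(ids, function(id) {
          s <- sub[sub$participant == id & sub$system == sys, ]
          lf <- s$range[s$foot == "left"]
          rt <- s$range[s$foot == "right"]
          combine_feet(if (length(lf)) lf[1] else NA_real_,
                       if (length(rt)) rt[1] else NA_real_)$value
        }, numeric(1))
      })
      ok <- is.finite(per_system[[1]]) & is.finite(per_system[[2]])
      if (sum(ok) < min_pairs) next
      ba <- bland_altman(
        paired_samples(per_system[[1]][ok], per_system[[2]][ok],
                       labels = ids[ok], unit = ch),
        alpha_norm = alpha_norm
      )
      res[[length(res) + 1L]] <- data.frame(
        activity = act, channel = ch, n = ba$n, variant = ba$variant,
        center = ba$center, loa_lower = ba$loa_lower,
        loa_upper = ba$loa_upper, t_p = ba$t_p, ks_p = ba$ks_p
      )
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(activity = character(0), channel = character(0),
               n = integer(0), variant = character(0), center = numeric(0),
               loa_lower = numeric(0), loa_upper = numeric(0),
               t_p = numeric(0), ks_p = numeric(0))
}

#' Test-retest reliability experiment
#'
#' Computes per-channel range outcomes for each participant in two
#' sessions (insole recordings only), then per activity, foot and
#' channel forms the subjects-by-sessions matrix (listwise deletion of
#' participants missing either session), and reports the consistency
#' ICC with its F-based 95% CI, the qualitative label, and the SEM.
#'
#' @param session1,session2 Lists of trials; each trial a list with
#'   `participant`, `foot`, `activity`, `insole` (an
#'   [insole_recording()]).
#' @param spec A [filter_spec()].
#' @param load_floor_n COP load floor, N.
#' @param min_subjects Minimum subjects per ICC (default 3).
#' @return A list of class `run_report` with data frames `outcomes`,
#'   `reliability` (activity, foot, channel, icc, ci, label, sem, n),
#'   `exclusions`, and `provenance`.
#' @export
run_reliability <- function(session1, session2, spec = filter_spec(),
                            load_floor_n = 10, min_subjects = 3) {
  per_session <- lapply(list(session1, session2), function(trials) {
    rows <- list()
    excl <- list()
    for (tr in trials) {
      res <- tryCatch({
        ch <- derive_channels(tr$insole, load_floor_n = load_floor_n)
        filt <- derived_channels(
          ch$t_s,
          pmax(lowpass_filter(ch$vgrf_n, tr$insole$nominal_rate, spec), 0),
          lowpass_filter(ch$peak_pressure_kpa, tr$insole$nominal_rate, spec),
          filter_with_gaps(ch$cop_ml_cm, tr$insole$nominal_rate, spec),
          filter_with_gaps(ch$cop_ap_cm, tr$insole$nominal_rate, spec),
          rate = tr$insole$nominal_rate
        )
        sp <- segmentation_params(tr$activity)
        participant_outcomes(filt, tr$activity, tr$insole$nominal_rate,
                             sp$min_prominence, sp$min_separation_s,
                             sp$max_gap_fraction)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        excl[[length(excl) + 1L]] <- data.frame(
          participant = tr$participant, activity = tr$activity, foot = tr$foot,
          code = .exclusion_code(conditionMessage(res)),
          reason = conditionMessage(res)
        )
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = tr$participant, activity = tr$activity, foot = tr$foot,
        channel = names(res$ranges), range = unname(res$ranges),
        n_cycles = unname(res$n_cycles_used), row.names = NULL
      )
    }
    list(rows = rows, excl = excl)
  })
  outcomes <- do.call(rbind, c(
    lapply(seq_along(per_session), function(s) {
      if (length(per_session[[s]]$rows)) {
        d <- do.call(rbind, per_session[[s]]$rows)
        d$session <- s
        d
      }
    })
  ))
  excl <- do.call(rbind, c(lapply(per_session, `[[`, "excl"),
                           make.row.names = FALSE))
  rel <- list()
  if (!is.null(outcomes)) {
    combos <- unique(outcomes[, c("activity", "foot", "channel")])
    for (j in seq_len(nrow(combos))) {
      act <- combos$activity[j]; ft <- combos$foot[j]; ch <- combos$channel[j]
      sub <- outcomes[outcomes$activity == act & outcomes$foot == ft &
                        outcomes$channel == ch, ]
      ids <- sort(unique(sub$participant))
      m <- t(vapply(ids, function(id) {
        c(s1 = sub$range[sub$participant == id & sub$session == 1][1],
          s2 = sub$range[sub$participant == id & sub$session == 2][1])
      }, numeric(2)))
      m <- m[stats::complete.cases(m), , drop = FALSE]
      if (nrow(m) < min_subjects) next
      icc <- tryCatch(icc_consistency(m), error = function(e) NULL)
      if (is.null(icc)) next
      sem <- sem_from(m, icc$icc)
      rel[[length(rel) + 1L]] <- data.frame(
        activity = act, foot = ft, channel = ch, n = nrow(m),
        icc = icc$icc, ci_lower = icc$ci_lower, ci_upper = icc$ci_upper,
        label = icc$label, sem = sem$sem
      )
    }
  }
  structure(
    list(
      outcomes = outcomes %||% data.frame(),
      reliability = if (length(rel)) do.call(rbind, rel) else
        data.frame(activity = character(0), foot = character(0),
                   channel = character(0), n = integer(0), icc = numeric(0),
                   ci_lower = numeric(0), ci_upper = numeric(0),
                   label = character(0), sem = numeric(0)),
      exclusions = excl %||% data.frame(),
      provenance = .provenance(spec)
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$agreement) && nrow(x$agreement)) {
    cat("agreement (Bland-Altman):\n")
    print(x$agreement, digits = 4, row.names = FALSE)
  }
  if (!is.null(x$reliability) && nrow(x$reliability)) {
    cat("reliability (ICC / SEM):\n")
    print(x$reliability, digits = 4, row.names = FALSE)
  }
  if (!is.null(x$exclusions) && nrow(x$exclusions)) {
    cat(nrow(x$exclusions), "exclusion(s):\n")
    print(x$exclusions[, c("participant", "activity", "foot", "code")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a run report's tables to CSV
#'
#' Exports the tables of a [run_agreement()] or [run_reliability()]
#' report (`agreement` and/or `reliability`, plus `outcomes` and
#' `exclusions`) as CSV files, and the provenance block as JSON.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (tab in c("agreement", "reliability", "outcomes", "exclusions")) {
    d <- report[[tab]]
    if (is.null(d) || nrow(d) == 0L) next
    p <- file.path(dir, paste0(tab, ".csv"))
    utils::write.csv(d, p, row.names = FALSE, quote = FALSE, na = "")
    paths <- c(paths, p)
  }
  pj <- file.path(dir, "provenance.json")
  jsonlite::write_json(report$provenance, pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}

#' Simulate a cohort for the agreement experiment
#'
#' Renders paired insole/plate trials for `n_subjects`, with
#' between-subject variation in body weight, for the agreement
#' activities (squat, jump, sit-to-stand by default).
#'
#' @param n_subjects Cohort size.
#' @param activities Activities to render.
#' @param feet `"both"` or `"right"`.
#' @param cfg Base [simulation_config()]; per-subject seeds and body
#'   weights are derived from it (body weight N(cfg mean, 80^2),
#'   truncated at 450 N).
#' @param bw_sd_n Between-subject body-weight SD, N.
#' @return A list of trials suitable for [run_agreement()].
#' @export
simulate_agreement_study <- function(n_subjects,
                                     activities = c("squat", "jump", "sit_to_stand"),
                                     feet = c("both", "right"),
                                     cfg = simulation_config(),
                                     bw_sd_n = 80) {
  feet <- match.arg(feet)
  sides <- if (feet == "both") c("left", "right") else "right"
  set.seed(cfg$seed)
  bw <- pmax(stats::rnorm(n_subjects, cfg$body_weight_n, bw_sd_n), 450)
  grids <- lapply(sides, default_sensel_grid)
  names(grids) <- sides
  trials <- list()
  for (s in seq_len(n_subjects)) {
    for (act in activities) {
      for (side in sides) {
        cfg_s <- cfg
        cfg_s$seed <- cfg$seed + 1000L * s + 10L * match(act, ACTIVITIES) +
          match(side, c("left", "right"))
        cfg_s$body_weight_n <- bw[s]
        tr <- simulate_trial(act, cfg_s, grids[[side]])
        trials[[length(trials) + 1L]] <- list(
          participant = sprintf("P%02d", s), foot = side, activity = act,
          insole = tr$insole, plate = tr$plate, anchor = tr$anchor
        )
      }
    }
  }
  trials
}

#' Simulate a two-session cohort for the reliability experiment
#'
#' Renders insole-only trials for two sessions with a controlled
#' compound-symmetry structure on the per-subject waveform amplitude:
#' subject `i` in session `j` scales body weight and COP amplitudes by
#' `1 + b_i + w_ij` with `b_i ~ N(0, var_between)`,
#' `w_ij ~ N(0, var_within)`, so the population ICC of any
#' amplitude-proportional range outcome is approximately
#' `var_between / (var_between + var_within)`.
#'
#' @param n_subjects Cohort size.
#' @param activities Activities to render.
#' @param cfg Base [simulation_config()].
#' @param var_between,var_within Variance components of the relative
#'   amplitude factor (defaults 0.018 and 0.002, population ICC 0.9).
#' @param side Foot to render (default right).
#' @return A list with `session1` and `session2` trial lists for
#'   [run_reliability()], and `true_icc`.
#' @export
simulate_reliability_study <- function(n_subjects, activities = "squat",
                                       cfg = simulation_config(),
                                       var_between = 0.018, var_within = 0.002,
                                       side = "right") {
  set.seed(cfg$seed + 7L)
  b <- stats::rnorm(n_subjects, 0, sqrt(var_between))
  w <- matrix(stats::rnorm(2 * n_subjects, 0, sqrt(var_within)), ncol = 2)
  grid <- default_sensel_grid(side)
  sessions <- lapply(1:2, function(sess) {
    trials <- list()
    for (s in seq_len(n_subjects)) {
      for (act in activities) {
        cfg_s <- cfg
        cfg_s$seed <- cfg$seed + 5000L * sess + 100L * s + match(act, ACTIVITIES)
        scale <- max(1 + b[s] + w[s, sess], 0.3)
        cfg_s$body_weight_n <- cfg$body_weight_n * scale
        truth <- make_truth_waveform(act, cfg_s)
        # scale COP excursions about their centre by the same factor
        truth$cop_ml_cm <- cfg$cop_center_cm[1] +
          (truth$cop_ml_cm - cfg$cop_center_cm[1]) * scale
        truth$cop_ap_cm <- cfg$cop_center_cm[2] +
          (truth$cop_ap_cm - cfg$cop_center_cm[2]) * scale
        trials[[length(trials) + 1L]] <- list(
          participant = sprintf("P%02d", s), foot = side, activity = act,
          insole = render_insole(truth, grid, cfg_s)
        )
      }
    }
    trials
  })
  list(session1 = sessions[[1]], session2 = sessions[[2]],
       true_icc = var_between / (var_between + var_within))
}
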