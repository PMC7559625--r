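#' Build the trial table with analysis windows from triggers
#'
#' Trigger codes follow the session convention: reference onset
#' `10*task + cond` (task AN = 1, SG = 2; external = 1, internal = 2),
#' activation onset `100 + code`, response onset `200 + code`. The
#' reference analysis window discards the first and last 500 ms of the 5 s
#' fixation period (`[ref_on + 0.5, ref_on + 4.5)`, 4 s usable); the
#' activation analysis window starts 1.5 s after stimulus onset (1 s after
#' conditional stimulus masking) and runs to the end of stimulus
#' presentation (`[act_on + 1.5, act_on + 20)`, 18.5 s).
#'
#' @param triggers Tibble with `time`, `code`.
#' @param ref_dur,act_dur Phase durations (s).
#' @param ref_trim Seconds trimmed from each end of the reference phase.
#' @param act_skip Seconds skipped after stimulus onset.
#' @return Tibble: `index`, `task`, `condition`, `ref_on`, `act_on`,
#'   `resp_on`, and the analysis windows `ref_win_lo/hi`, `act_win_lo/hi`.
#' @export
build_trials <- function(triggers, ref_dur = 5, act_dur = 20,
                         ref_trim = 0.5, act_skip = 1.5) {
  tr <- triggers[triggers$code >= 11 & triggers$code <= 222, ]
  tr <- tr[order(tr$time), ]
  phase <- ifelse(tr$code >= 200, "resp", ifelse(tr$code >= 100, "act", "ref"))
  base <- tr$code %% 100
  refs <- which(phase == "ref")
  out <- vector("list", length(refs))
  for (k in seq_along(refs)) {
    i <- refs[k]
    if (i + 2 > nrow(tr) || phase[i + 1] != "act" || phase[i + 2] != "resp" ||
        base[i + 1] != base[i] || base[i + 2] != base[i]) {
      stop("malformed trigger sequence at trial ", k)
    }
    out[[k]] <- tibble::tibble(
      index = k,
      task = ifelse(base[i] %/% 10 == 1, "AN", "SG"),
      condition = ifelse(base[i] %% 10 == 2, "internal", "external"),
      ref_on = tr$time[i], act_on = tr$time[i + 1], resp_on = tr$time[i + 2]
    )
  }
  d <- dplyr::bind_rows(out)
  d$ref_win_lo <- d$ref_on + ref_trim
  d$ref_win_hi <- d$ref_on + ref_dur - ref_trim
  d$act_win_lo <- d$act_on + act_skip
  d$act_win_hi <- d$act_on + act_dur
  d
}

#' Trial-level validity
#'
#' A trial enters analysis iff the response was correct, the reference
#' window retains *more than* `min_ref_s` seconds of artifact-free data
#' (strict, "more than 500 ms"), and at least `min_act_frac` of the
#' activation window is artifact-free (inclusive, mirroring the "=3/9"
#' reading of the 33% participant rule).
#'
#' @param correct Logical.
#' @param ref_valid_s Artifact-free seconds in the reference window.
#' @param act_valid_fraction Artifact-free fraction of the activation
#'   window.
#' @param min_ref_s,min_act_frac Thresholds (0.5 s; 1/3).
#' @return Logical vector.
#' @export
trial_validity <- function(correct, ref_valid_s, act_valid_fraction,
                           min_ref_s = 0.5, min_act_frac = 1 / 3) {
  as.logical(correct) & ref_valid_s > min_ref_s &
    act_valid_fraction >= min_act_frac
}

#' Participant-level validity
#'
#' A participant is retained iff every task x condition cell holds at
#' least `min_per_cell` valid trials (33% of 9) and at least `min_correct`
#' trials were answered correctly overall (50% of 36).
#'
#' @param trials Tibble with columns `task`, `condition`, `correct`,
#'   `valid`.
#' @param min_per_cell,min_correct Inclusion minima.
#' @return Logical flag.
#' @export
participant_validity <- function(trials, min_per_cell = 3, min_correct = 18) {
  cells <- expand.grid(task = unique(trials$task),
                       condition = unique(trials$condition),
                       stringsAsFactors = FALSE)
  per_cell <- vapply(seq_len(nrow(cells)), function(i) {
    sum(trials$valid & trials$task == cells$task[i] &
          trials$condition == cells$condition[i])
  }, numeric(1))
  all(per_cell >= min_per_cell) && sum(trials$correct) >= min_correct
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise alpha (default 0.05).
#' @param m Number of tests; `m = 12` gives the 0.00417 threshold of the
#'   per-parameter eye analyses, `m = 40` the 0.00125 threshold of the
#'   rest covariation matrix.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' Flag p values against a threshold (strict)
#' @param p Numeric p values.
#' @param threshold Per-test threshold.
#' @return Logical vector, `TRUE` where `p < threshold`.
#' @export
bonferroni_flag <- function(p, threshold) !is.na(p) & p < threshold

#' Per-trial TRP and oculometric features for one subject
#'
#' The per-subject workhorse: conditions the EEG, computes alpha power by
#' complex demodulation, builds the coregistration artifact mask (extended
#' blink windows, padded saccades, manual intervals), conditions the eye
#' series (binocular pupil average, z-scored over the task period;
#' vergence angle), detects micro/saccades at the native rate, and then
#' extracts, per trial, the TRP per electrode and the twelve oculometric
#' parameters over the activation window plus the validity bookkeeping.
#'
#' @param rec A [coreg_recording()].
#' @param trials Trial metadata tibble (needs `index`, `task`,
#'   `condition`, `correct`) whose rows match [build_trials()] output by
#'   index, or `NULL` to derive windows purely from triggers.
#' @param band Alpha band `c(center, halfband)` (Hz).
#' @param min_valid Minimum samples for a power mean (see [mean_power()]).
#' @return List with `trials` (per-trial features + validity) and `trp`
#'   (long per-electrode table: subject, trial, electrode, ref_mean,
#'   act_mean, trp).
#' @export
trial_features <- function(rec, trials, band = c(10.5, 2.0), min_valid = 10) {
  subject <- rec$meta$subject %||% "s01"
  duration <- recording_duration(rec)
  windows <- build_trials(rec$triggers)
  tinfo <- if (is.null(trials)) {
    dplyr::mutate(windows, correct = TRUE)
  } else {
    dplyr::left_join(windows, trials[, c("index", "correct")], by = "index")
  }

  cond <- preprocess_eeg(rec)
  pow <- alpha_power(cond, center = band[1], halfband = band[2])
  eeg_mask <- build_eeg_mask(
    blinks = rec$events$blink %||% interval_set(),
    saccades = rec$events$saccade %||% interval_set(),
    manual = rec$events$manual %||% interval_set(),
    duration = duration, rate = 100
  )

  task_span <- c(min(tinfo$ref_on), max(tinfo$resp_on) + 6)
  eye <- condition_eye(rec, scope = task_span)
  combined <- mask_and(eeg_mask, eye$eye_mask)

  trp_rows <- list()
  feat_rows <- list()
  for (i in seq_len(nrow(tinfo))) {
    ref_w <- c(tinfo$ref_win_lo[i], tinfo$ref_win_hi[i])
    act_w <- c(tinfo$act_win_lo[i], tinfo$act_win_hi[i])
    ref_valid_s <- valid_fraction(combined, ref_w) * diff(ref_w)
    act_frac <- valid_fraction(combined, act_w)
    pm <- vapply(names(pow), function(ch) {
      c(mean_power(pow[[ch]], eeg_mask, ref_w, min_valid),
        mean_power(pow[[ch]], eeg_mask, act_w, min_valid))
    }, numeric(2))
    trp_rows[[i]] <- tibble::tibble(
      subject = subject, trial = tinfo$index[i],
      electrode = colnames(pm),
      ref_mean = pm[1, ], act_mean = pm[2, ],
      trp = trp(pm[2, ], pm[1, ])
    )
    feat_rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(subject = subject, index = tinfo$index[i],
                     task = tinfo$task[i], condition = tinfo$condition[i],
                     correct = tinfo$correct[i],
                     ref_valid_s = ref_valid_s,
                     act_valid_fraction = act_frac),
      window_features(eye$pd_z, eye$aoev_ts, eye$events, act_w)
    )
  }
  feats <- dplyr::bind_rows(feat_rows)
  feats$valid <- trial_validity(feats$correct, feats$ref_valid_s,
                                feats$act_valid_fraction)
  list(trials = feats, trp = dplyr::bind_rows(trp_rows))
}

# Shared eye-side conditioning: pupil (z), vergence, detector events,
# fixations, and the 100 Hz eye validity mask.
condition_eye <- function(rec, scope = NULL) {
  pd_raw <- pupil_diameter(rec$eye$pl, rec$eye$pr)
  pd100 <- suppressWarnings(block_downsample(pd_raw, pd_raw$rate / 100))
  scope_idx <- if (!is.null(scope)) ts_window_idx(pd100, scope)
  pd_z <- condition_series(pd100, scope_idx)
  gl <- gaze_to_deg(rec$eye$xl, rec$eye$yl, rec$geometry)
  gr <- gaze_to_deg(rec$eye$xr, rec$eye$yr, rec$geometry)
  av <- aoev(rec$eye$xl, rec$eye$yl, rec$eye$xr, rec$eye$yr, rec$geometry)
  av100 <- suppressWarnings(block_downsample(av, av$rate / 100))

  det_l <- suppressWarnings(engbert_detect(gl$x, gl$y))
  det_r <- suppressWarnings(engbert_detect(gr$x, gr$y))
  bino <- classify_saccadic(binocular_combine(det_l, det_r))
  blinks <- rec$events$blink %||%
    dropout_blinks(rec$eye$pl, rec$eye$pr)
  na_runs <- dropout_blinks(rec$eye$pl, rec$eye$pr, min_dur = 0)
  span <- c(0, ts_duration(rec$eye$xl))
  fixations <- derive_fixations(span, blinks, bino, na_runs,
                                rate = rec$eye$xl$rate)
  eye_mask <- binary_mask(!is.na(pd_z$values), 100, pd_z$start)
  list(pd_z = pd_z, aoev_ts = av100,
       events = list(
         blinks = blinks,
         saccades = bino[bino$kind == "saccade", ],
         microsaccades = bino[bino$kind == "microsaccade", ],
         fixations = fixations),
       eye_mask = eye_mask)
}

#' Attention/task ANOVAs over a multi-subject feature set
#'
#' Applies participant-level inclusion, collapses valid trials to subject
#' cell means and runs: the 2 x 2 x 2 x 5 TRP ANOVA (ATTENTION x TASK x
#' HEMISPHERE x AREA, electrodes aggregated topographically), the
#' reference- and activation-period log-power control ANOVAs on the same
#' design, and a 2 x 2 ANOVA per oculometric parameter with the
#' Bonferroni-corrected (0.05/12) attention threshold.
#'
#' @param features List of [trial_features()] results (one per subject).
#' @param grouping See [electrode_grouping()].
#' @param alpha Family-wise alpha for the eye parameters.
#' @return List: `trp_anova`, `act_power_anova`, `ref_power_anova`,
#'   `eye_anova` (per parameter x effect with `significant` flag at
#'   `alpha/12`), `included_subjects`, `eye_threshold`.
#' @export
attention_task_analysis <- function(features, grouping = electrode_grouping(),
                                    alpha = 0.05) {
  keep <- vapply(features, function(f) participant_validity(f$trials),
                 logical(1))
  if (sum(keep) < 2) stop("fewer than 2 valid participants")
  features <- features[keep]

  trials <- dplyr::bind_rows(lapply(features, `[[`, "trials"))
  trp_long <- dplyr::bind_rows(lapply(features, `[[`, "trp"))
  meta <- trials[, c("subject", "index", "task", "condition", "valid")]
  trp_long <- dplyr::inner_join(trp_long, meta,
                                by = c("subject", "trial" = "index"))
  trp_long <- trp_long[trp_long$valid, ]
  trp_long <- dplyr::inner_join(trp_long, grouping,
                                by = c("electrode" = "electrode"))

  region_cells <- function(col) {
    trp_long |>
      dplyr::group_by(.data$subject, .data$condition, .data$task,
                      .data$hemisphere, .data$region) |>
      dplyr::summarise(value = mean(.data[[col]], na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::rename(attention = "condition", area = "region")
  }
  trp_long$log_act <- log1p(trp_long$act_mean)
  trp_long$log_ref <- log1p(trp_long$ref_mean)
  within4 <- c("attention", "task", "hemisphere", "area")
  trp_anova <- rm_anova(region_cells("trp"), within = within4)
  act_anova <- rm_anova(region_cells("log_act"), within = within4)
  ref_anova <- rm_anova(region_cells("log_ref"), within = within4)

  eye_params <- c("pd_mean", "pd_var", "aoev_mean", "aoev_var",
                  "fixation_count", "fixation_duration_mean",
                  "saccade_count", "saccade_amplitude_mean",
                  "microsaccade_count", "microsaccade_amplitude_mean",
                  "blink_count", "blink_duration_mean")
  thr <- bonferroni_threshold(alpha, length(eye_params))
  valid_trials <- trials[trials$valid, ]
  eye_anova <- dplyr::bind_rows(lapply(eye_params, function(pp) {
    cells <- valid_trials |>
      dplyr::group_by(.data$subject, .data$condition, .data$task) |>
      dplyr::summarise(value = mean(.data[[pp]], na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::rename(attention = "condition")
    res <- tryCatch(
      rm_anova(cells, within = c("attention", "task")),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    res$parameter <- pp
    res
  }))
  eye_anova$significant <- bonferroni_flag(eye_anova$p, thr)

  list(trp_anova = trp_anova, act_power_anova = act_anova,
       ref_power_anova = ref_anova, eye_anova = eye_anova,
       included_subjects = vapply(features, function(f) f$trials$subject[1],
                                  character(1)),
       eye_threshold = thr)
}

#' Condition means and standard errors per task x condition
#'
#' Subject-level means over valid trials first, then grand mean and
#' `SE = SD / sqrt(n)` across subjects (SE missing when `n = 1`).
#'
#' @param trials Combined per-trial feature tibble (with `valid`).
#' @param params Character vector of feature columns to summarize.
#' @return Tibble: `parameter`, `task`, `condition`, `n`, `mean`, `se`.
#' @export
summarize_conditions <- function(trials,
                                 params = c("pd_mean", "microsaccade_count")) {
  vt <- trials[trials$valid, ]
  dplyr::bind_rows(lapply(params, function(pp) {
    vt |>
      dplyr::group_by(.data$subject, .data$task, .data$condition) |>
      dplyr::summarise(value = mean(.data[[pp]], na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::group_by(.data$task, .data$condition) |>
      dplyr::summarise(
        parameter = pp, n = dplyr::n(), mean = mean(.data$value),
        se = if (dplyr::n() > 1) {
          stats::sd(.data$value) / sqrt(dplyr::n())
        } else NA_real_,
        .groups = "drop")
  }))
}

#' Within-trial condition time course of a continuous series
#'
#' Bins a series into `resolution`-second steps of within-trial time
#' (from stimulus onset) and averages across trials per condition.
#'
#' @param series A [time_series()] (e.g. occipital power or pupil z).
#' @param trials Trial tibble with `act_on`, `condition` (and optionally
#'   `valid`).
#' @param dur Trial-phase length to cover (s, default 20).
#' @param resolution Bin width (s).
#' @return Tibble: `condition`, `time` (bin start, s), `mean`, `se`, `n`.
#' @export
condition_timecourse <- function(series, trials, dur = 20, resolution = 1) {
  if ("valid" %in% names(trials)) trials <- trials[trials$valid, ]
  if (nrow(trials) == 0L) stop("no usable trials")
  bins <- seq(0, dur - resolution, by = resolution)
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    vals <- vapply(bins, function(b) {
      idx <- ts_window_idx(series, trials$act_on[i] + c(b, b + resolution))
      mean(series$values[idx], na.rm = TRUE)
    }, numeric(1))
    tibble::tibble(condition = trials$condition[i], time = bins, value = vals)
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$condition, .data$time) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = stats::sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)), .groups = "drop")
}
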