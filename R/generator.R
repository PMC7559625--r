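#' Configuration for the synthetic coregistration generator
#'
#' Defaults emulate the study design the pipeline targets: a 120 s
#' eyes-open rest period and a task session of 6 blocks x 6 trials (5 s
#' reference, 20 s activation with conditional stimulus masking at 0.5 s,
#' 6 s response; 9 trials per task x condition cell), recorded at 1000 Hz
#' for both EEG and eye tracking.
#'
#' EEG alpha amplitude, pupil diameter and micro/saccade rates are coupled
#' through (a) a two-state latent attention process (internal/external;
#' Markov at rest with mean dwell `state_dwell`, clamped to the condition
#' label during task activation) and (b) a continuous Ornstein-Uhlenbeck
#' arousal latent shared by alpha amplitude (`kappa`) and pupil (`beta`).
#' Independent OU nuisance processes (`kappa_ind`, `beta_ind`) set how much
#' of each signal's variance is *not* shared, which controls the expected
#' rest covariation (see [theoretical_coupling()]).
#'
#' Noise amplitudes are spectral-density referenced (`white_psd`,
#' `pink_psd10` in uV^2/Hz) so in-band signal-to-noise does not depend on
#' the simulation rate.
#'
#' @param n_subjects Number of subjects for study-level helpers.
#' @param rest_duration Rest period length (s).
#' @param n_blocks,trials_per_block Task structure (6 x 6 = 36 trials).
#' @param ref_dur,act_dur,resp_dur,mask_onset,gap_dur,cue_dur Phase
#'   durations (s): reference, activation, response, conditional mask
#'   latency, inter-trial drift-check gap, block-cue length.
#' @param block_order `"ABBAAB"` or `"BAABBA"` (A = anagram, B = sentence
#'   generation).
#' @param eeg_rate,eye_rate Sampling rates (Hz); must be multiples of 100.
#' @param alpha_freq Alpha carrier frequency (Hz).
#' @param alpha_base Baseline alpha amplitude per region (uV), posterior
#'   dominant.
#' @param attention_gain Relative amplitude gain under internal attention
#'   per region (posterior > frontal).
#' @param task_desync Multiplicative alpha amplitude factor during task
#'   activation (< 1: event-related desynchronization).
#' @param kappa,kappa_ind Shared-latent and channel-independent relative
#'   alpha amplitude modulation per unit latent.
#' @param beta,beta_ind Shared-latent and independent pupil modulation
#'   (a.u. per unit latent).
#' @param ou_theta OU mean-reversion rate (1/s) of all continuous latents.
#' @param state_dwell Mean dwell time (s) of the rest attention state.
#' @param pupil_base,pupil_state_gain,pupil_task_gain,pupil_noise_sd Pupil
#'   baseline (a.u.), internal-state offset, sentence-task offset, and
#'   per-sample measurement noise SD.
#' @param white_psd,pink_psd10 EEG background noise: white one-sided PSD
#'   and pink (1/f) PSD at 10 Hz, both uV^2/Hz.
#' @param blink_rate,blink_dur_meanlog,blink_dur_sdlog Binocular blink
#'   Poisson rate (1/s) and lognormal duration parameters.
#' @param ms_rate,sacc_rate Named rates (1/s) per attention state
#'   (`internal`, `external`) for microsaccades and larger saccades;
#'   internal < external.
#' @param ms_amp_meanlog,ms_amp_sdlog Lognormal microsaccade amplitude
#'   (deg; median 0.3).
#' @param sacc_target_sd SD (deg) of the 2-D fixation-target scatter that
#'   macrosaccades jump between.
#' @param main_seq_scale,main_seq_exp Main sequence: peak velocity =
#'   `scale * amplitude^exp` (deg/s); event duration follows from the
#'   raised-cosine profile, clamped to 6-80 ms.
#' @param drift_sd,drift_tau Fixational drift OU SD (deg) and time constant
#'   (s).
#' @param gaze_noise_sd Per-sample, per-eye gaze measurement noise SD (deg).
#' @param verg_sd_mm,verg_tau Fixation-depth OU SD (mm around the screen
#'   plane) and time constant (s), driving vergence variation.
#' @param correct_prob Per-task, per-condition probability of a correct
#'   response.
#' @param time_varying_gain Linear shrink of the attention gain across the
#'   activation phase (0 = constant, 1 = gain decays to zero at phase end).
#'   Off by default.
#' @param geometry See [default_geometry()].
#' @return A validated config list of class `ag_config`.
#' @export
gen_config <- function(n_subjects = 20,
                       rest_duration = 120,
                       n_blocks = 6, trials_per_block = 6,
                       ref_dur = 5, act_dur = 20, resp_dur = 6,
                       mask_onset = 0.5, gap_dur = 1.5, cue_dur = 2,
                       block_order = "ABBAAB",
                       eeg_rate = 1000, eye_rate = 1000,
                       alpha_freq = 10.5,
                       alpha_base = c(AF = 4, F = 5, CT = 6, P = 8, O = 10),
                       attention_gain = c(AF = 0.02, F = 0.05, CT = 0.10,
                                          P = 0.18, O = 0.22),
                       task_desync = 0.75,
                       kappa = 0.25, kappa_ind = 0.45,
                       beta = 50, beta_ind = 110,
                       ou_theta = 0.5,
                       state_dwell = 12,
                       pupil_base = 4000, pupil_state_gain = 120,
                       pupil_task_gain = 60, pupil_noise_sd = 30,
                       white_psd = 0.2, pink_psd10 = 0.3,
                       blink_rate = 0.15,
                       blink_dur_meanlog = log(0.12), blink_dur_sdlog = 0.4,
                       ms_rate = c(internal = 1.0, external = 1.8),
                       sacc_rate = c(internal = 0.08, external = 0.25),
                       ms_amp_meanlog = log(0.3), ms_amp_sdlog = 0.4,
                       sacc_target_sd = 1.2,
                       main_seq_scale = 100, main_seq_exp = 0.7,
                       drift_sd = 0.1, drift_tau = 2,
                       gaze_noise_sd = 0.008,
                       verg_sd_mm = 30, verg_tau = 5,
                       correct_prob = list(
                         AN = c(external = 0.92, internal = 0.86),
                         SG = c(external = 0.86, internal = 0.76)),
                       time_varying_gain = 0,
                       geometry = default_geometry()) {
  cfg <- as.list(environment())
  stopifnot(
    rest_duration > 0, ref_dur > 0, act_dur > 0, resp_dur > 0,
    eeg_rate %% 100 == 0, eye_rate %% 100 == 0,
    ou_theta > 0, state_dwell > 1,
    all(alpha_base > 0), pupil_noise_sd > 0,
    blink_rate >= 0, all(ms_rate >= 0), all(sacc_rate >= 0),
    all(unlist(correct_prob) >= 0), all(unlist(correct_prob) <= 1),
    block_order %in% c("ABBAAB", "BAABBA")
  )
  class(cfg) <- c("ag_config", "list")
  cfg
}

# --- low-level stochastic building blocks ----------------------------------

# Exact-discretization stationary OU with unit stationary variance.
ou_unit <- function(n, dt, theta) {
  a <- exp(-theta * dt)
  innov <- stats::rnorm(n, sd = sqrt(1 - a^2))
  innov[1] <- stats::rnorm(1)  # stationary start
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# Two-state Markov chain ("external"/"internal") sampled on a dt grid.
markov_state <- function(n, dt, dwell) {
  times <- numeric(0)
  t <- 0
  s0 <- sample(c("external", "internal"), 1)
  states <- s0
  while (t < n * dt) {
    t <- t + stats::rexp(1, rate = 1 / dwell)
    times <- c(times, t)
    states <- c(states, ifelse(states[length(states)] == "internal",
                               "external", "internal"))
  }
  idx <- findInterval((seq_len(n) - 1) * dt, times) + 1L
  states[idx]
}

# Real noise with prescribed one-sided PSD S(f) via spectral synthesis.
psd_noise <- function(n, rate, psd_fun) {
  nf <- floor(n / 2)
  f <- (1:nf) * rate / n
  amp <- sqrt(n * psd_fun(f) * rate / 4)
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- z
  if (n %% 2 == 0) spec[nf + 1] <- stats::rnorm(1) * sqrt(n * psd_fun(f[nf]) * rate / 2)
  spec[n:(n - nf + 2)] <- Conj(spec[2:(nf)])
  Re(stats::fft(spec, inverse = TRUE) / n)
}

pink_noise <- function(n, rate, psd10) {
  psd_noise(n, rate, function(f) psd10 * 10 / pmax(f, 0.5))
}

# Poisson event onsets with piecewise-constant rate given per-sample on a
# dt grid (thinning).
poisson_onsets <- function(rate_per_sample_grid, dt) {
  rmax <- max(rate_per_sample_grid)
  if (rmax <= 0) return(numeric(0))
  n <- length(rate_per_sample_grid)
  horizon <- n * dt
  cand <- cumsum(stats::rexp(ceiling(horizon * rmax * 1.5) + 20, rate = rmax))
  cand <- cand[cand < horizon]
  if (length(cand) == 0L) return(numeric(0))
  g <- pmin(floor(cand / dt) + 1L, n)
  keep <- stats::runif(length(cand)) < rate_per_sample_grid[g] / rmax
  cand[keep]
}

main_sequence_duration <- function(amplitude, scale, expo) {
  vpeak <- scale * amplitude^expo
  pmin(pmax(pi * amplitude / (2 * vpeak), 0.006), 0.08)
}

# Raised-cosine position step of unit height over idx grid [0, 1].
smooth_step <- function(m) 0.5 * (1 - cos(pi * seq(0, 1, length.out = m)))

# --- phase schedule --------------------------------------------------------

# Tibble describing what happens when: phase in {rest, gap, cue, reference,
# activation, response}, with task/condition labels for trial phases.
session_schedule <- function(cfg, rng_trials = TRUE) {
  tasks <- strsplit(cfg$block_order, "")[[1]]
  tasks <- ifelse(tasks == "A", "AN", "SG")
  rows <- list()
  t <- 0
  add <- function(phase, dur, task = NA, condition = NA, trial = NA) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      phase = phase, start = t, end = t + dur,
      task = task, condition = condition, trial = trial)
    t <<- t + dur
  }
  add("rest", cfg$rest_duration)
  trial_idx <- 0L
  for (b in seq_len(cfg$n_blocks)) {
    add("cue", cfg$cue_dur, task = tasks[b])
    conds <- sample(rep(c("internal", "external"),
                        length.out = cfg$trials_per_block))
    for (k in seq_len(cfg$trials_per_block)) {
      trial_idx <- trial_idx + 1L
      add("gap", cfg$gap_dur, tasks[b], conds[k], trial_idx)
      add("reference", cfg$ref_dur, tasks[b], conds[k], trial_idx)
      add("activation", cfg$act_dur, tasks[b], conds[k], trial_idx)
      add("response", cfg$resp_dur, tasks[b], conds[k], trial_idx)
    }
  }
  dplyr::bind_rows(rows)
}

# Per-sample phase/condition labels on a dt grid from a schedule.
schedule_labels <- function(schedule, n, dt) {
  tt <- (seq_len(n) - 1) * dt
  i <- findInterval(tt, schedule$start)
  i[i < 1] <- 1L
  list(phase = schedule$phase[i], task = schedule$task[i],
       condition = schedule$condition[i],
       phase_start = schedule$start[i], phase_end = schedule$end[i])
}

# --- core synthesis --------------------------------------------------------

# Shared latents on a 100 Hz grid over `duration` seconds.
gen_latents <- function(duration, cfg) {
  dt <- 0.01
  n <- round(duration / dt)
  list(
    dt = dt, n = n,
    state = markov_state(n, dt, cfg$state_dwell),
    g = ou_unit(n, dt, cfg$ou_theta),
    xi = ou_unit(n, dt, cfg$ou_theta),
    eta = NULL  # filled per channel lazily
  )
}

# Region of a channel label under the default grouping (midline -> own key).
channel_region <- function(ch) {
  g <- electrode_grouping()
  r <- g$region[match(ch, g$electrode)]
  r[is.na(r)] <- "F"  # midline channels carry frontal-like base amplitude
  r
}

# Multiplicative attention factor per sample for a channel's region.
region_mult <- function(region, labels, cfg, tt) {
  gain <- cfg$attention_gain[[region]]
  mult <- rep(1, length(labels$phase))
  internal <- !is.na(labels$condition) & labels$condition == "internal"
  if (cfg$time_varying_gain > 0) {
    prog <- (tt - labels$phase_start) /
      pmax(labels$phase_end - labels$phase_start, 1e-9)
    gain_t <- gain * (1 - cfg$time_varying_gain * prog)
  } else {
    gain_t <- gain
  }
  act <- labels$phase == "activation"
  mult[act] <- cfg$task_desync *
    (1 + (if (length(gain_t) > 1) gain_t[act] else gain_t) *
       internal[act])
  rest <- labels$phase == "rest"
  mult[rest] <- 1 + gain * (labels$state[rest] == "internal")
  mult
}

gen_eeg <- function(duration, cfg, latents, labels) {
  rate <- cfg$eeg_rate
  n <- round(duration * rate)
  up <- rate / 100
  channels <- scalp_channels()
  tt1000 <- (seq_len(n) - 1) / rate
  eeg <- vector("list", length(channels))
  names(eeg) <- channels
  shared_mod <- 1 + cfg$kappa * latents$g
  for (ch in channels) {
    region <- channel_region(ch)
    eta <- ou_unit(latents$n, latents$dt, cfg$ou_theta)
    env100 <- cfg$alpha_base[[region]] *
      region_mult(region, labels, cfg, (seq_len(latents$n) - 1) * latents$dt) *
      pmax(0.05, shared_mod + cfg$kappa_ind * eta)
    env <- rep(env100, each = up)[seq_len(n)]
    phase <- stats::runif(1, 0, 2 * pi)
    carrier <- sin(2 * pi * cfg$alpha_freq * tt1000 + phase)
    noise <- pink_noise(n, rate, cfg$pink_psd10) +
      stats::rnorm(n, sd = sqrt(cfg$white_psd * rate / 2))
    eeg[[ch]] <- time_series(env * carrier + noise, rate, 0, "uV")
  }
  eeg
}

# Blink intervals + saccadic events + per-sample state labels -> eye channels.
gen_eye <- function(duration, cfg, latents, labels) {
  rate <- cfg$eye_rate
  n <- round(duration * rate)
  dt <- 1 / rate
  up <- rate / 100
  geom <- cfg$geometry

  # blinks (binocular by construction)
  bl_on <- sort(stats::runif(stats::rpois(1, cfg$blink_rate * duration),
                             0, duration))
  bl_dur <- stats::rlnorm(length(bl_on), cfg$blink_dur_meanlog,
                          cfg$blink_dur_sdlog)
  blinks <- if (length(bl_on) > 0) {
    merge_intervals(interval_set(bl_on, pmin(bl_on + bl_dur, duration)))
  } else interval_set()

  # state-dependent saccadic rates on the 100 Hz grid
  st <- labels$state_full  # per-sample state incl. task conditions
  ms_rate_grid <- unname(cfg$ms_rate[st])
  sc_rate_grid <- unname(cfg$sacc_rate[st])

  ms_on <- poisson_onsets(ms_rate_grid, latents$dt)
  sc_on <- poisson_onsets(sc_rate_grid, latents$dt)

  ms <- tibble::tibble(
    onset = ms_on,
    amplitude = stats::rlnorm(length(ms_on), cfg$ms_amp_meanlog,
                              cfg$ms_amp_sdlog),
    kind_hint = "micro"
  )
  sc <- tibble::tibble(onset = sc_on, amplitude = NA_real_, kind_hint = "macro")
  ev <- dplyr::arrange(dplyr::bind_rows(ms, sc), .data$onset)

  # resolve macro amplitudes by jumping between scattered fixation targets,
  # then drop events that collide with blinks or each other (30 ms margin)
  cur <- c(0, 0)
  keep <- logical(nrow(ev))
  dirx <- diry <- dur <- amp <- numeric(nrow(ev))
  last_end <- -Inf
  bl_pad <- if (nrow(blinks) > 0) {
    pad_intervals(blinks, pre = 0.03, post = 0.03)
  } else interval_set()
  in_blink <- function(t0, t1) {
    nrow(bl_pad) > 0 && any(t0 < bl_pad$offset & t1 > bl_pad$onset)
  }
  for (i in seq_len(nrow(ev))) {
    if (ev$kind_hint[i] == "macro") {
      target <- stats::rnorm(2, sd = cfg$sacc_target_sd)
      step <- target - cur
      a <- sqrt(sum(step^2))
      if (a < 1.0) next  # too small to count as a tracker saccade; skip
      d <- main_sequence_duration(a, cfg$main_seq_scale, cfg$main_seq_exp)
      u <- step / a
    } else {
      a <- ev$amplitude[i]
      d <- main_sequence_duration(a, cfg$main_seq_scale, cfg$main_seq_exp)
      ang <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(ang), sin(ang))
    }
    t0 <- ev$onset[i]; t1 <- t0 + d
    if (t0 < last_end + 0.03 || t1 > duration || in_blink(t0, t1)) next
    keep[i] <- TRUE
    amp[i] <- a; dur[i] <- d; dirx[i] <- u[1]; diry[i] <- u[2]
    if (ev$kind_hint[i] == "macro") cur <- cur + a * u
    last_end <- t1
  }
  ev <- ev[keep, ]
  ev$amplitude <- amp[keep]; ev$duration <- dur[keep]
  ev$dirx <- dirx[keep]; ev$diry <- diry[keep]
  ev$offset <- ev$onset + ev$duration

  # gaze displacement: accumulate event steps via one cumsum
  dx <- numeric(n); dy <- numeric(n)
  for (i in seq_len(nrow(ev))) {
    i0 <- floor(ev$onset[i] * rate) + 1L
    m <- max(2L, round(ev$duration[i] * rate))
    i1 <- min(i0 + m - 1L, n)
    prof <- diff(c(0, smooth_step(i1 - i0 + 1L))) * ev$amplitude[i]
    dx[i0:i1] <- dx[i0:i1] + prof * ev$dirx[i]
    dy[i0:i1] <- dy[i0:i1] + prof * ev$diry[i]
  }
  dx <- cumsum(dx); dy <- cumsum(dy)

  a_dr <- exp(-dt / cfg$drift_tau)
  drift <- function() cfg$drift_sd * as.numeric(stats::filter(
    { z <- stats::rnorm(n, sd = sqrt(1 - a_dr^2)); z[1] <- stats::rnorm(1); z },
    a_dr, method = "recursive"))
  gx <- dx + drift(); gy <- dy + drift()

  # vergence: fixation depth OU around the screen plane
  depth <- geom$distance_mm +
    cfg$verg_sd_mm * rep(ou_unit(latents$n, latents$dt, 1 / cfg$verg_tau),
                         each = up)[seq_len(n)]
  sep_mm <- geom$ipd_mm * (1 - geom$distance_mm / depth)
  deg_per_px <- atan(geom$pitch_mm / geom$distance_mm) * 180 / pi
  sep_px <- sep_mm / geom$pitch_mm

  cx <- geom$screen_px[1] / 2; cy <- geom$screen_px[2] / 2
  nz <- function() stats::rnorm(n, sd = cfg$gaze_noise_sd / deg_per_px)
  xl <- cx + gx / deg_per_px - sep_px / 2 + nz()
  xr <- cx + gx / deg_per_px + sep_px / 2 + nz()
  yl <- cy - gy / deg_per_px + nz()
  yr <- cy - gy / deg_per_px + nz()

  # pupil: shared latent + state + independent arousal + noise
  st_int <- st == "internal"
  pup100 <- cfg$pupil_base + cfg$pupil_state_gain * st_int +
    cfg$beta * latents$g + cfg$beta_ind * latents$xi
  if (!is.null(labels$task)) {
    sg <- !is.na(labels$task) & labels$task == "SG" &
      labels$phase %in% c("reference", "activation", "response")
    pup100 <- pup100 + cfg$pupil_task_gain * sg
  }
  pup <- rep(pup100, each = up)[seq_len(n)]
  pl <- pup + stats::rnorm(n, sd = cfg$pupil_noise_sd)
  pr <- pup + stats::rnorm(n, sd = cfg$pupil_noise_sd)

  # blank everything during blinks (tracker dropout)
  if (nrow(blinks) > 0) {
    bm <- intervals_to_mask(blinks, rate, duration)
    na_idx <- which(!bm$valid)
    xl[na_idx] <- yl[na_idx] <- xr[na_idx] <- yr[na_idx] <- NA
    pl[na_idx] <- pr[na_idx] <- NA
  }

  gt <- dplyr::bind_rows(
    tibble::tibble(kind = ifelse(ev$amplitude < 1, "microsaccade", "saccade"),
                   onset = ev$onset, offset = ev$offset,
                   amplitude = ev$amplitude),
    tibble::tibble(kind = "blink", onset = blinks$onset,
                   offset = blinks$offset, amplitude = NA_real_)
  ) |> dplyr::arrange(.data$onset)

  macro <- ev[ev$amplitude >= 1, ]
  events <- list(
    blink = if (nrow(blinks) > 0) {
      interval_set(blinks$onset, blinks$offset, "blink")
    } else interval_set(kind = character(0)),
    saccade = if (nrow(macro) > 0) {
      interval_set(macro$onset, macro$offset, "saccade")
    } else interval_set(kind = character(0))
  )

  eye <- list(
    xl = time_series(xl, rate, 0, "px"), yl = time_series(yl, rate, 0, "px"),
    xr = time_series(xr, rate, 0, "px"), yr = time_series(yr, rate, 0, "px"),
    pl = time_series(pl, rate, 0, "a.u."), pr = time_series(pr, rate, 0, "a.u.")
  )
  list(eye = eye, events = events, ground_truth = gt)
}

generate_core <- function(cfg, seed, schedule) {
  set.seed(seed)
  duration <- max(schedule$end)
  latents <- gen_latents(duration, cfg)
  labels <- schedule_labels(schedule, latents$n, latents$dt)
  labels$state <- latents$state
  # per-sample effective state: clamped to condition during activation
  st <- ifelse(labels$phase == "rest", latents$state, "external")
  act <- labels$phase == "activation" & !is.na(labels$condition)
  st[act] <- labels$condition[act]
  labels$state_full <- st
  # alpha/pupil internal-state coupling also follows the clamped state
  labels$condition[labels$phase %in% c("gap", "cue", "reference",
                                       "response")] <- NA
  eeg <- gen_eeg(duration, cfg, latents, labels)
  eyeset <- gen_eye(duration, cfg, latents, labels)
  latent_tab <- tibble::tibble(
    time = (seq_len(latents$n) - 1) * latents$dt,
    latent = latents$g, arousal = latents$xi, state = labels$state_full
  )
  list(duration = duration, latents = latents, labels = labels,
       eeg = eeg, eye = eyeset$eye, events = eyeset$events,
       ground_truth = eyeset$ground_truth, latent_tab = latent_tab)
}

#' Generate a single-subject resting-state bundle
#'
#' Produces a 120 s (by default) eyes-open rest recording: 19-channel EEG
#' whose alpha amplitude follows the latent attention state and arousal
#' process, pink + white background noise, binocular gaze with fixational
#' drift and injected micro/saccades on a main sequence, binocular blinks
#' with pupil dropout, and pupil diameter coupled to the same latent.
#' Ground-truth event and latent tables ride along for validation.
#'
#' @param cfg A [gen_config()].
#' @param seed Integer RNG seed; identical seeds give identical bundles.
#' @param subject Subject identifier string.
#' @return A list with `recording` ([coreg_recording()]), `trials = NULL`,
#'   `ground_truth` and `latent` tibbles.
#' @export
generate_rest <- function(cfg = gen_config(), seed = 1, subject = "s01") {
  if (cfg$rest_duration <= 0) stop("rest duration must be positive")
  schedule <- tibble::tibble(phase = "rest", start = 0,
                             end = cfg$rest_duration,
                             task = NA_character_,
                             condition = NA_character_, trial = NA_integer_)
  core <- generate_core(cfg, seed, schedule)
  triggers <- tibble::tibble(time = c(0, cfg$rest_duration - 1e-3),
                             code = c(250L, 251L))
  rec <- coreg_recording(
    eeg = core$eeg, eye = core$eye, events = core$events,
    triggers = triggers, geometry = cfg$geometry,
    meta = list(subject = subject, seed = seed, referenced = TRUE,
                config = list(rest_duration = cfg$rest_duration,
                              eeg_rate = cfg$eeg_rate,
                              eye_rate = cfg$eye_rate))
  )
  list(recording = rec, trials = NULL,
       ground_truth = core$ground_truth, latent = core$latent_tab)
}

#' Generate a full task session bundle (rest + 36 trials)
#'
#' The session timeline is the rest period followed by 6 task blocks of 6
#' trials (ABBAAB/BAABBA task order; 3 internal + 3 external trials per
#' block in random order). TTL-style triggers mark phase onsets: reference
#' `10*task + cond`, activation `100 + ...`, response `200 + ...` (task AN
#' = 1, SG = 2; external = 1, internal = 2), block cue 9, rest 250/251.
#'
#' @inheritParams generate_rest
#' @return A list with `recording`, `trials` (36-row tibble), and the
#'   generator's `ground_truth` and `latent` tables.
#' @export
generate_session <- function(cfg = gen_config(), seed = 1, subject = "s01") {
  set.seed(seed)
  schedule <- session_schedule(cfg)
  core <- generate_core(cfg, seed + 1L, schedule)

  tr <- schedule[schedule$phase == "reference", ]
  ta <- schedule[schedule$phase == "activation", ]
  rp <- schedule[schedule$phase == "response", ]
  task_id <- ifelse(tr$task == "AN", 1L, 2L)
  cond_id <- ifelse(tr$condition == "internal", 2L, 1L)
  code <- 10L * task_id + cond_id

  words <- c("ROBE", "MAST", "LEAN", "TIDE", "RACE", "NOTE", "STAR", "PALE",
             "LIME", "CORE", "DUNE", "VASE", "MINT", "GLOW", "PEAR", "SALT",
             "WREN", "FERN", "OPAL", "CLAM", "DOVE", "REED", "MOTH", "LARK",
             "SAGE", "IRIS", "NEWT", "KELP", "WOLF", "HARE", "TOAD", "CRAB",
             "SWAN", "MOLE", "LYNX", "IBEX")
  set.seed(seed + 2L)
  correct <- vapply(seq_len(nrow(tr)), function(i) {
    p <- cfg$correct_prob[[tr$task[i]]][[tr$condition[i]]]
    stats::runif(1) < p
  }, logical(1))

  trials <- tibble::tibble(
    index = tr$trial, task = tr$task, condition = tr$condition,
    stimulus = rep_len(words, nrow(tr)),
    ref_on = tr$start, act_on = ta$start, resp_on = rp$start,
    correct = correct
  )

  cue <- schedule[schedule$phase == "cue", ]
  triggers <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(time = c(0, cfg$rest_duration - 1e-3), code = c(250L, 251L)),
    tibble::tibble(time = cue$start, code = 9L),
    tibble::tibble(time = tr$start, code = code),
    tibble::tibble(time = ta$start, code = 100L + code),
    tibble::tibble(time = rp$start, code = 200L + code)
  ), .data$time)

  rec <- coreg_recording(
    eeg = core$eeg, eye = core$eye, events = core$events,
    triggers = triggers, geometry = cfg$geometry,
    meta = list(subject = subject, seed = seed, referenced = TRUE,
                config = list(eeg_rate = cfg$eeg_rate,
                              eye_rate = cfg$eye_rate))
  )
  list(recording = rec, trials = trials,
       ground_truth = core$ground_truth, latent = core$latent_tab)
}

#' Expected rest-segment alpha-power/pupil correlation (simulation oracle)
#'
#' Estimates, per EEG region, the segment-level Pearson correlation between
#' log alpha power and mean pupil diameter that the generator's coupling
#' implies, bypassing the analysis pipeline entirely: the latent processes
#' are simulated for a long run, alpha power and pupil are binned into 1 s
#' segments from their noiseless amplitudes, and measurement noise enters
#' only through analytically derived per-segment variances (band-limited
#' noise power jitter for EEG, mean measurement noise for pupil).
#'
#' @param cfg A [gen_config()].
#' @param duration Simulated run length in seconds (default 2 h).
#' @param seed RNG seed for the long-run simulation.
#' @return Named numeric vector of expected correlations per region
#'   (AF, F, CT, P, O).
#' @export
theoretical_coupling <- function(cfg = gen_config(), duration = 7200,
                                 seed = 1000003L) {
  set.seed(seed)
  dt <- 0.01
  n <- round(duration / dt)
  nseg <- floor(duration)
  seg <- rep(seq_len(nseg), each = round(1 / dt))[seq_len(n)]
  state <- markov_state(n, dt, cfg$state_dwell)
  g <- ou_unit(n, dt, cfg$ou_theta)
  xi <- ou_unit(n, dt, cfg$ou_theta)
  st_int <- state == "internal"
  shared <- 1 + cfg$kappa * g

  # per-segment band-noise power statistics (complex demod, ~4 Hz band)
  band_w <- 4
  p_noise <- band_w * (cfg$white_psd + cfg$pink_psd10 * 10 / cfg$alpha_freq)
  noise_sd <- p_noise / sqrt(band_w * 1)  # SE of 1 s mean of band power

  grouping <- electrode_grouping()
  regions <- unique(grouping$region)
  pup_seg <- as.numeric(tapply(
    cfg$pupil_base + cfg$pupil_state_gain * st_int + cfg$beta * g +
      cfg$beta_ind * xi, seg, mean)) +
    stats::rnorm(nseg, sd = cfg$pupil_noise_sd / sqrt(2 * cfg$eye_rate))

  out <- stats::setNames(numeric(length(regions)), regions)
  for (r in regions) {
    members <- grouping$electrode[grouping$region == r]
    gain <- cfg$attention_gain[[r]]
    logp <- matrix(0, nseg, length(members))
    for (j in seq_along(members)) {
      eta <- ou_unit(n, dt, cfg$ou_theta)
      amp <- cfg$alpha_base[[r]] * (1 + gain * st_int) *
        pmax(0.05, shared + cfg$kappa_ind * eta)
      pow_seg <- as.numeric(tapply(amp^2 / 2, seg, mean)) + p_noise +
        stats::rnorm(nseg, sd = noise_sd)
      logp[, j] <- log1p(pmax(pow_seg, 0))
    }
    out[[r]] <- stats::cor(rowMeans(logp), pup_seg)
  }
  out
}
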