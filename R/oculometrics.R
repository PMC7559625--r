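#' Block-average downsampling for eye data
#'
#' Downsamples by averaging consecutive blocks of `factor` samples (the
#' convention for pupil and vergence series: 1000 Hz -> 100 Hz by averaging
#' 10 samples). A block mean is taken over its non-`NA` members and is `NA`
#' when more than half the block is missing. A trailing partial block is
#' dropped with a warning.
#'
#' @param x A [time_series()].
#' @param factor Positive integer decimation factor (default 10).
#' @return A [time_series()] at `x$rate / factor`.
#' @export
block_downsample <- function(x, factor = 10) {
  if (factor <= 0 || factor != round(factor)) {
    stop("factor must be a positive integer")
  }
  n <- length(x$values)
  nb <- n %/% factor
  if (nb * factor < n) {
    warning("dropping trailing partial block of ", n - nb * factor, " samples")
  }
  m <- matrix(x$values[seq_len(nb * factor)], nrow = factor)
  n_ok <- colSums(!is.na(m))
  means <- colMeans(m, na.rm = TRUE)
  means[n_ok < factor / 2] <- NA
  means[n_ok == 0] <- NA
  time_series(means, x$rate / factor, x$start, x$unit)
}

#' Pupil diameter: binocular average
#'
#' `PD = (pl + pr) / 2`, `NA` whenever either eye is missing.
#'
#' @param pl,pr Left/right pupil [time_series()] (a.u.) on a common clock.
#' @return A [time_series()] (a.u.).
#' @export
pupil_diameter <- function(pl, pr) {
  stopifnot(pl$rate == pr$rate, length(pl$values) == length(pr$values))
  v <- (pl$values + pr$values) / 2
  time_series(v, pl$rate, pl$start, "a.u.")
}

#' Condition a continuous eye series: outlier removal and z-scoring
#'
#' Samples beyond +/- 3 SD of the scope mean are set `NA`; the series is
#' then z-scored using the mean/SD recomputed after outlier removal. The
#' scope is the set of samples defining the subject-level distribution
#' (rest and task periods are scoped separately).
#'
#' @param x A [time_series()].
#' @param scope_idx Optional integer indices (1-based) delimiting the
#'   scope; default: all samples.
#' @param sd_limit Outlier cutoff in SD units (default 3).
#' @return A z-scored [time_series()] (`NA` preserved/added for outliers).
#' @export
condition_series <- function(x, scope_idx = NULL, sd_limit = 3) {
  v <- x$values
  idx <- scope_idx %||% seq_along(v)
  sv <- v[idx]
  mu <- mean(sv, na.rm = TRUE)
  sdv <- stats::sd(sv, na.rm = TRUE)
  if (!is.finite(sdv) || sdv == 0) {
    stop("degenerate subject: zero variance in conditioning scope")
  }
  out_of_range <- !is.na(v) & abs(v - mu) > sd_limit * sdv
  v[out_of_range] <- NA
  sv <- v[idx]
  mu2 <- mean(sv, na.rm = TRUE)
  sd2 <- stats::sd(sv, na.rm = TRUE)
  if (!is.finite(sd2) || sd2 == 0) {
    stop("degenerate subject: zero variance after outlier removal")
  }
  time_series((v - mu2) / sd2, x$rate, x$start, "z")
}

#' Gaze position in degrees of visual angle
#'
#' Converts screen-pixel gaze to degrees relative to the screen center via
#' the true projection geometry (`atan` of the metric offset over viewing
#' distance). Screen origin is top-left with y down; output y is up.
#'
#' @param x_px,y_px Gaze coordinates ([time_series()] in px).
#' @param geometry See [default_geometry()].
#' @return List of two [time_series()] `x`, `y` in degrees.
#' @export
gaze_to_deg <- function(x_px, y_px, geometry = default_geometry()) {
  cx <- geometry$screen_px[1] / 2
  cy <- geometry$screen_px[2] / 2
  r2d <- 180 / pi
  xd <- atan((x_px$values - cx) * geometry$pitch_mm / geometry$distance_mm) * r2d
  yd <- atan((cy - y_px$values) * geometry$pitch_mm / geometry$distance_mm) * r2d
  list(x = time_series(xd, x_px$rate, x_px$start, "deg"),
       y = time_series(yd, y_px$rate, y_px$start, "deg"))
}

#' Angle of eye vergence from binocular gaze
#'
#' Reconstructs each eye's gaze ray in 3-D (eyes at x = -/+ IPD/2 on the
#' interocular axis, screen plane at the viewing distance) and returns the
#' angle between the two rays in degrees. Converging rays (fixation in
#' front of / at the screen) and parallel rays (gaze points offset exactly
#' by the IPD) give positive and zero vergence respectively. `NA` gaze
#' propagates.
#'
#' @param xl,yl,xr,yr Per-eye gaze [time_series()] in px.
#' @param geometry See [default_geometry()]; `distance_mm` must be
#'   positive.
#' @return A [time_series()] of vergence angles (deg).
#' @export
aoev <- function(xl, yl, xr, yr, geometry = default_geometry()) {
  if (geometry$distance_mm <= 0) stop("viewing distance must be positive")
  p <- geometry$pitch_mm
  cx <- geometry$screen_px[1] / 2
  cy <- geometry$screen_px[2] / 2
  d <- geometry$distance_mm
  half_ipd <- geometry$ipd_mm / 2
  # ray direction components per eye (origin at each eye)
  lx <- (xl$values - cx) * p + half_ipd
  ly <- (cy - yl$values) * p
  rx <- (xr$values - cx) * p - half_ipd
  ry <- (cy - yr$values) * p
  dot <- lx * rx + ly * ry + d * d
  nl <- sqrt(lx^2 + ly^2 + d^2)
  nr <- sqrt(rx^2 + ry^2 + d^2)
  ang <- acos(pmin(pmax(dot / (nl * nr), -1), 1)) * 180 / pi
  time_series(ang, xl$rate, xl$start, "deg")
}

#' Velocity-threshold micro/saccade detection (one eye)
#'
#' The classic velocity-threshold algorithm: gaze velocity from a 5-point
#' moving window, `v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt)`;
#' a robust per-axis velocity SD from the median estimator
#' `sqrt(median(v^2) - median(v)^2)`; an elliptic threshold at `lambda`
#' robust SDs; events are runs where
#' `(vx/(lambda sx))^2 + (vy/(lambda sy))^2 > 1` lasting at least
#' `min_dur`. `NA` runs split the series into chunks analyzed separately;
#' chunks shorter than 5 samples, or with zero robust SD, are skipped with
#' a warning.
#'
#' Event amplitude is `sqrt(dx^2 + dy^2)` of the per-axis extrema within
#' the event; peak velocity is the maximal speed.
#'
#' @param x,y Gaze [time_series()] in degrees at the native (1000 Hz)
#'   rate.
#' @param lambda Velocity threshold multiplier (default 4).
#' @param min_dur Minimum event duration in seconds (default 0.006).
#' @return Tibble with columns `onset`, `offset` (s, half-open),
#'   `duration`, `amplitude` (deg), `peak_velocity` (deg/s).
#' @export
engbert_detect <- function(x, y, lambda = 4, min_dur = 0.006) {
  rate <- x$rate
  dt <- 1 / rate
  xv <- x$values; yv <- y$values
  ok <- !is.na(xv) & !is.na(yv)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_v <- off_v <- amp_v <- pv_v <- numeric(0)
  for (ci in which(r$values)) {
    i0 <- starts[ci]; i1 <- ends[ci]
    m <- i1 - i0 + 1L
    if (m < 5L) {
      warning("skipping gaze chunk shorter than 5 samples")
      next
    }
    cx <- xv[i0:i1]; cy <- yv[i0:i1]
    k <- 3:(m - 2)
    vx <- (cx[k + 2] + cx[k + 1] - cx[k - 1] - cx[k - 2]) / (6 * dt)
    vy <- (cy[k + 2] + cy[k + 1] - cy[k - 1] - cy[k - 2]) / (6 * dt)
    sx <- sqrt(stats::median(vx^2) - stats::median(vx)^2)
    sy <- sqrt(stats::median(vy^2) - stats::median(vy)^2)
    if (!is.finite(sx) || !is.finite(sy) || sx <= 0 || sy <= 0) {
      warning("skipping gaze chunk with degenerate velocity spread")
      next
    }
    crit <- (vx / (lambda * sx))^2 + (vy / (lambda * sy))^2 > 1
    cr <- rle(crit)
    cends <- cumsum(cr$lengths)
    cstarts <- cends - cr$lengths + 1L
    min_samp <- max(1L, round(min_dur * rate))
    for (ei in which(cr$values & cr$lengths >= min_samp)) {
      a <- cstarts[ei]; b <- cends[ei]          # indices into vx (k grid)
      ga <- i0 + a + 1L; gb <- i0 + b + 1L      # global sample indices
      seg_x <- xv[ga:gb]; seg_y <- yv[ga:gb]
      on_v <- c(on_v, x$start + (ga - 1L) * dt)
      off_v <- c(off_v, x$start + gb * dt)
      amp_v <- c(amp_v, sqrt((max(seg_x) - min(seg_x))^2 +
                               (max(seg_y) - min(seg_y))^2))
      pv_v <- c(pv_v, max(sqrt(vx[a:b]^2 + vy[a:b]^2)))
    }
  }
  ord <- order(on_v)
  tibble::tibble(onset = on_v[ord], offset = off_v[ord],
                 duration = off_v[ord] - on_v[ord],
                 amplitude = amp_v[ord], peak_velocity = pv_v[ord])
}

#' Combine per-eye saccadic events into binocular events
#'
#' Keeps pairs of left/right events that overlap in time by at least one
#' sample; the binocular event spans the temporal union of the pair and
#' carries the mean of the two eyes' amplitudes and peak velocities. Each
#' event joins at most one pair (first overlapping partner in time order).
#'
#' @param left,right Event tibbles from [engbert_detect()].
#' @return A tibble in the same format.
#' @export
binocular_combine <- function(left, right) {
  if (nrow(left) == 0L || nrow(right) == 0L) return(left[0, ])
  used <- logical(nrow(right))
  li <- integer(0); rj <- integer(0)
  j_next <- 1L
  for (i in seq_len(nrow(left))) {
    while (j_next <= nrow(right) &&
           (used[j_next] || right$offset[j_next] <= left$onset[i])) {
      j_next <- j_next + 1L
    }
    if (j_next > nrow(right)) break
    if (right$onset[j_next] < left$offset[i]) {
      used[j_next] <- TRUE
      li <- c(li, i); rj <- c(rj, j_next)
    }
  }
  if (length(li) == 0L) return(left[0, ])
  on <- pmin(left$onset[li], right$onset[rj])
  off <- pmax(left$offset[li], right$offset[rj])
  tibble::tibble(
    onset = on, offset = off, duration = off - on,
    amplitude = (left$amplitude[li] + right$amplitude[rj]) / 2,
    peak_velocity = (left$peak_velocity[li] + right$peak_velocity[rj]) / 2
  )
}

#' Split saccadic events into saccades and microsaccades
#'
#' Amplitude strictly below `amp_max` (1 degree of visual angle) makes a
#' microsaccade; amplitude at or above the cutoff makes a saccade.
#'
#' @param events Binocular event tibble.
#' @param amp_max Amplitude cutoff in degrees.
#' @return The tibble with an added `kind` column
#'   (`"microsaccade"`/`"saccade"`).
#' @export
classify_saccadic <- function(events, amp_max = 1.0) {
  events$kind <- ifelse(events$amplitude < amp_max, "microsaccade", "saccade")
  events
}

#' Fixations: complement of blinks, saccadic events and dropout
#'
#' A fixation is any interval of the analysis span containing neither
#' blinks nor saccadic events (nor tracking dropout). Fixations shorter
#' than one sample are dropped.
#'
#' @param span `c(on, off)` seconds.
#' @param blinks An [interval_set()].
#' @param saccadic Event tibble (needs `onset`/`offset`) or
#'   [interval_set()].
#' @param na_runs Optional [interval_set()] of tracking-dropout runs not
#'   already covered by blinks.
#' @param rate Sample rate defining the minimum fixation length (s = 1 /
#'   rate).
#' @return An [interval_set()] of fixations.
#' @export
derive_fixations <- function(span, blinks = interval_set(),
                             saccadic = interval_set(),
                             na_runs = interval_set(), rate = 1000) {
  occupied <- dplyr::bind_rows(
    tibble::tibble(onset = blinks$onset, offset = blinks$offset),
    tibble::tibble(onset = saccadic$onset, offset = saccadic$offset),
    tibble::tibble(onset = na_runs$onset, offset = na_runs$offset)
  )
  occupied <- occupied[occupied$offset > span[1] & occupied$onset < span[2], ]
  if (nrow(occupied) == 0L) {
    return(interval_set(span[1], span[2], "fixation"))
  }
  occ <- merge_intervals(interval_set(pmax(occupied$onset, span[1]),
                                      pmin(occupied$offset, span[2])))
  gaps_on <- c(span[1], occ$offset)
  gaps_off <- c(occ$onset, span[2])
  keep <- gaps_off - gaps_on >= 1 / rate
  if (!any(keep)) return(interval_set(kind = character(0)))
  interval_set(gaps_on[keep], gaps_off[keep], "fixation")
}

#' The twelve oculometric parameters over one analysis window
#'
#' Continuous parameters (pupil diameter and vergence angle, plus their
#' variances) are means/variances of the conditioned 100 Hz series over
#' non-`NA` samples inside the window. Discrete parameters (fixations,
#' saccades, microsaccades, blinks) are counted by event *onset* inside
#' the window; duration/amplitude means run over those same events and are
#' `NA` when the count is zero.
#'
#' @param pd_z,aoev_z Conditioned 100 Hz [time_series()] (z units / deg).
#' @param events Named list with tibbles/interval sets `blinks`,
#'   `saccades`, `microsaccades`, `fixations` (each with `onset`,
#'   `offset`; saccadic kinds with `amplitude`).
#' @param window `c(on, off)` seconds.
#' @return One-row tibble with the 12 parameters plus `eye_valid_fraction`
#'   (share of non-`NA` pupil samples in the window).
#' @export
window_features <- function(pd_z, aoev_z, events, window) {
  cont <- function(x) {
    v <- x$values[ts_window_idx(x, window)]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(c(NA_real_, NA_real_))
    c(mean(v), if (length(v) > 1L) stats::var(v) else 0)
  }
  pd <- cont(pd_z); av <- cont(aoev_z)
  in_win <- function(ev) {
    ev[ev$onset >= window[1] & ev$onset < window[2], , drop = FALSE]
  }
  bl <- in_win(events$blinks)
  sc <- in_win(events$saccades)
  ms <- in_win(events$microsaccades)
  fx <- in_win(events$fixations)
  mean_or_na <- function(v) if (length(v) == 0L) NA_real_ else mean(v)
  pv <- pd_z$values[ts_window_idx(pd_z, window)]
  tibble::tibble(
    pd_mean = pd[1], pd_var = pd[2],
    aoev_mean = av[1], aoev_var = av[2],
    fixation_count = nrow(fx),
    fixation_duration_mean = mean_or_na(fx$offset - fx$onset),
    saccade_count = nrow(sc),
    saccade_amplitude_mean = mean_or_na(sc$amplitude),
    microsaccade_count = nrow(ms),
    microsaccade_amplitude_mean = mean_or_na(ms$amplitude),
    blink_count = nrow(bl),
    blink_duration_mean = mean_or_na(bl$offset - bl$onset),
    eye_valid_fraction = if (length(pv) == 0L) NA_real_ else mean(!is.na(pv))
  )
}

#' Tracking-dropout runs of a binocular pupil pair
#'
#' Runs where both eyes' pupil samples are `NA` for at least `min_dur`
#' seconds; the synthetic-data convention for blink detection (real-data
#' adapters trust the tracker's blink events instead).
#'
#' @param pl,pr Pupil [time_series()].
#' @param min_dur Minimum run length (s, default 0.02).
#' @return An [interval_set()].
#' @export
dropout_blinks <- function(pl, pr, min_dur = 0.02) {
  both_na <- is.na(pl$values) & is.na(pr$values)
  m <- binary_mask(!both_na, pl$rate, pl$start)
  iv <- mask_to_intervals(m)
  iv[iv$offset - iv$onset >= min_dur, ]
}
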