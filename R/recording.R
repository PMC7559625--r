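#' The 19 scalp labels of the 10-20 montage used throughout
#' @export
scalp_channels <- function() {
  c("FP1", "FP2", "F3", "F4", "F7", "F8", "C3", "C4", "T7", "T8",
    "P3", "P4", "P7", "P8", "O1", "O2", "Fz", "Cz", "Pz")
}

#' Default screen/eye geometry
#'
#' Viewing distance and screen resolution follow the recording setup
#' (70.5 cm, 1280 x 1024 px); interpupil distance defaults to the population
#' mean of 60 mm; the pixel pitch is configurable (0.294 mm/px default, a
#' typical 24-inch panel).
#'
#' @param distance_mm Eye-to-screen distance in mm.
#' @param ipd_mm Interpupil distance in mm.
#' @param screen_px Screen resolution `c(width, height)` in px.
#' @param pitch_mm Pixel pitch in mm/px.
#' @return A named list.
#' @export
default_geometry <- function(distance_mm = 705, ipd_mm = 60,
                             screen_px = c(1280, 1024), pitch_mm = 0.294) {
  list(distance_mm = distance_mm, ipd_mm = ipd_mm,
       screen_px = screen_px, pitch_mm = pitch_mm)
}

#' Coregistered EEG + eye-tracking recording
#'
#' Container for one subject's synchronized recording: multichannel EEG,
#' binocular gaze/pupil series, event intervals, trigger list and geometry
#' metadata.
#'
#' @param eeg Named list of [time_series()] (uV), one per channel; all must
#'   share rate and length. Scalp channels plus optional mastoids (`M1`,
#'   `M2`) and EOG channels.
#' @param eye Named list with elements `xl`, `yl`, `xr`, `yr` (px) and `pl`,
#'   `pr` (a.u.), all [time_series()] on a common clock; `NA` during
#'   tracking dropout.
#' @param events Named list mapping kind (`blink`, `saccade`, `manual`, ...)
#'   to [interval_set()].
#' @param triggers Tibble with columns `time` (s) and `code` (integer).
#' @param geometry See [default_geometry()].
#' @param meta Free-form named list (subject id, seed, config echo,
#'   `referenced` flag, ...).
#' @return An object of class `coreg_recording`.
#' @export
coreg_recording <- function(eeg, eye, events = list(),
                            triggers = tibble::tibble(time = numeric(0), code = integer(0)),
                            geometry = default_geometry(), meta = list()) {
  rates <- vapply(eeg, function(ch) ch$rate, numeric(1))
  lens <- vapply(eeg, function(ch) length(ch$values), numeric(1))
  if (length(unique(rates)) > 1L || length(unique(lens)) > 1L) {
    stop("all EEG channels must share rate and length")
  }
  need <- c("xl", "yl", "xr", "yr", "pl", "pr")
  if (!all(need %in% names(eye))) {
    stop("eye must contain channels: ", paste(setdiff(need, names(eye)), collapse = ", "))
  }
  erates <- vapply(eye[need], function(ch) ch$rate, numeric(1))
  elens <- vapply(eye[need], function(ch) length(ch$values), numeric(1))
  if (length(unique(erates)) > 1L || length(unique(elens)) > 1L) {
    stop("all eye channels must share rate and length")
  }
  dur <- lens[1] / rates[1]
  if (nrow(triggers) > 0L && (any(triggers$time < 0) || any(triggers$time > dur))) {
    stop("trigger times must lie within the recording span")
  }
  structure(
    list(eeg = eeg, eye = eye, events = events, triggers = triggers,
         geometry = geometry, meta = meta),
    class = "coreg_recording"
  )
}

#' @export
print.coreg_recording <- function(x, ...) {
  cat(sprintf(
    "<coreg_recording> %d EEG ch @ %g Hz (%.0f s), eye @ %g Hz, %d event kinds, %d triggers\n",
    length(x$eeg), x$eeg[[1]]$rate, ts_duration(x$eeg[[1]]),
    x$eye$xl$rate, length(x$events), nrow(x$triggers)
  ))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A `coreg_recording`.
#' @export
recording_duration <- function(rec) ts_duration(rec$eeg[[1]])

#' Topographic electrode grouping
#'
#' Default mapping of the 16 lateral scalp electrodes into five regions
#' (anteriofrontal AF, frontal F, centro-temporal CT, parietal P, occipital
#' O) by hemisphere. Midline electrodes are not grouped (hemispheric
#' contrasts are of interest).
#'
#' @return Tibble with columns `region`, `hemisphere`, `electrode`.
#' @export
electrode_grouping <- function() {
  tibble::tribble(
    ~region, ~hemisphere, ~electrode,
    "AF", "left",  "FP1", "AF", "right", "FP2",
    "F",  "left",  "F3",  "F",  "left",  "F7",
    "F",  "right", "F4",  "F",  "right", "F8",
    "CT", "left",  "T7",  "CT", "left",  "C3",
    "CT", "right", "T8",  "CT", "right", "C4",
    "P",  "left",  "P3",  "P",  "left",  "P7",
    "P",  "right", "P4",  "P",  "right", "P8",
    "O",  "left",  "O1",  "O",  "right", "O2"
  )
}

#' Aggregate per-electrode values into region x hemisphere means
#'
#' Unweighted mean of the member electrodes of each region/hemisphere cell;
#' singleton regions pass through unchanged.
#'
#' @param values Named numeric vector, one entry per electrode label.
#' @param grouping Tibble as returned by [electrode_grouping()].
#' @return Tibble with columns `region`, `hemisphere`, `value`.
#' @export
aggregate_regions <- function(values, grouping = electrode_grouping()) {
  missing <- setdiff(grouping$electrode, names(values))
  if (length(missing) > 0L) {
    stop("missing electrode value(s): ", paste(missing, collapse = ", "))
  }
  grouping |>
    dplyr::mutate(value = unname(values[.data$electrode])) |>
    dplyr::group_by(.data$region, .data$hemisphere) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

#' Aggregate per-electrode values into per-region means across hemispheres
#'
#' Used by the rest covariation stage, which reports regions pooled over
#' both hemispheres: the mean over all (left + right) member electrodes of
#' each region.
#'
#' @inheritParams aggregate_regions
#' @return Named numeric vector, one entry per region (AF, F, CT, P, O).
#' @export
hemisphere_aggregate <- function(values, grouping = electrode_grouping()) {
  missing <- setdiff(grouping$electrode, names(values))
  if (length(missing) > 0L) {
    stop("missing electrode value(s): ", paste(missing, collapse = ", "))
  }
  agg <- grouping |>
    dplyr::mutate(value = unname(values[.data$electrode])) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  stats::setNames(agg$value, agg$region)
}
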