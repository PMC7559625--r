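#' EEG conditioning: notch, anti-aliased downsampling, re-referencing
#'
#' Applies, in order: a 50 Hz notch filter (zero-phase 2nd-order Butterworth
#' band-stop), anti-aliased downsampling to `target_rate` (zero-phase
#' 6th-order Butterworth low-pass at 0.8 x target Nyquist followed by
#' decimation), and re-referencing to the average of the two mastoid
#' channels (`M1`, `M2`) when present. Synthetic recordings are generated
#' already referenced (`meta$referenced`), in which case the missing
#' mastoids are expected and no warning is raised; otherwise a warning
#' notes that re-referencing was skipped. Output contains the scalp
#' channels only.
#'
#' @param rec A [coreg_recording()] with raw EEG at >= 200 Hz.
#' @param target_rate Output rate (Hz); the raw rate must be an integer
#'   multiple of it.
#' @param notch Power-line frequency to suppress (Hz); `NULL` to skip.
#' @return Named list of [time_series()] at `target_rate` (uV), scalp
#'   channels only.
#' @export
preprocess_eeg <- function(rec, target_rate = 100, notch = 50) {
  rate <- rec$eeg[[1]]$rate
  if (rate < 200) stop("raw EEG rate must be at least 200 Hz")
  q <- rate / target_rate
  if (abs(q - round(q)) > 1e-9) {
    stop("raw rate must be an integer multiple of the target rate")
  }
  q <- round(q)

  keep <- intersect(names(rec$eeg), scalp_channels())
  channels <- rec$eeg[keep]
  mast <- intersect(names(rec$eeg), c("M1", "M2"))
  reref <- length(mast) == 2L
  if (!reref && !isTRUE(rec$meta$referenced)) {
    warning("mastoid channels absent; skipping re-referencing")
  }

  bf_notch <- if (!is.null(notch)) {
    if (notch >= rate / 2) NULL else {
      signal::butter(2, c(notch - 2, notch + 2) / (rate / 2), type = "stop")
    }
  }
  bf_aa <- signal::butter(6, 0.8 * target_rate / rate)

  condition_one <- function(ch) {
    x <- ch$values
    if (!is.null(bf_notch)) x <- fast_filtfilt(bf_notch, x)
    if (q > 1) x <- fast_filtfilt(bf_aa, x)[seq(1, length(x), by = q)]
    time_series(x, target_rate, ch$start, "uV")
  }

  out <- lapply(channels, condition_one)
  if (reref) {
    ref <- (condition_one(rec$eeg[[mast[1]]])$values +
              condition_one(rec$eeg[[mast[2]]])$values) / 2
    out <- lapply(out, function(ch) {
      time_series(ch$values - ref, ch$rate, ch$start, "uV")
    })
  }
  out
}

#' Build the EEG artifact mask from coregistered eye events
#'
#' Invalidates the union of: each blink expanded from 350 ms before its
#' onset to 200 ms after its offset (the window over which blinks visibly
#' distort alpha power), each saccade padded by +/- 20 ms, and any manual
#' artifact intervals; everything clipped to `[0, duration)`.
#'
#' @param blinks,saccades,manual [interval_set()]s (may be empty).
#' @param duration Recording duration (s).
#' @param rate Mask sampling rate (Hz), conventionally the conditioned EEG
#'   rate.
#' @param blink_pre,blink_post,sacc_pad Expansion margins in seconds.
#' @return An [binary_mask()] where `TRUE` marks artifact-free samples.
#' @export
build_eeg_mask <- function(blinks = interval_set(), saccades = interval_set(),
                           manual = interval_set(), duration, rate = 100,
                           blink_pre = 0.350, blink_post = 0.200,
                           sacc_pad = 0.020) {
  clip <- c(0, duration)
  bad <- dplyr::bind_rows(
    pad_intervals(blinks, pre = blink_pre, post = blink_post, clip = clip),
    pad_intervals(saccades, pre = sacc_pad, post = sacc_pad, clip = clip),
    pad_intervals(manual, clip = clip)
  )
  if (nrow(bad) == 0L) {
    return(binary_mask(rep(TRUE, round(duration * rate)), rate, 0))
  }
  intervals_to_mask(merge_intervals(interval_set(bad$onset, bad$offset)),
                    rate, duration)
}

#' Instantaneous alpha-band power by complex demodulation
#'
#' Shifts the band of interest to 0 Hz by multiplication with a complex
#' exponential at `center`, low-passes the product with a zero-phase
#' 4th-order Butterworth at `halfband`, and returns `2 * |z|^2`, scaled so
#' a pure in-band sine of amplitude A yields mean power A^2 / 2 (its mean
#' square). `NA` inputs stay `NA` at the same positions (interior gaps are
#' bridged by linear interpolation before filtering); the first and last
#' `edge_na` seconds are flagged `NA` against filter edge effects.
#'
#' @param x A [time_series()] (uV).
#' @param center Band center frequency (Hz); default 10.5 for the
#'   8.5-12.5 Hz alpha band.
#' @param halfband Half bandwidth of the demodulation low-pass (Hz).
#' @param edge_na Seconds flagged `NA` at both ends.
#' @return A [time_series()] of band power (uV^2) with a `band` attribute
#'   `c(center - halfband, center + halfband)`.
#' @export
complex_demod_power <- function(x, center = 10.5, halfband = 2.0,
                                edge_na = 0.5) {
  if (x$rate <= 2 * (center + halfband)) {
    stop("band extends beyond the Nyquist frequency")
  }
  v <- x$values
  na_idx <- which(is.na(v))
  if (length(na_idx) > 0L) {
    if (length(na_idx) == length(v)) {
      return(time_series(v, x$rate, x$start, "uV^2"))
    }
    v <- zoo::na.approx(v, na.rm = FALSE, rule = 2)
  }
  tt <- (seq_along(v) - 1) / x$rate
  z <- v * exp(-2i * pi * center * tt)
  bf <- signal::butter(4, halfband / (x$rate / 2))
  zf <- complex(real = fast_filtfilt(bf, Re(z)),
                imaginary = fast_filtfilt(bf, Im(z)))
  pow <- 2 * Mod(zf)^2
  pow[na_idx] <- NA
  ne <- round(edge_na * x$rate)
  if (ne > 0 && length(pow) > 0) {
    pow[seq_len(min(ne, length(pow)))] <- NA
    pow[seq.int(max(1L, length(pow) - ne + 1L), length(pow))] <- NA
  }
  out <- time_series(pow, x$rate, x$start, "uV^2")
  attr(out, "band") <- c(center - halfband, center + halfband)
  out
}

#' Mean band power over mask-valid samples in a window
#'
#' Averages power over samples that are valid in the artifact mask and not
#' `NA`. Returns `NA` ("missing", not an error) when fewer than `min_valid`
#' samples remain — a variance guard for windows truncated by blinks.
#'
#' @param power A power [time_series()].
#' @param mask An [binary_mask()] on the same clock.
#' @param window `c(on, off)` seconds.
#' @param min_valid Minimum number of contributing samples (default 10,
#'   i.e. 0.1 s at 100 Hz).
#' @return Mean power (uV^2) or `NA`.
#' @export
mean_power <- function(power, mask, window, min_valid = 10) {
  idx <- ts_window_idx(power, window)
  if (length(idx) == 0L) return(NA_real_)
  ok <- mask$valid[idx] & !is.na(power$values[idx])
  if (sum(ok) < min_valid) return(NA_real_)
  mean(power$values[idx][ok])
}

#' Task-related power (TRP)
#'
#' `log(1 + act_mean) - log(1 + ref_mean)` (natural log): the log change in
#' mean alpha power from the pre-stimulus reference phase to the task
#' activation phase. Negative values reflect task-related alpha
#' desynchronization, positive values synchronization. The log base only
#' rescales TRP; sign and all ANOVA F statistics are base-invariant.
#'
#' @param act_mean,ref_mean Mean band power (uV^2) in the activation and
#'   reference windows; must be non-negative (may be `NA`).
#' @return Dimensionless TRP value (`NA` if either input is missing).
#' @export
trp <- function(act_mean, ref_mean) {
  if (any(stats::na.omit(c(act_mean, ref_mean)) < 0)) {
    stop("power means must be non-negative")
  }
  log1p(act_mean) - log1p(ref_mean)
}

#' Welch-averaged power spectrum
#'
#' Splits the series into 50%-overlapping Hann-windowed segments of
#' `window_s` seconds and averages their periodograms; used to validate the
#' alpha band choice against the empirical spectrum.
#'
#' @param x A [time_series()].
#' @param window_s Segment length in seconds (default 2).
#' @return Tibble with columns `freq` (Hz) and `power` (uV^2/Hz, one-sided
#'   density).
#' @export
power_spectrum <- function(x, window_s = 2) {
  nw <- round(window_s * x$rate)
  v <- x$values
  v[is.na(v)] <- 0
  if (length(v) < nw) stop("series shorter than one spectrum window")
  step <- max(1L, nw %/% 2L)
  starts <- seq(1L, length(v) - nw + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nw) - 1) / (nw - 1))
  wnorm <- sum(win^2)
  nf <- nw %/% 2L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- v[s:(s + nw - 1L)] * win
    sp <- Mod(stats::fft(seg))^2
    acc <- acc + sp[2:(nf + 1L)]
  }
  dens <- 2 * acc / (length(starts) * wnorm * x$rate)
  tibble::tibble(freq = (1:nf) * x$rate / nw, power = dens)
}

#' Frequency of maximal spectral power within a search band
#'
#' @param spectrum Output of [power_spectrum()].
#' @param band Search band `c(lo, hi)` Hz (default 6-14, bracketing alpha).
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(spectrum, band = c(6, 14)) {
  sel <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  if (!any(sel)) stop("no spectral bins inside the search band")
  spectrum$freq[sel][which.max(spectrum$power[sel])]
}

#' Blink-locked average band-power time course
#'
#' Event-locked averages of a power series around blink onsets and
#' offsets, the diagnostic that motivates the extended blink exclusion
#' window: residual blink influence shows up as a systematic deviation
#' before onsets / after offsets.
#'
#' @param power A power [time_series()].
#' @param blinks An [interval_set()] of blink events.
#' @param window `c(lo, hi)` seconds around the alignment point.
#' @return List with tibbles `onset` and `offset` (columns `time`, `mean`,
#'   `n_events`) and the number of contributing events.
#' @export
blink_locked_power <- function(power, blinks, window = c(-1, 1)) {
  if (nrow(blinks) == 0L) stop("no blink events supplied")
  rel <- seq(round(window[1] * power$rate), round(window[2] * power$rate))
  span <- c(power$start, power$start + ts_duration(power))
  lock <- function(times) {
    ok <- times + window[1] >= span[1] & times + window[2] <= span[2]
    times <- times[ok]
    if (length(times) == 0L) stop("no usable blink events inside the span")
    mat <- vapply(times, function(t0) {
      i0 <- round((t0 - power$start) * power$rate)
      power$values[i0 + rel + 1L]
    }, numeric(length(rel)))
    tibble::tibble(time = rel / power$rate,
                   mean = rowMeans(mat, na.rm = TRUE),
                   n_events = length(times))
  }
  list(onset = lock(blinks$onset), offset = lock(blinks$offset))
}

#' Per-electrode alpha power series for a conditioned recording
#'
#' Convenience driver: [complex_demod_power()] applied to every channel.
#'
#' @param channels Named list of conditioned [time_series()] (100 Hz).
#' @param center,halfband See [complex_demod_power()].
#' @return Named list of power series.
#' @export
alpha_power <- function(channels, center = 10.5, halfband = 2.0) {
  lapply(channels, complex_demod_power, center = center, halfband = halfband)
}
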