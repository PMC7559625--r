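#' Regularly sampled time series
#'
#' Lightweight carrier for all signals in the package: a numeric vector
#' sampled at a fixed rate, starting at a known time (seconds from recording
#' start). Missing samples are explicit `NA`, never dropped. Sample `n`
#' (0-based) is located at `start + n / rate`.
#'
#' @param values Numeric vector, `NA` allowed.
#' @param rate Sampling rate in samples/s, must be positive.
#' @param start Time of the first sample in seconds.
#' @param unit Unit tag for the values (e.g. `"uV"`, `"px"`, `"a.u."`,
#'   `"deg"`, `"uV^2"`). Informational only.
#' @return An object of class `ag_ts`.
#' @export
time_series <- function(values, rate, start = 0, unit = NA_character_) {
  stopifnot(is.numeric(values) || is.logical(values))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  structure(
    list(values = as.numeric(values), rate = rate, start = start, unit = unit),
    class = "ag_ts"
  )
}

#' @export
print.ag_ts <- function(x, ...) {
  cat(sprintf(
    "<ag_ts> %d samples @ %g Hz, start %.3f s, span %.3f s, unit %s\n",
    length(x$values), x$rate, x$start, ts_duration(x),
    ifelse(is.na(x$unit), "?", x$unit)
  ))
  invisible(x)
}

#' @export
length.ag_ts <- function(x) length(x$values)

#' Sample times of a time series
#' @param x An `ag_ts`.
#' @return Numeric vector of timestamps (s).
#' @export
ts_times <- function(x) x$start + (seq_along(x$values) - 1) / x$rate

#' Duration covered by a time series (s)
#' @param x An `ag_ts`.
#' @export
ts_duration <- function(x) length(x$values) / x$rate

#' 0-based sample indices whose timestamps fall in a half-open window
#'
#' A sample at time `t` belongs to `[on, off)` iff `on <= t < off`. A small
#' fuzz (1e-9 of a sample) guards against floating-point boundary jitter.
#'
#' @param x An `ag_ts` or `ag_mask`.
#' @param window Numeric `c(on, off)` in seconds.
#' @return Integer vector of 1-based R indices into `x$values`/`x$valid`.
#' @export
ts_window_idx <- function(x, window) {
  if (length(window) != 2L || !(window[2] > window[1])) {
    stop("window must be c(on, off) with off > on")
  }
  n <- if (inherits(x, "ag_mask")) length(x$valid) else length(x$values)
  eps <- 1e-9
  lo <- ceiling((window[1] - x$start) * x$rate - eps)
  hi <- ceiling((window[2] - x$start) * x$rate - eps) - 1
  lo <- max(lo, 0)
  hi <- min(hi, n - 1)
  if (hi < lo) return(integer(0))
  seq.int(lo, hi) + 1L
}

#' Half-open interval sets for events and artifacts
#'
#' Intervals are `[onset, offset)` in seconds from recording start. `kind`
#' labels the event class (`blink`, `saccade`, `manual`, `fixation`, ...).
#'
#' @param onset,offset Numeric vectors of equal length; `onset < offset`.
#' @param kind Optional character scalar or vector with the event kind.
#' @return A tibble of class `ag_intervals` with columns `onset`, `offset`
#'   and (if given) `kind`.
#' @export
interval_set <- function(onset = numeric(0), offset = numeric(0), kind = NULL) {
  if (length(onset) != length(offset)) stop("onset and offset lengths differ")
  if (any(onset >= offset)) stop("every interval needs onset < offset")
  out <- tibble::tibble(onset = as.numeric(onset), offset = as.numeric(offset))
  if (!is.null(kind)) out$kind <- kind
  class(out) <- c("ag_intervals", class(out))
  out
}

#' Normalize an interval set: sort and merge overlaps
#'
#' The union of covered time is preserved exactly; abutting intervals are
#' coalesced. Extra columns are dropped (a merged interval has no single
#' parent event).
#'
#' @param x An `ag_intervals` (or data frame with onset/offset columns).
#' @return A sorted, pairwise-disjoint `ag_intervals`.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(interval_set())
  if (any(x$onset >= x$offset)) stop("every interval needs onset < offset")
  ord <- order(x$onset, x$offset)
  on <- x$onset[ord]; off <- x$offset[ord]
  keep_on <- on[1]; keep_off <- off[1]
  outs_on <- numeric(0); outs_off <- numeric(0)
  for (i in seq_along(on)[-1]) {
    if (on[i] <= keep_off) {
      keep_off <- max(keep_off, off[i])
    } else {
      outs_on <- c(outs_on, keep_on); outs_off <- c(outs_off, keep_off)
      keep_on <- on[i]; keep_off <- off[i]
    }
  }
  interval_set(c(outs_on, keep_on), c(outs_off, keep_off))
}

#' Pad every interval by fixed margins
#'
#' @param x An `ag_intervals`.
#' @param pre Seconds added before each onset (non-negative).
#' @param post Seconds added after each offset (non-negative).
#' @param clip Optional `c(lo, hi)`; padded intervals are clipped to it and
#'   intervals that vanish are dropped.
#' @return An `ag_intervals` (not merged; see [merge_intervals()]).
#' @export
pad_intervals <- function(x, pre = 0, post = 0, clip = NULL) {
  if (nrow(x) == 0L) return(interval_set())
  on <- x$onset - pre
  off <- x$offset + post
  if (!is.null(clip)) {
    on <- pmax(on, clip[1]); off <- pmin(off, clip[2])
    keep <- on < off
    on <- on[keep]; off <- off[keep]
  }
  interval_set(on, off)
}

#' Per-sample validity mask
#'
#' Same indexing contract as [time_series()]: entry `n` (0-based) describes
#' the sample at `start + n / rate`.
#'
#' @param valid Logical vector (`TRUE` = valid sample).
#' @param rate Samples/s.
#' @param start Time of first sample (s).
#' @return An object of class `ag_mask`.
#' @export
binary_mask <- function(valid, rate, start = 0) {
  stopifnot(is.logical(valid), rate > 0)
  structure(list(valid = valid, rate = rate, start = start), class = "ag_mask")
}

#' @export
print.ag_mask <- function(x, ...) {
  cat(sprintf(
    "<ag_mask> %d samples @ %g Hz, %.1f%% valid\n",
    length(x$valid), x$rate, 100 * mean(x$valid)
  ))
  invisible(x)
}

#' Render an interval set as a per-sample validity mask
#'
#' Sample `n` is invalid iff its timestamp lies inside any interval
#' (half-open convention). The complement is untouched.
#'
#' @param intervals An `ag_intervals` of artifact intervals.
#' @param rate Samples/s of the target mask.
#' @param duration Duration of the mask span (s), must be positive.
#' @param start Start time (s) of the mask.
#' @return An `ag_mask` with `floor(duration * rate)` entries (plus the
#'   boundary sample when `duration * rate` is integral).
#' @export
intervals_to_mask <- function(intervals, rate, duration, start = 0) {
  if (duration <= 0) stop("duration must be positive")
  n <- round(duration * rate)
  valid <- rep(TRUE, n)
  if (nrow(intervals) > 0L) {
    m <- merge_intervals(intervals)
    eps <- 1e-9
    for (i in seq_len(nrow(m))) {
      lo <- ceiling((m$onset[i] - start) * rate - eps)
      hi <- ceiling((m$offset[i] - start) * rate - eps) - 1
      lo <- max(lo, 0); hi <- min(hi, n - 1)
      if (hi >= lo) valid[(lo:hi) + 1L] <- FALSE
    }
  }
  binary_mask(valid, rate, start)
}

#' Reconstruct intervals from runs of invalid samples
#'
#' Inverse of [intervals_to_mask()] at sample resolution: each maximal run of
#' invalid samples becomes one interval spanning those samples.
#'
#' @param mask An `ag_mask`.
#' @return An `ag_intervals`.
#' @export
mask_to_intervals <- function(mask) {
  inv <- !mask$valid
  if (!any(inv)) return(interval_set())
  r <- rle(inv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  interval_set(
    mask$start + (starts[sel] - 1L) / mask$rate,
    mask$start + ends[sel] / mask$rate
  )
}

#' Fraction of valid samples inside a window
#'
#' @param mask An `ag_mask`.
#' @param window `c(on, off)` seconds; must be non-empty and lie within the
#'   mask span.
#' @return Proportion in `[0, 1]`.
#' @export
valid_fraction <- function(mask, window) {
  if (length(window) != 2L || !(window[2] > window[1])) {
    stop("window must be c(on, off) with off > on")
  }
  span_hi <- mask$start + length(mask$valid) / mask$rate
  eps <- 1e-9
  if (window[1] < mask$start - eps || window[2] > span_hi + eps) {
    stop("window lies outside the mask span")
  }
  idx <- ts_window_idx(mask, window)
  if (length(idx) == 0L) stop("window contains no samples")
  mean(mask$valid[idx])
}

#' Combine masks on a common clock (logical AND)
#'
#' @param a,b `ag_mask` objects with identical rate, start and length.
#' @return An `ag_mask` valid where both inputs are valid.
#' @export
mask_and <- function(a, b) {
  stopifnot(a$rate == b$rate, a$start == b$start,
            length(a$valid) == length(b$valid))
  binary_mask(a$valid & b$valid, a$rate, a$start)
}
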