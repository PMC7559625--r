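# Shared fixtures built in code.

# A minimal synthetic recording with constant eye channels and sinusoidal
# EEG, optionally with mastoid channels for re-referencing tests.
make_sine_recording <- function(freq = 10.5, amp = 1, dur = 10, rate = 1000,
                                mastoids = FALSE, offset = 0) {
  n <- dur * rate
  tt <- (0:(n - 1)) / rate
  labels <- scalp_channels()
  if (mastoids) labels <- c(labels, "M1", "M2")
  eeg <- lapply(labels, function(ch) {
    time_series(amp * sin(2 * pi * freq * tt) + offset, rate, 0, "uV")
  })
  names(eeg) <- labels
  eye <- list(
    xl = time_series(rep(640, n), rate, 0, "px"),
    yl = time_series(rep(512, n), rate, 0, "px"),
    xr = time_series(rep(640, n), rate, 0, "px"),
    yr = time_series(rep(512, n), rate, 0, "px"),
    pl = time_series(rep(4000, n), rate, 0, "a.u."),
    pr = time_series(rep(4000, n), rate, 0, "a.u.")
  )
  coreg_recording(eeg, eye, meta = list(referenced = !mastoids))
}

# Greedy interval matching of detected against ground-truth events.
match_events <- function(det, gt, tol = 0.01) {
  if (nrow(gt) == 0L) return(c(recall = NA, precision = NA))
  hit <- logical(nrow(gt))
  used <- logical(max(nrow(det), 1L))
  for (i in seq_len(nrow(gt))) {
    j <- which(!used[seq_len(nrow(det))] &
                 det$onset < gt$offset[i] + tol &
                 det$offset > gt$onset[i] - tol)
    if (length(j) > 0L) {
      hit[i] <- TRUE
      used[j[1]] <- TRUE
    }
  }
  c(recall = mean(hit),
    precision = if (nrow(det) == 0L) NA else mean(used[seq_len(nrow(det))]))
}

# Reduced-rate generator config used where full-rate simulation cost is not
# the point of the test (rates stay multiples of 100 Hz; noise is
# PSD-referenced so in-band statistics match the 1000 Hz defaults).
cfg_scaled <- function(...) {
  gen_config(eeg_rate = 200, eye_rate = 500, ...)
}

# Segment tables for a small rest study, computed once per test run.
cached_rest_tables <- local({
  tabs <- NULL
  function(n = 6, seed0 = 7000) {
    if (is.null(tabs)) {
      cfg <- cfg_scaled()
      tabs <<- lapply(seq_len(n), function(i) {
        rest_segments(generate_rest(cfg, seed = seed0 + i,
                                    subject = sprintf("s%02d", i))$recording)
      })
    }
    tabs
  }
})
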