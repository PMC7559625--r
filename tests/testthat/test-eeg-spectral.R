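fft_amplitude <- function(v, f, rate) {
  n <- length(v)
  2 * Mod(stats::fft(v))[round(f * n / rate) + 1] / n
}

test_that("preprocessing notches line noise and preserves the passband", {
  r50 <- make_sine_recording(freq = 50, amp = 1, dur = 10)
  out <- preprocess_eeg(r50)
  expect_equal(out$O1$rate, 100)
  resid <- fft_amplitude(out$O1$values[101:900], 50, 100)
  expect_lt(20 * log10(resid / 1), -40)

  r5 <- make_sine_recording(freq = 5, amp = 1, dur = 10)
  out5 <- preprocess_eeg(r5)
  expect_equal(fft_amplitude(out5$O1$values, 5, 100), 1, tolerance = 0.02)
})

test_that("re-referencing removes any common offset when mastoids exist", {
  base <- make_sine_recording(freq = 7, dur = 4, mastoids = TRUE)
  shifted <- make_sine_recording(freq = 7, dur = 4, mastoids = TRUE,
                                 offset = 25)
  a <- preprocess_eeg(base)
  b <- preprocess_eeg(shifted)
  expect_equal(a$C3$values, b$C3$values, tolerance = 1e-8)
  expect_false("M1" %in% names(a))

  no_mast <- make_sine_recording(freq = 7, dur = 4)
  no_mast$meta$referenced <- FALSE
  expect_warning(preprocess_eeg(no_mast), "mastoid")
  expect_error(preprocess_eeg(make_sine_recording(dur = 2, rate = 100)),
               "at least 200")
})

test_that("EEG mask applies the blink and saccade exclusion margins", {
  m <- build_eeg_mask(blinks = interval_set(10.0, 10.2), duration = 20)
  iv <- mask_to_intervals(m)
  expect_equal(iv$onset, 9.65)
  expect_equal(iv$offset, 10.4)

  m2 <- build_eeg_mask(saccades = interval_set(5.00, 5.03), duration = 10)
  iv2 <- mask_to_intervals(m2)
  expect_equal(iv2$onset, 4.98)
  expect_equal(iv2$offset, 5.05)

  m3 <- build_eeg_mask(blinks = interval_set(c(1.0, 1.3), c(1.2, 1.5)),
                       duration = 5)
  iv3 <- mask_to_intervals(m3)
  expect_equal(nrow(iv3), 1)
  expect_equal(iv3$onset, 0.65)
  expect_equal(iv3$offset, 1.7)
})

test_that("complex demodulation recovers in-band mean square power", {
  tt <- (0:5999) / 100
  z <- complex_demod_power(time_series(rep(0, 6000), 100))
  expect_true(all(z$values == 0 | is.na(z$values)))

  x <- time_series(2 * sin(2 * pi * 10.5 * tt), 100)
  p <- complex_demod_power(x)
  # FFT oracle: mean square of the band-passed signal
  sp <- stats::fft(x$values)
  f <- (0:5999) * 100 / 6000
  fmir <- pmin(f, 100 - f)
  sp[fmir < 8.5 | fmir > 12.5] <- 0
  oracle <- mean(Re(stats::fft(sp, inverse = TRUE) / 6000)^2)
  expect_equal(mean(p$values, na.rm = TRUE), oracle, tolerance = 0.03)
  expect_equal(mean(p$values, na.rm = TRUE), 2.0, tolerance = 0.03)

  x25 <- time_series(2 * sin(2 * pi * 25 * tt), 100)
  p25 <- complex_demod_power(x25)
  expect_lt(mean(p25$values, na.rm = TRUE),
            0.01 * mean(p$values, na.rm = TRUE))

  # two-tone: out-of-band component contributes < 3%
  x2 <- time_series(2 * sin(2 * pi * 10.5 * tt) + 3 * sin(2 * pi * 30 * tt), 100)
  p2 <- complex_demod_power(x2)
  expect_equal(mean(p2$values, na.rm = TRUE), mean(p$values, na.rm = TRUE),
               tolerance = 0.03)

  # NA in -> NA out at the same positions; edges flagged
  v <- 2 * sin(2 * pi * 10.5 * tt)
  v[1000:1020] <- NA
  pna <- complex_demod_power(time_series(v, 100))
  expect_true(all(is.na(pna$values[1000:1020])))
  expect_true(all(is.na(pna$values[1:50])))
  expect_false(anyNA(pna$values[2000:3000]))

  expect_error(complex_demod_power(time_series(rnorm(100), 20)), "Nyquist")
})

test_that("mean_power averages mask-valid samples with a validity floor", {
  p <- time_series(rep(4, 200), 100, 0, "uV^2")
  full <- binary_mask(rep(TRUE, 200), 100)
  expect_equal(mean_power(p, full, c(0, 2)), 4)

  v <- rep(c(2, 99), 100)
  half <- binary_mask(rep(c(TRUE, FALSE), 100), 100)
  expect_equal(mean_power(time_series(v, 100), half, c(0, 2)), 2)

  none <- binary_mask(rep(FALSE, 200), 100)
  expect_true(is.na(mean_power(p, none, c(0, 2))))
  # below the minimum validity floor -> missing
  m9 <- binary_mask(c(rep(TRUE, 9), rep(FALSE, 191)), 100)
  expect_true(is.na(mean_power(p, m9, c(0, 2), min_valid = 10)))
})

test_that("trp follows the log-power-change definition", {
  expect_equal(trp(5, 5), 0)
  expect_equal(trp(exp(1) - 1, 0), 1.0)
  expect_lt(trp(1, 3), 0)
  expect_error(trp(-1, 2), "non-negative")
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0, 50); b <- runif(1, 0, 50)
    expect_equal(trp(a, b), -trp(b, a))
  }
})

test_that("region aggregation then hemisphere pooling equals direct pooling", {
  g <- electrode_grouping()
  set.seed(5)
  vals <- stats::setNames(rnorm(16), g$electrode)
  region_hemi <- aggregate_regions(vals, g)
  pooled <- hemisphere_aggregate(vals, g)
  for (rg in unique(g$region)) {
    members <- g$electrode[g$region == rg]
    # equal electrode counts per hemisphere within region, so the mean of
    # hemisphere means equals the mean over all member electrodes
    two <- region_hemi$value[region_hemi$region == rg]
    expect_equal(mean(two), mean(vals[members]))
    expect_equal(pooled[[rg]], mean(vals[members]))
  }
})

test_that("power spectrum locates tones and is flat for white noise", {
  tt <- (0:9999) / 100
  sp <- power_spectrum(time_series(sin(2 * pi * 10 * tt), 100), window_s = 2)
  expect_equal(peak_frequency(sp), 10, tolerance = 0.5)

  set.seed(6)
  spw <- power_spectrum(time_series(rnorm(20000), 100), window_s = 2)
  mid <- spw$power[spw$freq > 5 & spw$freq < 45]
  expect_lt(max(mid) / min(mid), 3)

  sp0 <- power_spectrum(time_series(rep(0, 1000), 100))
  expect_true(all(sp0$power == 0))
  expect_error(power_spectrum(time_series(rnorm(50), 100), window_s = 2),
               "shorter")
})

test_that("blink-locked averages recover event-locked structure", {
  pow <- time_series(rep(4, 2000), 100, 0, "uV^2")
  blinks <- interval_set(c(5, 12), c(5.2, 12.3))
  bl <- blink_locked_power(pow, blinks)
  expect_true(all(abs(bl$onset$mean - 4) < 1e-12))

  # boxcar bump of +2 during each blink
  v <- rep(1, 2000)
  for (i in seq_len(nrow(blinks))) {
    idx <- ts_window_idx(pow, c(blinks$onset[i], blinks$offset[i]))
    v[idx] <- v[idx] + 2
  }
  bl2 <- blink_locked_power(time_series(v, 100), blinks)
  during <- bl2$onset$mean[bl2$onset$time > 0.05 & bl2$onset$time < 0.15]
  before <- bl2$onset$mean[bl2$onset$time < -0.05]
  expect_equal(mean(during), 3, tolerance = 0.05 * 3)
  expect_equal(mean(before), 1, tolerance = 0.05)

  one <- interval_set(5, 5.2)
  bl3 <- blink_locked_power(time_series(v, 100), one)
  i0 <- round((5 - 1) * 100)
  expect_equal(bl3$onset$mean, v[(i0 + 1):(i0 + 201)])
  expect_error(blink_locked_power(pow, interval_set(0.1, 0.2)), "usable")
})
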