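test_that("block downsampling averages 10-sample blocks with an NA majority rule", {
  x <- time_series(rep(4000, 10), 1000)
  expect_equal(block_downsample(x)$values, 4000)

  y <- block_downsample(time_series(0:9, 1000))
  expect_equal(y$values, 4.5)
  expect_equal(y$rate, 100)

  v <- 0:9; v[1:6] <- NA
  expect_true(is.na(block_downsample(time_series(v, 1000))$values))
  v2 <- 0:9; v2[1:5] <- NA
  expect_equal(block_downsample(time_series(v2, 1000))$values, 7)

  expect_warning(block_downsample(time_series(0:10, 1000)), "partial block")
  expect_error(block_downsample(time_series(0:9, 1000), factor = 0), "positive")
})

test_that("pupil conditioning averages eyes, drops outliers and z-scores", {
  pd <- pupil_diameter(time_series(c(4000, 4000, NA), 1000),
                       time_series(c(5000, 4500, 4500), 1000))
  expect_equal(pd$values[1:2], c(4500, 4250))
  expect_true(is.na(pd$values[3]))

  set.seed(7)
  v <- rnorm(2000, 4000, 10)
  v[100] <- 4000 + 40  # 4 SD out
  z <- condition_series(time_series(v, 100))
  expect_true(is.na(z$values[100]))
  expect_equal(mean(z$values, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z$values, na.rm = TRUE), 1, tolerance = 1e-9)

  expect_error(condition_series(time_series(rep(1, 50), 100)), "degenerate")
})

test_that("vergence geometry matches the explicit 3-D ray oracle", {
  g <- default_geometry()
  mid <- time_series(640, 1000); midy <- time_series(512, 1000)
  a <- aoev(mid, midy, mid, midy, g)
  expect_equal(a$values, 2 * atan((g$ipd_mm / 2) / g$distance_mm) * 180 / pi,
               tolerance = 1e-9)

  g0 <- default_geometry(ipd_mm = 0)
  expect_equal(aoev(mid, midy, mid, midy, g0)$values, 0)

  off <- g$ipd_mm / g$pitch_mm
  par <- aoev(time_series(640 - off / 2, 1000), midy,
              time_series(640 + off / 2, 1000), midy, g)
  expect_equal(par$values, 0, tolerance = 1e-9)

  # vergence decreases monotonically with fixation depth at fixed IPD
  depths <- c(500, 705, 900, 1200, 2000)
  angles <- vapply(depths, function(df) {
    sep_px <- g$ipd_mm * (1 - g$distance_mm / df) / g$pitch_mm
    aoev(time_series(640 - sep_px / 2, 1000), midy,
         time_series(640 + sep_px / 2, 1000), midy, g)$values
  }, numeric(1))
  expect_true(all(diff(angles) < 0))

  expect_error(aoev(mid, midy, mid, midy, default_geometry(distance_mm = -1)),
               "positive")
  na_in <- aoev(time_series(NA_real_, 1000), midy, mid, midy, g)
  expect_true(is.na(na_in$values))
})

test_that("velocity detector: low false alarms, accurate onsets, robust sigma", {
  # false-alarm oracle: pure Gaussian noise on slow drift
  set.seed(8)
  hits <- vapply(1:20, function(i) {
    drift <- cumsum(rnorm(10000, sd = 1e-4))
    gx <- time_series(drift + rnorm(10000, sd = 0.008), 1000)
    gy <- time_series(rnorm(10000, sd = 0.008), 1000)
    nrow(suppressWarnings(engbert_detect(gx, gy)))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)

  # injected 0.5 deg, 12 ms raised-cosine event
  set.seed(9)
  x <- rnorm(5000, sd = 0.005)
  prof <- 0.5 * 0.5 * (1 - cos(pi * seq(0, 1, length.out = 12)))
  x[2001:2012] <- x[2001:2012] + prof
  x[2013:5000] <- x[2013:5000] + 0.5
  det <- engbert_detect(time_series(x, 1000), time_series(rnorm(5000, sd = 0.005), 1000))
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$onset - 2.000), 0.003)
  expect_equal(det$amplitude, 0.5, tolerance = 0.1)

  # the median-based spread estimator concentrates on its Gaussian value
  # (median(|v|) = 0.6745 sd), i.e. it tracks the noise SD up to a known
  # constant, within 10%
  set.seed(10)
  reps <- vapply(1:30, function(i) {
    v <- rnorm(20000)
    sqrt(stats::median(v^2) - stats::median(v)^2)
  }, numeric(1))
  expect_true(all(abs(reps / stats::qnorm(0.75) - 1) < 0.1))
})

test_that("binocular combination keeps overlapping pairs with union extent", {
  ev <- tibble::tibble(onset = c(1, 3), offset = c(1.02, 3.03),
                       duration = c(0.02, 0.03), amplitude = c(0.5, 2),
                       peak_velocity = c(30, 100))
  expect_equal(binocular_combine(ev, ev), ev)

  other <- tibble::tibble(onset = 5, offset = 5.02, duration = 0.02,
                          amplitude = 1, peak_velocity = 50)
  expect_equal(nrow(binocular_combine(ev, other)), 0)

  l <- tibble::tibble(onset = 1.000, offset = 1.020, duration = 0.02,
                      amplitude = 0.4, peak_velocity = 30)
  r <- tibble::tibble(onset = 1.010, offset = 1.028, duration = 0.018,
                      amplitude = 0.6, peak_velocity = 40)
  b <- binocular_combine(l, r)
  expect_equal(b$onset, 1.000)
  expect_equal(b$offset, 1.028)
  expect_equal(b$amplitude, 0.5)
  # label-swap symmetry
  b2 <- binocular_combine(r, l)
  expect_equal(b2$onset, b$onset)
  expect_equal(b2$amplitude, b$amplitude)
})

test_that("amplitude classification uses the strict 1-degree rule", {
  ev <- tibble::tibble(onset = c(1, 2, 3), offset = c(1.012, 2.03, 3.02),
                       duration = c(0.012, 0.03, 0.02),
                       amplitude = c(0.5, 1.2, 1.0),
                       peak_velocity = c(30, 100, 80))
  k <- classify_saccadic(ev)
  expect_equal(k$kind, c("microsaccade", "saccade", "saccade"))
})

test_that("fixations are the complement of events within the span", {
  f0 <- derive_fixations(c(0, 10))
  expect_equal(nrow(f0), 1)
  expect_equal(f0$offset - f0$onset, 10)

  f1 <- derive_fixations(c(0, 10), saccadic = interval_set(5, 5.03))
  expect_equal(nrow(f1), 2)
  expect_equal(f1$onset, c(0, 5.03))

  f2 <- derive_fixations(c(0, 10), blinks = interval_set(2, 2.2),
                         saccadic = interval_set(2.2, 2.23))
  expect_equal(nrow(f2), 2)
  expect_equal(f2$offset[1], 2)
  expect_equal(f2$onset[2], 2.23)
})

test_that("events + fixations + dropout partition a generated rest span", {
  cfg <- gen_config(rest_duration = 30, eeg_rate = 200, eye_rate = 500)
  b <- generate_rest(cfg, seed = 41)
  rec <- b$recording
  eye <- alphagaze:::condition_eye(rec, scope = c(0, 30))
  rate <- rec$eye$xl$rate
  span <- c(0, 30)
  cover <- dplyr::bind_rows(
    tibble::tibble(onset = eye$events$blinks$onset,
                   offset = eye$events$blinks$offset),
    tibble::tibble(onset = eye$events$saccades$onset,
                   offset = eye$events$saccades$offset),
    tibble::tibble(onset = eye$events$microsaccades$onset,
                   offset = eye$events$microsaccades$offset),
    tibble::tibble(onset = eye$events$fixations$onset,
                   offset = eye$events$fixations$offset)
  )
  m <- intervals_to_mask(merge_intervals(interval_set(
    pmax(cover$onset, 0), pmin(cover$offset, 30))), rate, 30)
  expect_true(all(!m$valid))  # full cover
  total <- sum(cover$offset - cover$onset)
  expect_equal(total, 30, tolerance = 0.02 * 30)  # near-disjoint cover
})

test_that("window features follow the onset-count rule", {
  pd <- time_series(rep(0.5, 1000), 100)
  av <- time_series(rep(4.8, 1000), 100)
  events <- list(
    blinks = interval_set(c(0.5, 2.5, 4.9), c(1.2, 2.8, 5.4)),
    saccades = tibble::tibble(onset = numeric(0), offset = numeric(0),
                              amplitude = numeric(0)),
    microsaccades = tibble::tibble(onset = 3, offset = 3.01, amplitude = 0.4),
    fixations = interval_set(c(0, 1.4), c(1.0, 2.4))
  )
  w <- window_features(pd, av, events, c(1, 5))
  expect_equal(w$blink_count, 2)  # onset at 4.9 counts, offset-only at 5.4 not
  expect_equal(w$pd_mean, 0.5)
  expect_equal(w$pd_var, 0)
  expect_equal(w$saccade_count, 0)
  expect_true(is.na(w$saccade_amplitude_mean))
  expect_equal(w$microsaccade_count, 1)
  expect_equal(w$microsaccade_amplitude_mean, 0.4)
  expect_equal(w$fixation_count, 1)
})
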