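test_that("trial windows follow the reference-trim and activation-skip rules", {
  trig <- tibble::tibble(time = c(10, 15, 35, 95, 100, 120),
                         code = c(12L, 112L, 212L, 21L, 121L, 221L))
  d <- build_trials(trig)
  expect_equal(nrow(d), 2)
  expect_equal(d$task, c("AN", "SG"))
  expect_equal(d$condition, c("internal", "external"))
  expect_equal(d$act_win_lo[2], 101.5)
  expect_equal(d$act_win_hi[2], 120)
  expect_equal(d$act_win_hi[2] - d$act_win_lo[2], 18.5)
  expect_equal(d$ref_win_hi - d$ref_win_lo, c(4, 4))

  bad <- tibble::tibble(time = c(10, 15), code = c(12L, 111L))
  expect_error(build_trials(bad), "trial 1")
})

test_that("generated sessions yield 36 trials, 9 per design cell", {
  s <- generate_session(cfg_scaled(), seed = 51)
  d <- build_trials(s$recording$triggers)
  expect_equal(nrow(d), 36)
  expect_true(all(table(d$task, d$condition) == 9))
  # trigger-derived labels agree with the trial table
  expect_equal(d$task, s$trials$task)
  expect_equal(d$condition, s$trials$condition)
})

test_that("trial and participant validity implement the inclusion rules", {
  expect_false(trial_validity(TRUE, 0.4, 0.9))
  expect_true(trial_validity(TRUE, 0.51, 0.9))
  expect_false(trial_validity(TRUE, 0.5, 0.9))   # strict 'more than 500 ms'
  expect_false(trial_validity(TRUE, 4, 0.30))
  expect_true(trial_validity(TRUE, 4, 0.34))
  expect_true(trial_validity(TRUE, 4, 1 / 3))    # inclusive 33%
  expect_false(trial_validity(FALSE, 4, 0.9))

  mk <- function(cells, n_correct) {
    d <- expand.grid(task = c("AN", "SG"), condition = c("internal", "external"),
                     rep = 1:9, stringsAsFactors = FALSE)
    d$valid <- FALSE
    for (i in seq_len(4)) {
      cell <- d$task == c("AN", "AN", "SG", "SG")[i] &
        d$condition == c("internal", "external")[c(1, 2, 1, 2)][i]
      d$valid[which(cell)[seq_len(cells[i])]] <- TRUE
    }
    d$correct <- c(rep(TRUE, n_correct), rep(FALSE, 36 - n_correct))
    d
  }
  expect_true(participant_validity(mk(c(3, 3, 3, 3), 20)))
  expect_false(participant_validity(mk(c(2, 9, 9, 9), 20)))
  expect_false(participant_validity(mk(c(9, 9, 9, 9), 17)))
  expect_true(participant_validity(mk(c(9, 9, 9, 9), 18)))
})

test_that("rm_anova on a 2-level factor equals the squared paired t", {
  d <- tibble::tibble(subject = rep(c("A", "B", "C"), each = 2),
                      cond = rep(c("x", "y"), 3),
                      value = c(1, 2, 2, 4, 3, 5))
  res <- rm_anova(d, within = "cond")
  expect_equal(res$F, 25.0, tolerance = 1e-10)

  set.seed(13)
  for (i in 1:100) {
    ns <- sample(3:8, 1)
    d <- tibble::tibble(
      subject = rep(seq_len(ns), each = 2),
      cond = rep(c("a", "b"), ns),
      value = rnorm(2 * ns)
    )
    f <- rm_anova(d, within = "cond")$F
    tt <- t.test(d$value[d$cond == "a"], d$value[d$cond == "b"],
                 paired = TRUE)$statistic
    expect_equal(f, unname(tt^2), tolerance = 1e-8)
  }
})

test_that("rm_anova flags degenerate error terms and is label-exchangeable", {
  d <- tibble::tibble(subject = rep(1:4, each = 2),
                      cond = rep(c("x", "y"), 4),
                      value = rep(1:4, each = 2) + rep(c(0, 1), 4))
  res <- rm_anova(d, within = "cond")
  expect_true(res$degenerate)
  expect_true(is.infinite(res$F))

  set.seed(14)
  d2 <- tibble::tibble(
    subject = rep(1:6, each = 4),
    a = rep(rep(c("l", "r"), each = 2), 6),
    b = rep(c("u", "v"), 12),
    value = rnorm(24)
  )
  r1 <- rm_anova(d2, within = c("a", "b"))
  perm <- setNames(sample(1:6), 1:6)
  d3 <- d2; d3$subject <- perm[as.character(d2$subject)]
  r2 <- rm_anova(d3, within = c("a", "b"))
  expect_equal(r1$F, r2$F, tolerance = 1e-10)

  expect_error(rm_anova(d2[d2$subject == 1, ], within = c("a", "b")),
               "at least 2")
})

test_that("rm_anova matches the multistratum aov oracle on a 2x2x2 design", {
  set.seed(15)
  d <- expand.grid(subject = factor(1:7), a = c("a1", "a2"),
                   b = c("b1", "b2"), c = c("c1", "c2"),
                   stringsAsFactors = TRUE)
  d$value <- rnorm(nrow(d)) + as.integer(d$a) * 0.5
  mine <- rm_anova(d, within = c("a", "b", "c"))

  oracle <- stats::aov(value ~ a * b * c + Error(subject / (a * b * c)),
                       data = d)
  so <- summary(oracle)
  for (eff in c("a", "b", "c", "a:b", "a:c", "b:c", "a:b:c")) {
    stratum <- so[[paste0("Error: subject:", eff)]][[1]]
    f_oracle <- stratum[trimws(rownames(stratum)) == eff, "F value"]
    expect_equal(mine$F[mine$effect == eff], f_oracle, tolerance = 1e-8)
  }
})

test_that("within-subject sums of squares close the decomposition", {
  set.seed(16)
  d <- expand.grid(subject = factor(1:5), a = c("a1", "a2"),
                   b = c("b1", "b2", "b3"), stringsAsFactors = TRUE)
  d$value <- rnorm(nrow(d))
  res <- rm_anova(d, within = c("a", "b"))
  cell_means <- d$value
  subj_means <- ave(d$value, d$subject)
  ss_total_within <- sum((cell_means - subj_means)^2)
  expect_equal(sum(res$ss_effect) + sum(res$ss_error), ss_total_within,
               tolerance = 1e-8)
})

test_that("relaxing the activation threshold never loses valid trials", {
  set.seed(17)
  correct <- runif(50) < 0.85
  refs <- runif(50, 0, 4)
  fracs <- runif(50)
  thresholds <- seq(0.6, 0.1, by = -0.1)
  counts <- vapply(thresholds, function(th) {
    sum(trial_validity(correct, refs, fracs, min_act_frac = th))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("bonferroni thresholds reproduce the published critical alphas", {
  expect_equal(bonferroni_threshold(0.05, 12), 0.0041667, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 40), 0.00125)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
  expect_equal(bonferroni_flag(c(0.004, 0.005, NA), 0.00417),
               c(TRUE, FALSE, FALSE))
})

test_that("condition summaries aggregate subjects before averaging", {
  mk <- function(subj, val) {
    tibble::tibble(subject = subj, task = "AN", condition = "internal",
                   valid = TRUE, pd_mean = val)
  }
  two <- dplyr::bind_rows(mk("a", 0), mk("b", 2))
  s <- summarize_conditions(two, params = "pd_mean")
  expect_equal(s$mean, 1)
  expect_equal(s$se, 1)

  same <- dplyr::bind_rows(mk("a", 2), mk("b", 2), mk("c", 2))
  s2 <- summarize_conditions(same, params = "pd_mean")
  expect_equal(s2$se, 0)

  one <- mk("a", 3)
  s3 <- summarize_conditions(one, params = "pd_mean")
  expect_true(is.na(s3$se))
})

test_that("condition time courses are flat for constant input", {
  series <- time_series(rep(2, 5000), 100)
  trials <- tibble::tibble(act_on = c(5, 20), condition = c("internal", "external"))
  tc <- condition_timecourse(series, trials, dur = 10)
  expect_true(all(tc$mean == 2))

  one <- tibble::tibble(act_on = 5, condition = "internal")
  v <- rep(seq_len(50), each = 100)
  tc1 <- condition_timecourse(time_series(v, 100), one, dur = 10)
  manual <- vapply(0:9, function(b) {
    mean(v[(500 + b * 100 + 1):(500 + b * 100 + 100)])
  }, numeric(1))
  expect_equal(tc1$mean, manual)
})
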