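test_that("velocity splitting rectifies and reconstructs exactly", {
  out <- split_velocity(c(2, -3, 0))
  expect_equal(out$forward, c(2, 0, 0))
  expect_equal(out$backward, c(0, 3, 0))

  expect_equal(split_velocity(numeric(5))$forward, numeric(5))
  expect_equal(split_velocity(numeric(5))$backward, numeric(5))

  # property: non-negative channels, exact reconstruction, mutual exclusivity
  withr::with_seed(3, {
    for (k in 1:10) {
      v <- rnorm(200)
      s <- split_velocity(v)
      expect_true(all(s$forward >= 0 & s$backward >= 0))
      expect_equal(s$forward - s$backward, v)
      expect_true(all(s$forward * s$backward == 0))
    }
  })
  expect_error(split_velocity(c(1, NA)), "finite")
})

test_that("tracking cleanup interpolates isolated drops and omits runs", {
  lik <- rep(1, 11)
  pos <- as.numeric(1:11)
  # one low frame between good frames: midpoint, not omitted
  lik1 <- replace(lik, 6, 0.5)
  pos1 <- replace(pos, 6, 999)
  out <- clean_tracking(pos1, lik1, native_rate = 30, target_rate = 30)
  expect_equal(out$position[6], (pos[5] + pos[7]) / 2)
  expect_false(any(out$omitted))

  # two consecutive low frames: both omitted
  lik2 <- replace(lik, 6:7, 0.5)
  out2 <- clean_tracking(pos, lik2, native_rate = 30, target_rate = 30)
  expect_true(all(out2$omitted[6:7]))

  # all likelihoods 1: identity at equal rates
  out3 <- clean_tracking(pos, lik, native_rate = 30, target_rate = 30)
  expect_equal(out3$position, pos)
  expect_false(any(out3$omitted))

  expect_error(clean_tracking(pos, rep(0.1, 11)), "unusable")
  expect_error(clean_tracking(pos, lik, native_rate = 20, target_rate = 30), "native_rate")
})

test_that("camera-to-imaging resampling preserves a smooth trace", {
  t70 <- seq(0, 10, by = 1 / 70)
  x <- sin(t70)
  out <- clean_tracking(x, rep(1, length(x)), native_rate = 70, target_rate = 30)
  t30 <- seq(0, 10, by = 1 / 30)
  expect_equal(length(out$position), length(t30))
  expect_equal(out$position, sin(t30), tolerance = 1e-3)
})

test_that("lever-component removal matches a grid-search oracle", {
  withr::with_seed(11, {
    lever <- cumsum(rnorm(800)) / 10
    # exact linear dependence
    out <- remove_lever_component(2 * lever + 1, lever)
    expect_equal(out$gain, 2)
    expect_lt(diff(range(out$residual)), 1e-10)

    # orthogonal input: zero gain
    noise <- rnorm(800)
    noise <- noise - lever * cov(noise, lever) / var(lever)
    out2 <- remove_lever_component(noise, lever)
    expect_equal(out2$gain, 0, tolerance = 1e-10)
    expect_equal(out2$residual, noise, tolerance = 1e-8)

    # random trace: gain agrees with brute-force grid minimization of the
    # residual SD over g in [-10, 10] step 1e-4
    rf <- 1.7 * lever + rnorm(800)
    out3 <- remove_lever_component(rf, lever)
    grid <- seq(-10, 10, by = 1e-4)
    # var(rf - g*lever) = var(rf) - 2 g cov + g^2 var(lever)
    obj <- var(rf) - 2 * grid * cov(rf, lever) + grid^2 * var(lever)
    g_grid <- grid[which.min(obj)]
    expect_equal(out3$gain, g_grid, tolerance = 1e-4)
    # residual decorrelated from the lever
    expect_lt(abs(cov(out3$residual, lever)), 1e-10 * var(lever))
  })
  expect_error(remove_lever_component(rnorm(10), rep(1, 10)), "constant")
})

test_that("binarization thresholds strictly and is idempotent", {
  expect_equal(binarize_activity(c(0, 0.005, 0.006)), c(0L, 0L, 1L))
  m <- matrix(c(0, 0.01, 0.004, 0.2), 2)
  bm <- binarize_activity(m)
  expect_identical(bm, matrix(c(0L, 1L, 0L, 1L), 2))
  expect_identical(binarize_activity(bm), bm)
  expect_error(binarize_activity(c(-1, 0)), "non-negative")
})

test_that("trial detection applies the threshold-and-hold rule", {
  cfg <- task_config()
  r <- cfg$frame_rate
  flat <- numeric(300)
  expect_equal(nrow(detect_trials(flat, cfg)), 0)

  pulse <- function(dur_s, amp = 4) {
    c(numeric(3 * r), rep(amp, round(dur_s * r)), numeric(3 * r))
  }
  # 0.7 s above threshold -> one success
  t1 <- detect_trials(pulse(0.7), cfg)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$outcome, "success")
  # 0.5 s then return -> one failure
  t2 <- detect_trials(pulse(0.5), cfg)
  expect_equal(t2$outcome, "failure")
  # a dip below threshold at 0.5 s, even briefly, breaks the hold
  lev <- pulse(1.2)
  dip_at <- 3 * r + round(0.5 * r)
  lev[dip_at] <- 2.0
  t3 <- detect_trials(lev, cfg)
  expect_equal(t3$outcome[1], "failure")

  # a pull without the qualifying wait below threshold opens no trial
  lev2 <- c(numeric(round(0.2 * r)), rep(4, r), rep(1, 2), rep(4, r), numeric(3 * r))
  t4 <- detect_trials(lev2, cfg)
  expect_equal(nrow(t4), 1) # the re-pull 2 frames later does not qualify
})

test_that("the detector reproduces the generator's trial table exactly", {
  b <- fx_behavior()
  expect_identical(detect_trials(b$lever_raw, b$config), b$trials)
})

test_that("trajectory error is a metric-like mean absolute deviation", {
  x <- sin(seq(0, 2, by = 1 / 30))
  expect_equal(trajectory_error(x, x), 0)
  expect_equal(trajectory_error(x + 1, x), 1)

  # hand-enumerated 18-frame oracle: triangle vs flat reference
  tri <- c(seq(0, 1, length.out = 9), seq(1, 0, length.out = 9))
  flat <- numeric(18)
  expect_equal(trajectory_error(tri, flat), sum(abs(tri)) / 18)

  # symmetry and the triangle inequality on fixtures
  withr::with_seed(4, {
    a <- rnorm(18); b <- rnorm(18); c <- rnorm(18)
    expect_equal(trajectory_error(a, b), trajectory_error(b, a))
    expect_lte(
      trajectory_error(a, c),
      trajectory_error(a, b) + trajectory_error(b, c) + 1e-12
    )
  })
  expect_error(trajectory_error(rnorm(5), rnorm(5), window = 0.6), "window")
})

test_that("trial averaging aligns windows and drops edge events", {
  fr <- 30
  sig <- numeric(600)
  sig[c(100, 300, 500)] <- 1 # impulses at the event times
  out <- trial_average(sig, c(100, 300, 500), window = c(-1, 1), frame_rate = fr)
  expect_equal(out$n_events, 3)
  expect_equal(out$n_dropped, 0)
  # the averaged trace peaks at lag zero
  expect_equal(out$lag_s[which.max(out$average[1, ])], 0)
  expect_equal(max(out$average), 1)

  # single event: the aligned window itself
  one <- trial_average(sig, 300, window = c(-1, 1), frame_rate = fr)
  expect_equal(one$average[1, ], sig[270:330])

  # events whose window exits the recording are dropped and counted
  out2 <- trial_average(sig, c(10, 300), window = c(-1, 1), frame_rate = fr)
  expect_equal(out2$n_events, 1)
  expect_equal(out2$n_dropped, 1)
  expect_error(trial_average(sig, 5, window = c(-1, 1), frame_rate = fr), "no event")
})

test_that("trial-to-trial correlation separates reproducible from noise trials", {
  fr <- 30
  template <- sin(seq(0, 4 * pi, length.out = 121))
  same <- matrix(rep(template, 12), nrow = 12, byrow = TRUE)
  out <- trial_to_trial_correlation(same, n_pairs = 200, seed = 1, frame_rate = fr)
  expect_equal(out$mean_correlation, 1)
  expect_true(out$significant)

  withr::with_seed(2, {
    noise <- matrix(rnorm(12 * 121), nrow = 12)
  })
  out2 <- trial_to_trial_correlation(noise, n_pairs = 1000, seed = 1, frame_rate = fr)
  expect_lt(abs(out2$mean_correlation), 3 / sqrt(1000))

  # two trials: every sampled pair is the same pair
  two <- rbind(template, template + rnorm(121, sd = 0.3))
  out3 <- trial_to_trial_correlation(two, n_pairs = 50, seed = 1, frame_rate = fr)
  expect_equal(out3$mean_correlation, cor(two[1, ], two[2, ]))

  # constant trials are flagged and excluded
  mixed <- rbind(same[1:3, ], matrix(5, 1, 121))
  out4 <- trial_to_trial_correlation(mixed, n_pairs = 400, seed = 1, frame_rate = fr)
  expect_gt(out4$n_excluded, 0)
  expect_error(trial_to_trial_correlation(same[1, , drop = FALSE]), "two trials")
})

test_that("identical traces across sessions are always classified stable", {
  withr::with_seed(5, {
    base <- matrix(rnorm(30 * 60), 30)
    sessions <- list(base, base, base, base)
  })
  out <- classify_stable_neurons(sessions, n_shuffles = 500, seed = 2)
  expect_true(all(out$stable))
  expect_equal(out$mean_correlation, rep(1, 30))
  expect_error(classify_stable_neurons(sessions[1]), "two sessions")
})

test_that("noise neurons are classified stable at about the nominal 5% rate", {
  withr::with_seed(6, {
    sessions <- lapply(1:4, function(s) matrix(rnorm(400 * 40), 400))
  })
  out <- classify_stable_neurons(sessions, n_shuffles = 2000, seed = 3)
  # 400 exchangeable neurons vs a 95th-percentile null
  expect_gt(mean(out$stable), 0.01)
  expect_lt(mean(out$stable), 0.11)
})

test_that("the set-wait ladder relaxes then tightens the inter-trial requirement", {
  cfg_fixed <- task_config()
  cfg_ladder <- task_config(set_wait_ladder = TRUE)
  r <- 30
  # pulses separated by a 0.1 s rest: admissible early in the ladder
  # (wait 0.01 s) but not under the fixed 0.6 s requirement
  pulse <- c(rep(4, 21), numeric(4)) # 0.7 s hold, 4-frame (0.13 s) rest
  lever <- c(numeric(30), rep(pulse, 10))
  t_fixed <- detect_trials(lever, cfg_fixed)
  t_ladder <- detect_trials(lever, cfg_ladder)
  expect_gt(nrow(t_ladder), nrow(t_fixed))
  # after 25 successes the ladder steps to 0.2 s (6 frames), so the 4-frame
  # rests stop qualifying and trials thin out
  lever_long <- c(numeric(30), rep(pulse, 40))
  t_long <- detect_trials(lever_long, cfg_ladder)
  expect_lte(sum(t_long$outcome == "success"), 26)
})
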