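test_that("task_config validates its invariants", {
  expect_s3_class(task_config(), "task_config")
  expect_error(task_config(pull_threshold = -1), "strictly positive")
  expect_error(task_config(hold_duration = 0), "strictly positive")
  expect_error(task_config(zone_k = 1), "between 0 and 1")
  expect_error(task_config(zone_k = 0), "between 0 and 1")
})

test_that("target-zone half-width follows the k^n decay plus waiting bonus", {
  cfg <- task_config()
  expect_equal(target_zone_half_width(0, 0, cfg), 3.5)
  expect_equal(target_zone_half_width(1, 0, cfg), 0.995 * 3.5)
  expect_equal(target_zone_half_width(0, 10, cfg), 3.5 + 10 * 0.004)
  # strictly decreasing in the number of successes at zero wait
  w <- target_zone_half_width(0:50, 0, cfg)
  expect_true(all(diff(w) < 0))
  expect_error(target_zone_half_width(-1, 0, cfg), "non-negative")
  expect_error(target_zone_half_width(0, -2, cfg), "non-negative")
})

test_that("simulated sessions are deterministic and respect lever bounds", {
  cfg <- task_config()
  b1 <- simulate_behavior(cfg, 120, skill = 0.7, seed = 5)
  b2 <- simulate_behavior(cfg, 120, skill = 0.7, seed = 5)
  expect_identical(b1$behavior, b2$behavior)
  expect_identical(b1$trials, b2$trials)
  b3 <- simulate_behavior(cfg, 120, skill = 0.7, seed = 6)
  expect_false(identical(b1$behavior, b3$behavior))

  expect_true(all(b1$lever_raw >= 0 & b1$lever_raw <= cfg$travel_limit))
  expect_error(simulate_behavior(cfg, 10), "at least 60")
})

test_that("every rewarded trial satisfies the hold rule exactly", {
  cfg <- task_config()
  b <- fx_behavior()
  hold_f <- round(cfg$hold_duration * cfg$frame_rate)
  above <- b$lever_raw > cfg$pull_threshold
  for (k in seq_len(nrow(b$trials))) {
    tr <- b$trials[k, ]
    run <- tr$init_frame:(tr$init_frame + hold_f - 1)
    if (tr$outcome == "success") {
      expect_true(all(above[run]))
      # reward follows the command by the configured delay (unless delivery
      # would fall past the end of the recording)
      if (!is.na(tr$reward_frame)) {
        expect_equal(
          tr$reward_frame - tr$command_frame,
          round(cfg$reward_delay * cfg$frame_rate)
        )
      }
    } else {
      expect_false(all(run <= b$n_frames) && all(above[run]))
    }
  }
  # no reward without a qualifying trial
  rew <- which(b$behavior$reward == 1L)
  expect_setequal(rew, b$trials$reward_frame[!is.na(b$trials$reward_frame)])
})

test_that("session serialization round-trips byte-identically", {
  b <- fx_session()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_session_bundle(b, dir1)
  b2 <- read_session_bundle(dir1)
  write_session_bundle(b2, dir2)
  for (f in c("behavior.csv", "trials.csv", "activity.mtx", "meta.json")) {
    expect_identical(
      readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
      info = f
    )
  }
  expect_equal(as.data.frame(b2$behavior), as.data.frame(b$behavior), tolerance = 1e-12)
  expect_identical(b2$activity, b$activity)
})

test_that("licking follows rewards and forepaws couple to the lever", {
  b <- fx_behavior()
  rew <- which(b$behavior$reward == 1L)
  lick <- which(b$behavior$lick == 1L)
  # a lick burst within a second of most rewards (consummatory bursts are
  # omitted on a fraction of trials by design)
  hits <- vapply(rew, function(rf) any(lick > rf & lick <= rf + 30), logical(1))
  expect_gt(mean(hits), 0.7)
  # RF_lever(-) is decorrelated from the lever, the raw RF was not
  expect_lt(abs(cor(b$behavior$rf_x, b$lever_raw)), 0.05)
})

test_that("Bernoulli activity generator hits its target rate", {
  b <- fx_behavior()
  d <- fx_design()
  n_frames <- b$n_frames
  # zero kernels, intercept calibrated for the observed sparseness 0.006:
  # empirical rate within 3 SE over >= 50,000 neuron-frames
  truth <- make_ground_truth(8, d, labels = rep("noise", 8), rate = 0.006, seed = 3)
  A <- simulate_activity(b, truth, d, seed = 4)
  F <- length(A)
  expect_gte(F, 50000)
  se <- sqrt(0.006 * (1 - 0.006) / F)
  expect_lt(abs(mean(A) - 0.006), 3 * se)
  expect_true(all(A %in% c(0L, 1L)))
})

test_that("empirical Bernoulli rate stays within 4 SE across seeded runs", {
  b <- fx_behavior()
  d <- fx_design()
  p <- 0.01
  truth <- make_ground_truth(2, d, labels = rep("noise", 2), rate = p, seed = 3)
  F <- 2 * b$n_frames
  bound <- 4 * sqrt(p * (1 - p) / F)
  ok <- vapply(1:20, function(s) {
    A <- simulate_activity(b, truth, d, seed = s)
    abs(mean(A) - p) <= bound
  }, logical(1))
  expect_gte(mean(ok), 0.99 - 1e-9) # allows zero failures in 20 runs
})

test_that("an extreme negative intercept silences all activity", {
  b <- fx_behavior()
  d <- fx_design()
  truth <- make_ground_truth(1, d, labels = "noise", rate = 0.01, seed = 3)
  truth$intercept[1] <- -50 # inverse-logit -> 0 limit
  A <- simulate_activity(b, truth, d, seed = 5)
  expect_true(all(A == 0L))
})

test_that("lever-driven neurons fire more during pulls than between them", {
  b <- fx_session()
  A <- b$activity
  pull <- b$lever_raw > 2.5
  expect_gt(sum(b$trials$outcome == "success"), 20) # enough pull epochs
  for (i in 1:4) { # the lever-driven neurons
    expect_gt(mean(A[i, pull]), mean(A[i, !pull]))
  }
})

test_that("simulate_study keeps stable kernels and the pursued mask fixed", {
  cfg <- task_config()
  st <- fixture("study_small", function() {
    simulate_study(cfg, 12, seeds = 11:14,
      duration = 90, rate = 0.02,
      labels = c(rep("stable", 5), rep("unstable", 4), rep("noise", 3))
    )
  })
  w13 <- st$truth$LS13$weights
  wts2 <- st$truth$TS2$weights
  stable <- which(st$labels == "stable")
  unstable <- which(st$labels == "unstable")
  noise <- which(st$labels == "noise")
  expect_identical(w13[stable, ], wts2[stable, ])
  for (i in unstable) expect_false(identical(w13[i, ], wts2[i, ]))
  expect_true(all(w13[noise, ] == 0))
  expect_identical(st$sessions$LS13$pursued, st$sessions$TS2$pursued)
  expect_named(st$sessions, c("LS13", "LS14", "TS1", "TS2"))
  expect_error(simulate_study(cfg, 12, seeds = 1:3, duration = 90), "4")
  expect_error(simulate_study(cfg, 5, seeds = 1:4, duration = 90), "at least 10")
})

test_that("resampled unstable kernels are uncorrelated across sessions on average", {
  # average ground-truth kernel correlation over >= 100 resampled neurons
  cfg <- task_config()
  b <- fx_behavior()
  d <- fx_design()
  t1 <- make_ground_truth(100, d, labels = rep("unstable", 100), rate = 0.01, seed = 21)
  t2 <- levercode:::resample_unstable(t1, d, seed = 22)
  cc <- vapply(1:100, function(i) cor(t1$weights[i, ], t2$weights[i, ]), numeric(1))
  expect_lt(abs(mean(cc)), 0.15)
})

test_that("the target-zone state machine rewards only in-zone holds", {
  cfg <- task_config()
  b <- simulate_behavior(cfg, 300, skill = 0.7, seed = 8, task = "target_zone")
  tr <- b$trials
  expect_gt(nrow(tr), 5)
  expect_true(all(tr$outcome %in% c("success", "failure")))
  # half-widths shrink as successes accumulate (apart from waiting bonuses)
  succ <- tr[tr$outcome == "success", ]
  if (nrow(succ) >= 2) {
    expect_lt(succ$half_width[nrow(succ)], succ$half_width[1] + 0.5)
  }
  # successful trials spent t_target in the zone
  tgt_f <- round(cfg$t_target * cfg$frame_rate)
  for (k in which(tr$outcome == "success")) {
    seg <- b$lever_raw[tr$init_frame[k]:min(tr$init_frame[k] + 30, b$n_frames)]
    in_zone <- abs(seg - cfg$zone_center) <= tr$half_width[k] + 0.15
    rl <- rle(in_zone)
    expect_true(any(rl$lengths[rl$values] >= tgt_f - 1))
  }
})
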