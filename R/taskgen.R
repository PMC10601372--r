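#' Task configuration for the lever-pull simulators
#'
#' Collects the behavioral-task constants shared by the synthetic session
#' generator and the trial detector. Defaults are the standard task settings:
#' a 30 Hz imaging frame clock, a 2.5 mm pull threshold that must be held
#' continuously for 0.6 s, a 5.0 mm travel limit, a ~176 ms delay between the
#' reward command and water delivery, and a set wait duration (time the lever
#' must rest below threshold before a new trial can start) fixed at 0.6 s as
#' in imaging sessions. The target-zone variant uses a zone centered 5 mm
#' from the natural position whose half-width starts at 3.5 mm and shrinks as
#' `k^n * 3.5` mm with cumulative successes n (k = 0.995), widened by
#' 0.004 mm per second of waiting time since the last reward.
#'
#' @param frame_rate imaging frame rate (Hz).
#' @param pull_threshold pull threshold (mm).
#' @param hold_duration required continuous hold past threshold (s).
#' @param travel_limit maximal lever excursion (mm).
#' @param reward_delay reward-command-to-delivery delay (s).
#' @param set_wait_duration required sub-threshold rest before a trial (s).
#' @param set_wait_ladder when `TRUE`, the set wait duration steps through
#'   0.01, 0.2, 0.4, 0.6 and 1.0 s every 25 successful trials (the training
#'   schedule); when `FALSE` (default, as in imaging sessions) it is fixed
#'   at `set_wait_duration`.
#' @param zone_center,zone_k,zone_w0,zone_wait_gain target-zone parameters:
#'   center (mm), per-success decay (unitless, in (0,1)), initial half-width
#'   (mm) and waiting-time widening gain (mm/s).
#' @param t_target required continuous in-zone time in the target-zone task (s).
#' @param seed integer seed attached to the configuration.
#' @return An object of class `task_config` (a named list).
#' @examples
#' cfg <- task_config()
#' cfg$pull_threshold
#' @export
task_config <- function(frame_rate = 30,
                        pull_threshold = 2.5,
                        hold_duration = 0.6,
                        travel_limit = 5.0,
                        reward_delay = 0.176,
                        set_wait_duration = 0.6,
                        set_wait_ladder = FALSE,
                        zone_center = 5.0,
                        zone_k = 0.995,
                        zone_w0 = 3.5,
                        zone_wait_gain = 0.004,
                        t_target = 0.2,
                        seed = 1L) {
  num_pos <- c(
    frame_rate = frame_rate, pull_threshold = pull_threshold,
    hold_duration = hold_duration, travel_limit = travel_limit,
    reward_delay = reward_delay, set_wait_duration = set_wait_duration,
    zone_center = zone_center, zone_w0 = zone_w0, t_target = t_target
  )
  if (any(!is.finite(num_pos)) || any(num_pos <= 0)) {
    stop("all task durations, rates and distances must be strictly positive", call. = FALSE)
  }
  if (!is.finite(zone_k) || zone_k <= 0 || zone_k >= 1) {
    stop("zone_k must lie strictly between 0 and 1", call. = FALSE)
  }
  if (zone_wait_gain < 0) stop("zone_wait_gain must be non-negative", call. = FALSE)
  structure(
    list(
      frame_rate = frame_rate, pull_threshold = pull_threshold,
      hold_duration = hold_duration, travel_limit = travel_limit,
      reward_delay = reward_delay, set_wait_duration = set_wait_duration,
      set_wait_ladder = isTRUE(set_wait_ladder),
      zone_center = zone_center, zone_k = zone_k, zone_w0 = zone_w0,
      zone_wait_gain = zone_wait_gain, t_target = t_target,
      seed = as.integer(seed)
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "<task_config> %g Hz; threshold %.1f mm held %.2g s; limit %.1f mm; reward delay %.0f ms\n",
    x$frame_rate, x$pull_threshold, x$hold_duration, x$travel_limit,
    1000 * x$reward_delay
  ))
  invisible(x)
}

#' Adaptive half-width of the target zone
#'
#' The target-zone task shrinks the acceptance window around the 5 mm zone
#' center as performance improves: after `n_success` cumulative successes the
#' half-width is `k^n * 3.5` mm, and `T_wait * 0.004` mm is added back when
#' the animal has waited `T_wait` seconds since the last reward.
#'
#' @param n_success cumulative number of successes in the session.
#' @param t_wait time since the last reward (s).
#' @param config a [task_config()].
#' @return Half-width in mm.
#' @examples
#' target_zone_half_width(0, 0) # 3.5
#' target_zone_half_width(1, 0) # 0.995 * 3.5
#' target_zone_half_width(0, 10) # 3.5 + 0.04
#' @export
target_zone_half_width <- function(n_success, t_wait, config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  if (any(n_success < 0) || any(t_wait < 0)) {
    stop("n_success and t_wait must be non-negative", call. = FALSE)
  }
  config$zone_k^n_success * config$zone_w0 + t_wait * config$zone_wait_gain
}

# internal: smooth a trace with a unit-area Gaussian window (sd in seconds)
smooth_gauss <- function(x, sd_s, frame_rate) {
  sd_f <- sd_s * frame_rate
  half <- max(1L, ceiling(3 * sd_f))
  w <- exp(-(seq(-half, half))^2 / (2 * sd_f^2))
  w <- w / sum(w)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  stats::filter(xp, w, sides = 2)[(half + 1):(half + n)]
}

# internal: generate the lever trace of a self-initiated session.
# Pulls are smoothed trapezoidal pulses; the hold-duration distribution
# depends on skill (probability that a pull holds past the required 0.6 s).
sim_lever_self_initiated <- function(config, n, skill) {
  r <- config$frame_rate
  lever <- numeric(n)
  hold_f <- round(config$hold_duration * r)
  wait_f <- round(config$set_wait_duration * r)
  t <- wait_f + 1L # guarantee an initial qualifying wait
  while (t < n) {
    t <- t + round(r * rexp(1, rate = 1 / 4)) + wait_f # inter-pull interval
    if (t >= n) break
    # a quarter of lever movements are sub-threshold "checking" pulls that
    # never open a trial; they decorrelate lever position from the
    # trial/reward structure, as fidgety real mice do
    checking <- runif(1) < 0.25
    if (checking) {
      amp <- runif(1, 0.3 * config$pull_threshold, 0.9 * config$pull_threshold)
      hold_s <- runif(1, 0.1, 0.8)
    } else {
      amp <- runif(1, config$pull_threshold + 0.7, config$travel_limit)
      success_intent <- runif(1) < skill
      hold_s <- if (success_intent) {
        config$hold_duration + 0.05 + rexp(1, 1 / 0.3)
      } else {
        runif(1, 0.1, config$hold_duration * 0.85)
      }
    }
    rise_f <- round(r * runif(1, 0.1, 0.25))
    fall_f <- round(r * runif(1, 0.15, 0.35))
    plateau_f <- max(1L, round(r * hold_s))
    pulse <- c(
      seq(0, amp, length.out = rise_f + 1L)[-1],
      amp + rnorm(plateau_f, 0, 0.05),
      seq(amp, 0, length.out = fall_f + 1L)[-1]
    )
    idx <- t + seq_along(pulse) - 1L
    keep <- idx <= n
    lever[idx[keep]] <- pmax(lever[idx[keep]], pulse[keep])
    t <- idx[length(idx)] + 1L
  }
  lever <- lever + 0.02 * abs(rnorm(n))
  lever <- smooth_gauss(lever, 0.02, r)
  pmin(pmax(lever, 0), config$travel_limit)
}

# internal: lever trace + trial table for a target-zone session state machine.
# States: ITI (hold < 0.5 mm for 1 s) -> Ready -> Go (1 s response period;
# success iff continuously in the adaptive zone for t_target) -> Success /
# Failure (2 s, pulls ignored) -> ITI.
sim_lever_target_zone <- function(config, n, skill) {
  r <- config$frame_rate
  lever <- 0.1 * abs(rnorm(n))
  trials <- list()
  n_success <- 0L
  last_reward_f <- 0L
  t <- round(r) + 1L
  while (t < n - 2 * r) {
    t <- t + round(r * (1 + rexp(1, 1 / 3))) # ITI holding time
    if (t >= n - 3 * r) break
    t_wait <- (t - last_reward_f) / r
    hw <- target_zone_half_width(n_success, t_wait, config)
    on_target <- runif(1) < skill
    amp <- if (on_target) {
      config$zone_center + runif(1, -0.5, 0.5) * hw
    } else {
      config$zone_center + sample(c(-1, 1), 1) * runif(1, 1.05, 2) * hw
    }
    amp <- max(amp, config$pull_threshold + 0.2)
    dwell_s <- if (on_target) config$t_target + runif(1, 0.05, 0.3) else runif(1, 0.05, config$t_target)
    rise_f <- round(r * 0.15)
    fall_f <- round(r * 0.25)
    plateau_f <- max(1L, round(r * dwell_s))
    pulse <- c(
      seq(0, amp, length.out = rise_f + 1L)[-1],
      amp + rnorm(plateau_f, 0, 0.03),
      seq(amp, 0, length.out = fall_f + 1L)[-1]
    )
    idx <- t + seq_along(pulse) - 1L
    keep <- idx <= n
    lever[idx[keep]] <- pulse[keep]
    # judge against the zone over the Go response period
    go_end <- min(t + round(r), n)
    in_zone <- abs(lever[t:go_end] - config$zone_center) <= hw
    rl <- rle(in_zone)
    ok <- any(rl$lengths[rl$values] >= round(config$t_target * r))
    init_f <- t
    if (ok) {
      n_success <- n_success + 1L
      cmd <- t + which(cumsum(in_zone * 1) >= round(config$t_target * r))[1] - 1L
      reward_f <- cmd # immediate delivery in this variant
      last_reward_f <- reward_f
      trials[[length(trials) + 1L]] <- tibble::tibble(
        init_frame = init_f, outcome = "success",
        command_frame = cmd, reward_frame = reward_f, half_width = hw
      )
    } else {
      trials[[length(trials) + 1L]] <- tibble::tibble(
        init_frame = init_f, outcome = "failure",
        command_frame = NA_integer_, reward_frame = NA_integer_, half_width = hw
      )
    }
    t <- idx[length(idx)] + 2L * round(r) # Success/Failure state: 2 s
  }
  list(
    lever = pmin(pmax(lever, 0), 2 * config$travel_limit),
    trials = dplyr::bind_rows(trials)
  )
}

#' Simulate a behavioral session
#'
#' Generates the behavioral side of a synthetic session on the imaging frame
#' clock: a lever trace built from smoothed pull pulses whose hold durations
#' depend on `skill`, the trial table implied by the task state machine,
#' reward delivery after the configured delay, lick bursts following rewards
#' with jittered latency, a jaw trace coupled to licking, and forepaw traces
#' (right forepaw = gain x lever + smooth noise; left forepaw = smooth noise).
#' The right-forepaw columns in the canonical matrix are the lever-independent
#' residuals (see [remove_lever_component()]). Trials are produced by running
#' [detect_trials()] on the generated lever trace, so the generator and the
#' detector agree exactly by construction.
#'
#' @param config a [task_config()].
#' @param duration session duration in seconds (>= 60).
#' @param skill pull skill in `[0, 1]`: probability that a pull is held long
#'   enough to succeed (self-initiated) or lands in the zone (target-zone).
#' @param seed integer seed; the same `(config, duration, skill, seed)`
#'   reproduces the session bit-for-bit.
#' @param task `"self_initiated"` (default) or `"target_zone"`.
#' @return A `session_bundle` (without activity): list with `behavior`
#'   (tibble, 20 canonical columns), `trials`, `lever_raw`, `frame_rate`,
#'   `n_frames`, `session_id`, `task`.
#' @export
simulate_behavior <- function(config, duration, skill = 0.8, seed = 1L,
                              task = c("self_initiated", "target_zone")) {
  stopifnot(inherits(config, "task_config"))
  task <- match.arg(task)
  if (!is.numeric(duration) || duration < 60) {
    stop("duration must be at least 60 s", call. = FALSE)
  }
  if (skill < 0 || skill > 1) stop("skill must lie in [0, 1]", call. = FALSE)
  r <- config$frame_rate
  n <- round(duration * r)

  withr::with_seed(as.integer(seed), {
    if (task == "self_initiated") {
      lever <- sim_lever_self_initiated(config, n, skill)
      trials <- detect_trials(lever, config)
    } else {
      tz <- sim_lever_target_zone(config, n, skill)
      lever <- tz$lever
      trials <- tz$trials
    }

    reward <- integer(n)
    rew_frames <- trials$reward_frame[!is.na(trials$reward_frame)]
    reward[rew_frames[rew_frames <= n]] <- 1L

    # licking: bursts after rewards with substantial trial-to-trial
    # variability (latency jitter, variable duration and rate, occasional
    # omissions), plus spontaneous bursts and isolated licks - uninstructed
    # orofacial behavior is far less stereotyped than the trained pull
    lick <- integer(n)
    jaw_drive <- numeric(n)
    emit_burst <- function(start) {
      len <- round(r * runif(1, 0.3, 1.5))
      gap <- max(2L, round(r / runif(1, 5, 9)))
      start <- max(start, 1L)
      if (start > n) return(invisible(NULL))
      at <- seq(start, min(start + len, n), by = gap)
      at <- at[at >= 1 & at <= n]
      lick[at] <<- 1L
      gain <- runif(1, 0.5, 1.6)
      jaw_drive[at] <<- pmax(jaw_drive[at], gain)
    }
    for (rf in rew_frames) {
      if (runif(1) < 0.15) next # omitted consummatory burst
      emit_burst(rf + round(r * pmax(0.05, rnorm(1, 0.25, 0.12))))
    }
    n_spont <- rpois(1, n / r / 30) # ~2 spontaneous bursts per minute
    for (st in sample.int(n, n_spont)) emit_burst(st)
    lick[runif(n) < 0.3 / r] <- 1L

    # jaw: continuous trace driven by the (variable-gain) lick train plus
    # independent slow noise
    jaw <- 1.5 * smooth_gauss(jaw_drive, 0.12, r) +
      0.45 * smooth_gauss(rnorm(n), 0.3, r)

    # forepaws: RF partly coupled to the lever, LF uninstructed
    rf_gain_x <- 0.8
    rf_gain_y <- 0.5
    rf_raw_x <- rf_gain_x * lever + 0.45 * smooth_gauss(rnorm(n), 0.15, r)
    rf_raw_y <- rf_gain_y * lever + 0.45 * smooth_gauss(rnorm(n), 0.15, r)
    lf_x <- 0.5 * smooth_gauss(rnorm(n), 0.15, r)
    lf_y <- 0.5 * smooth_gauss(rnorm(n), 0.15, r)

    rf_x <- remove_lever_component(rf_raw_x, lever)$residual
    rf_y <- remove_lever_component(rf_raw_y, lever)$residual

    behavior <- build_behavior_matrix(
      lever = lever, rf_x = rf_x, rf_y = rf_y, lf_x = lf_x, lf_y = lf_y,
      jaw = jaw, lick = lick, reward = reward, frame_rate = r
    )

    structure(
      list(
        behavior = behavior, trials = trials, lever_raw = lever,
        activity = NULL, truth = NULL, pursued = NULL,
        frame_rate = r, n_frames = n, session_id = NA_character_,
        task = task, config = config, seed = as.integer(seed)
      ),
      class = "session_bundle"
    )
  })
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf(
    "<session_bundle> %s: %d frames @ %g Hz, %d trials (%d success)%s\n",
    ifelse(is.na(x$session_id), "(unnamed)", x$session_id),
    x$n_frames, x$frame_rate, nrow(x$trials),
    sum(x$trials$outcome == "success"),
    if (!is.null(x$activity)) sprintf(", %d neurons", nrow(x$activity)) else ""
  ))
  invisible(x)
}

#' Ground-truth encoding kernels for simulated neurons
#'
#' Draws per-neuron ground-truth GLM weights in the basis expansion space.
#' Informative neurons load on lever position and pull velocity (bases near
#' the movement), with small loadings on other variables; `noise` neurons
#' have all-zero kernels. Weights are scaled so the linear predictor has the
#' requested standard deviation (`snr`) on a reference design, and intercepts
#' are calibrated so each neuron's expected positive-frame fraction equals
#' `rate`.
#'
#' @param n_neurons number of neurons (>= 1).
#' @param design a reference `design_matrix` (used for scaling/calibration).
#' @param labels character vector of per-neuron labels
#'   (`"stable"`, `"unstable"`, `"noise"`); recycled from `frac_*` if `NULL`.
#' @param frac_stable,frac_noise fractions used when `labels` is `NULL`.
#' @param rate target positive-frame fraction (default 0.006, the empirical
#'   sparseness of binarized activity).
#' @param snr standard deviation of the kernel-driven linear predictor
#'   (log-odds units).
#' @param seed integer seed.
#' @return Object of class `ground_truth`: list with `weights` (neurons x
#'   regressors), `intercept`, `labels`, `rate`, `variables`.
#' @export
make_ground_truth <- function(n_neurons, design, labels = NULL,
                              frac_stable = 0.4, frac_noise = 0.3,
                              rate = 0.006, snr = 2, seed = 1L) {
  stopifnot(inherits(design, "design_matrix"), n_neurons >= 1)
  if (is.null(labels)) {
    n_stable <- round(frac_stable * n_neurons)
    n_noise <- round(frac_noise * n_neurons)
    labels <- c(
      rep("stable", n_stable),
      rep("unstable", n_neurons - n_stable - n_noise),
      rep("noise", n_noise)
    )
  }
  stopifnot(length(labels) == n_neurons, all(labels %in% c("stable", "unstable", "noise")))
  withr::with_seed(as.integer(seed), {
    W <- matrix(0, n_neurons, ncol(design$X), dimnames = list(NULL, colnames(design$X)))
    b0 <- numeric(n_neurons)
    for (i in seq_len(n_neurons)) {
      if (labels[i] == "noise") {
        b0[i] <- qlogis(rate)
        next
      }
      w <- draw_truth_weights(design)
      eta <- drop(design$X %*% w)
      w <- w * snr / max(sd(eta), 1e-12)
      W[i, ] <- w
      b0[i] <- calibrate_intercept(drop(design$X %*% w), rate)
    }
    structure(
      list(
        weights = W, intercept = b0, labels = labels, rate = rate, snr = snr,
        variables = design$variables
      ),
      class = "ground_truth"
    )
  })
}

# internal: one draw of raw (unscaled) ground-truth weights.
# Informative neurons carry smooth, unimodal lag kernels on the lever
# variables (a Gaussian bump of basis weights centered at a
# movement-proximal lag), mimicking the pull-locked tuning of motor-cortex
# neurons.  Smooth kernels keep the recovery problem well posed: the fitted
# model may redistribute weight among neighboring (correlated) bases without
# changing the kernel shape in lag space.
draw_truth_weights <- function(design, variables = NULL) {
  centers <- design$basis$centers
  w <- numeric(ncol(design$X))
  if (is.null(variables)) {
    variables <- intersect(
      c("lever_position", "lever_velocity_pull"), design$variables
    )
  }
  for (v in variables) {
    cols <- which(design$variable_of == v)
    c0 <- runif(1, -0.3, 0.9) # bump center (s): behavior just before/at spikes
    width <- runif(1, 0.25, 0.45)
    amp <- sample(c(-1, 1), 1) * runif(1, 0.5, 1)
    wv <- amp * exp(-(centers - c0)^2 / (2 * width^2))
    # equalize each variable's leverage on the linear predictor
    s <- sd(drop(design$X[, cols, drop = FALSE] %*% wv))
    w[cols] <- wv / max(s, 1e-12)
  }
  w
}

# internal: intercept such that mean(plogis(b0 + eta)) == rate
calibrate_intercept <- function(eta, rate) {
  f <- function(b0) mean(plogis(b0 + eta)) - rate
  uniroot(f, c(-40, 10), tol = 1e-10)$root
}

#' Simulate binarized activity from ground-truth kernels
#'
#' Each neuron-frame is an independent Bernoulli draw with probability
#' `plogis(intercept_i + weights_i . design_row_t)` - the generative twin of
#' the encoding model, so fitted kernels can be compared against known truth.
#'
#' @param bundle a `session_bundle` from [simulate_behavior()].
#' @param truth a [make_ground_truth()] object.
#' @param design the design matrix built from `bundle$behavior` with the
#'   canonical basis.
#' @param seed integer seed.
#' @return Integer matrix (neurons x frames) of 0/1 activity.
#' @export
simulate_activity <- function(bundle, truth, design, seed = 1L) {
  stopifnot(
    inherits(bundle, "session_bundle"), inherits(truth, "ground_truth"),
    inherits(design, "design_matrix")
  )
  if (nrow(design$X) != bundle$n_frames) {
    stop("design and behavior disagree on the number of frames", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    eta <- truth$weights %*% t(design$X) # neurons x frames
    eta <- sweep(eta, 1, truth$intercept, "+")
    p <- plogis(eta)
    A <- matrix(rbinom(length(p), 1L, as.vector(p)), nrow(p), ncol(p))
    storage.mode(A) <- "integer"
    A
  })
}

#' Simulate a four-session imaging study
#'
#' Emulates the longitudinal design of the imaging experiment: two late
#' learning sessions (LS13, LS14) and two test sessions after nontraining
#' days (TS1, TS2), with a common population of neurons. Stable neurons keep
#' identical ground-truth kernels across all four sessions; unstable neurons
#' have their kernels independently resampled per session; noise neurons have
#' zero kernels throughout. A pursued mask (neurons tracked in every session)
#' is constant across sessions.
#'
#' @param config a [task_config()].
#' @param n_neurons number of neurons (>= 10).
#' @param seeds four integer seeds, one per session.
#' @param duration session duration in seconds (default 1800 s, the length of
#'   an imaging session at 30 Hz).
#' @param skill pull skill passed to [simulate_behavior()].
#' @param rate,snr,frac_stable,frac_noise,labels passed to
#'   [make_ground_truth()].
#' @param pursued_fraction fraction of neurons flagged as pursued.
#' @param basis basis set used for the generative design (default canonical).
#' @return List with `sessions` (named list of four `session_bundle`s, each
#'   with activity and a `truth` attached), `truth` (list per session),
#'   `labels`, `pursued`, `basis`.
#' @export
simulate_study <- function(config, n_neurons, seeds,
                           duration = 1800, skill = 0.8,
                           rate = 0.006, snr = 2,
                           frac_stable = 0.4, frac_noise = 0.3,
                           labels = NULL,
                           pursued_fraction = 0.8,
                           basis = gaussian_basis(config$frame_rate)) {
  stopifnot(inherits(config, "task_config"))
  if (n_neurons < 10) stop("n_neurons must be at least 10", call. = FALSE)
  if (length(seeds) < 4) stop("simulate_study needs one seed per session (4)", call. = FALSE)
  seeds <- as.integer(seeds[1:4])
  session_ids <- c("LS13", "LS14", "TS1", "TS2")

  sessions <- list()
  truths <- list()
  base_truth <- NULL
  pursued <- NULL
  for (k in 1:4) {
    b <- simulate_behavior(config, duration, skill, seed = seeds[k])
    b$session_id <- session_ids[k]
    d <- expand_design(b$behavior, basis)
    if (k == 1) {
      base_truth <- make_ground_truth(
        n_neurons, d,
        labels = labels, frac_stable = frac_stable,
        frac_noise = frac_noise, rate = rate, snr = snr, seed = seeds[1]
      )
      pursued <- withr::with_seed(
        seeds[1],
        seq_len(n_neurons) %in% sample(n_neurons, round(pursued_fraction * n_neurons))
      )
      truth_k <- base_truth
    } else {
      truth_k <- resample_unstable(base_truth, d, seed = seeds[k])
    }
    b$activity <- simulate_activity(b, truth_k, d, seed = seeds[k] + 1L)
    b$truth <- truth_k
    b$pursued <- pursued
    sessions[[session_ids[k]]] <- b
    truths[[session_ids[k]]] <- truth_k
  }
  list(
    sessions = sessions, truth = truths, labels = base_truth$labels,
    pursued = pursued, basis = basis, config = config, seeds = seeds
  )
}

# internal: new ground truth with unstable neurons' kernels resampled
resample_unstable <- function(truth, design, seed) {
  withr::with_seed(as.integer(seed) + 7L, {
    out <- truth
    for (i in which(truth$labels == "unstable")) {
      w <- draw_truth_weights(design)
      eta <- drop(design$X %*% w)
      w <- w * truth$snr / max(sd(eta), 1e-12)
      out$weights[i, ] <- w
      out$intercept[i] <- calibrate_intercept(drop(design$X %*% w), truth$rate)
    }
    out
  })
}

#' Ground-truth kernels as lag functions
#'
#' Converts basis-space ground-truth weights of one neuron into per-variable
#' temporal kernels (weight-summed basis functions over lag), for comparison
#' with kernels recovered by the encoding model.
#'
#' @param truth a [make_ground_truth()] object.
#' @param neuron neuron index.
#' @param basis the basis set used to build the generative design.
#' @return A `kernel_set` (see [extract_kernels()]).
#' @export
truth_kernels <- function(truth, neuron, basis) {
  stopifnot(inherits(truth, "ground_truth"))
  w <- truth$weights[neuron, ]
  kernel_set_from_weights(w, truth$variables, basis)
}
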