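#' Split a signed velocity into directional channels
#'
#' The encoding model represents each velocity as two non-negative channels
#' (e.g. pull vs return for the lever): `forward = max(v, 0)` and
#' `backward = max(-v, 0)`, so `forward - backward` reconstructs the signed
#' input and the two channels are never simultaneously positive.
#'
#' @param signed_velocity numeric vector of signed velocities.
#' @return A tibble with columns `forward` and `backward`.
#' @examples
#' split_velocity(c(2, -3, 0))
#' @export
split_velocity <- function(signed_velocity) {
  if (any(!is.finite(signed_velocity))) {
    stop("signed_velocity must be finite", call. = FALSE)
  }
  tibble::tibble(
    forward = pmax(signed_velocity, 0),
    backward = pmax(-signed_velocity, 0)
  )
}

# internal: frame-clock finite-difference velocity (units/s), first frame 0
frame_velocity <- function(x, frame_rate) {
  c(0, diff(x)) * frame_rate
}

# internal: assemble the canonical 20-column behavior tibble
build_behavior_matrix <- function(lever, rf_x, rf_y, lf_x, lf_y, jaw,
                                  lick, reward, frame_rate,
                                  omitted = NULL) {
  lv <- frame_velocity(lever, frame_rate)
  lvs <- split_velocity(lv)
  sv <- function(x) split_velocity(frame_velocity(x, frame_rate))
  rvx <- sv(rf_x); rvy <- sv(rf_y)
  fvx <- sv(lf_x); fvy <- sv(lf_y)
  jv <- sv(jaw)
  out <- tibble::tibble(
    lever_position = as.numeric(lever),
    lever_velocity_pull = lvs$forward,
    lever_velocity_return = lvs$backward,
    rf_x = as.numeric(rf_x), rf_y = as.numeric(rf_y),
    rf_vx_plus = rvx$forward, rf_vx_minus = rvx$backward,
    rf_vy_plus = rvy$forward, rf_vy_minus = rvy$backward,
    lf_x = as.numeric(lf_x), lf_y = as.numeric(lf_y),
    lf_vx_plus = fvx$forward, lf_vx_minus = fvx$backward,
    lf_vy_plus = fvy$forward, lf_vy_minus = fvy$backward,
    jaw_position = as.numeric(jaw),
    jaw_velocity_open = jv$forward, jaw_velocity_close = jv$backward,
    lick = as.integer(lick), reward = as.integer(reward)
  )
  attr(out, "omitted") <- if (is.null(omitted)) rep(FALSE, nrow(out)) else omitted
  out
}

#' Clean a tracked body-part trace
#'
#' Applies the pose-tracking post-processing rules: frames whose tracking
#' likelihood falls below `likelihood_threshold` are treated as ambiguous;
#' an isolated single ambiguous frame is linearly interpolated from the
#' frames before and after it, while runs of two or more consecutive
#' ambiguous frames are omitted from analysis. The cleaned trace is then
#' resampled from the camera rate to the imaging rate by linear
#' interpolation, with the omitted mask propagated to any target frame whose
#' interpolation interval touches an omitted source frame.
#'
#' @param position numeric vector, one axis of the tracked point.
#' @param likelihood tracking likelihood per frame, in `[0, 1]`.
#' @param likelihood_threshold frames with likelihood below this are
#'   ambiguous (default 0.99).
#' @param native_rate camera frame rate (Hz).
#' @param target_rate imaging frame rate (Hz); must not exceed `native_rate`.
#' @return A tibble with columns `position` and `omitted` on the target
#'   clock.
#' @export
clean_tracking <- function(position, likelihood, likelihood_threshold = 0.99,
                           native_rate = 70, target_rate = 30) {
  stopifnot(length(position) == length(likelihood))
  if (any(likelihood < 0 | likelihood > 1, na.rm = TRUE)) {
    stop("likelihood must lie in [0, 1]", call. = FALSE)
  }
  if (native_rate < target_rate) {
    stop("native_rate must be at least target_rate", call. = FALSE)
  }
  low <- !is.finite(likelihood) | likelihood < likelihood_threshold
  if (all(low)) stop("all frames have low tracking likelihood; trace unusable", call. = FALSE)
  n <- length(position)

  omitted <- rep(FALSE, n)
  x <- position
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    if (r$lengths[k] == 1L && starts[k] > 1L && ends[k] < n) {
      x[starts[k]] <- (x[starts[k] - 1L] + x[ends[k] + 1L]) / 2
    } else {
      omitted[starts[k]:ends[k]] <- TRUE
    }
  }

  t_native <- (seq_len(n) - 1L) / native_rate
  t_target <- seq(0, t_native[n], by = 1 / target_rate)
  good <- !omitted
  pos_t <- approx(t_native[good], x[good], xout = t_target, rule = 2)$y
  # a target frame is omitted if any native frame within one native sample of
  # it was omitted
  om_t <- vapply(t_target, function(tt) {
    any(omitted[abs(t_native - tt) <= 1 / native_rate])
  }, logical(1))
  tibble::tibble(position = pos_t, omitted = om_t)
}

#' Remove the lever-proportional component from a forepaw trace
#'
#' The right forepaw holds the lever, so its raw trajectory is dominated by
#' lever movement. The lever-independent component is obtained by
#' subtracting `gain * lever`, with the session-wise gain chosen to minimize
#' the deviation (variance) of the residual - the closed form
#' `gain = cov(rf, lever) / var(lever)`. The residual has zero covariance
#' with the lever by construction.
#'
#' @param rf forepaw position trace (one axis).
#' @param lever lever position trace, same length, non-constant.
#' @return List with `residual` and `gain`.
#' @examples
#' lever <- sin(seq(0, 10, by = 0.1))
#' out <- remove_lever_component(2 * lever + 0.5, lever)
#' out$gain # 2
#' @export
remove_lever_component <- function(rf, lever) {
  stopifnot(length(rf) == length(lever))
  v <- var(lever)
  if (!is.finite(v) || v < .Machine$double.eps) {
    stop("lever trace is constant; subtraction gain undefined", call. = FALSE)
  }
  g <- cov(rf, lever) / v
  list(residual = rf - g * lever, gain = g)
}

#' Binarize deconvolved activity traces
#'
#' Thresholds deconvolved calcium traces into per-frame binary activity:
#' a frame is active iff its value strictly exceeds `threshold` (default
#' 0.005). Idempotent on already-binary input for any threshold below 1.
#'
#' @param deconvolved numeric vector or matrix of non-negative traces.
#' @param threshold activation threshold.
#' @return Integer 0/1 object with the shape of the input.
#' @examples
#' binarize_activity(c(0, 0.004, 0.006))
#' @export
binarize_activity <- function(deconvolved, threshold = 0.005) {
  if (any(deconvolved < 0, na.rm = TRUE)) {
    stop("deconvolved traces must be non-negative", call. = FALSE)
  }
  out <- (deconvolved > threshold) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Detect lever-pull trials from a lever trace
#'
#' Runs the self-initiated task state machine over a lever trace: a trial
#' opens at an upward crossing of the pull threshold preceded by a
#' qualifying sub-threshold wait (`set_wait_duration`); the trial is a
#' success iff the lever then stays continuously past the threshold for at
#' least `hold_duration`, and a failure if it returns below the threshold,
#' even briefly, before that. For successes the reward command is issued the
#' moment the hold requirement is met and the reward is delivered
#' `reward_delay` later.
#'
#' @param lever lever position trace (mm) on the frame clock.
#' @param config a [task_config()].
#' @return Tibble with one row per trial: `trial`, `init_frame`, `outcome`
#'   (`"success"`/`"failure"`), `command_frame`, `reward_frame`, `end_frame`.
#'   Empty tibble if no trial was initiated.
#' @export
detect_trials <- function(lever, config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  r <- config$frame_rate
  hold_f <- round(config$hold_duration * r)
  wait_f <- round(config$set_wait_duration * r)
  delay_f <- round(config$reward_delay * r)
  n <- length(lever)
  above <- lever > config$pull_threshold

  empty <- tibble::tibble(
    trial = integer(), init_frame = integer(), outcome = character(),
    command_frame = integer(), reward_frame = integer(), end_frame = integer()
  )
  if (!any(above)) return(empty)

  # training schedule: the set wait duration steps up every 25 successes
  ladder <- c(0.01, 0.2, 0.4, 0.6, 1.0)
  n_success <- 0L
  current_wait_f <- function() {
    if (isTRUE(config$set_wait_ladder)) {
      round(ladder[min(n_success %/% 25L + 1L, length(ladder))] * r)
    } else {
      wait_f
    }
  }

  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  rows <- list()
  for (k in seq_along(rl$lengths)) {
    if (!rl$values[k]) next
    # qualifying wait: the preceding below-threshold run must last >= the
    # current set wait duration (the run that starts the recording
    # qualifies regardless)
    if (k == 1L) {
      qualified <- FALSE # lever already above threshold at session start
    } else {
      qualified <- (k == 2L && starts[k - 1L] == 1L) ||
        rl$lengths[k - 1L] >= current_wait_f()
    }
    if (!qualified) next
    init <- starts[k]
    len <- rl$lengths[k]
    if (len >= hold_f) {
      n_success <- n_success + 1L
      cmd <- init + hold_f - 1L
      rew <- cmd + delay_f
      rows[[length(rows) + 1L]] <- tibble::tibble(
        init_frame = init, outcome = "success",
        command_frame = cmd,
        reward_frame = if (rew <= n) rew else NA_integer_,
        end_frame = ends[k]
      )
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        init_frame = init, outcome = "failure",
        command_frame = NA_integer_, reward_frame = NA_integer_,
        end_frame = ends[k]
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, trial = dplyr::row_number(), .before = 1)
}

#' Mean absolute trajectory error over the initial pull window
#'
#' Compares a lever trajectory against a reference (expert) trajectory as the
#' mean absolute difference over the first `window` seconds from pull
#' initiation - the metric used to quantify how stereotyped a learned pull
#' has become.
#'
#' @param trajectory,reference numeric traces aligned at pull initiation.
#' @param window window length in seconds (default 0.6).
#' @param frame_rate frames per second.
#' @return Mean absolute difference (mm).
#' @export
trajectory_error <- function(trajectory, reference, window = 0.6, frame_rate = 30) {
  nf <- round(window * frame_rate)
  if (length(trajectory) < nf || length(reference) < nf) {
    stop("window exceeds the length of the supplied trajectories", call. = FALSE)
  }
  mean(abs(trajectory[seq_len(nf)] - reference[seq_len(nf)]))
}

#' Event-aligned trial average
#'
#' Aligns a signal (one trace per row, or a single vector) to event frames
#' and averages across events over a window from `window[1]` to `window[2]`
#' seconds relative to each event. Events whose window leaves the recording
#' are dropped and counted.
#'
#' @param signal numeric vector, or matrix with one row per neuron/variable.
#' @param events event frames (e.g. successful pull initiations).
#' @param window two-element window in seconds relative to the event
#'   (default `c(-1, 3)`, the task-related period).
#' @param frame_rate frames per second.
#' @return List with `average` (rows x window frames), `lag_s`, `n_events`
#'   used and `n_dropped`.
#' @export
trial_average <- function(signal, events, window = c(-1, 3), frame_rate = 30) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  n <- ncol(signal)
  lo <- round(window[1] * frame_rate)
  hi <- round(window[2] * frame_rate)
  usable <- events[events + lo >= 1 & events + hi <= n]
  n_dropped <- length(events) - length(usable)
  if (length(usable) == 0) {
    stop("no event window fits inside the recording", call. = FALSE)
  }
  lags <- lo:hi
  acc <- matrix(0, nrow(signal), length(lags))
  for (ev in usable) acc <- acc + signal[, ev + lags, drop = FALSE]
  list(
    average = acc / length(usable), lag_s = lags / frame_rate,
    n_events = length(usable), n_dropped = n_dropped
  )
}

# internal: align trials into a trials x frames matrix for one trace
align_trials <- function(signal, events, window = c(-1, 3), frame_rate = 30) {
  n <- length(signal)
  lo <- round(window[1] * frame_rate)
  hi <- round(window[2] * frame_rate)
  usable <- events[events + lo >= 1 & events + hi <= n]
  t(vapply(usable, function(ev) signal[(ev + lo):(ev + hi)], numeric(hi - lo + 1)))
}

#' Trial-to-trial correlation with a time-shifted null
#'
#' Measures the reproducibility of an aligned response across trials: the
#' mean Pearson correlation over `n_pairs` randomly selected pairs of
#' distinct trials. A null distribution is built from the same pairs with the
#' second trial of each pair circularly time-shifted by a random offset
#' (uniform between 0.5 s and the window length minus 0.5 s), and the
#' observed mean is declared significant when it exceeds the null's 95th
#' percentile. Constant trials (zero variance) yield undefined correlations;
#' such pairs are flagged and excluded from averaging.
#'
#' @param aligned_trials matrix, trials x frames.
#' @param n_pairs number of random trial pairs (default 1000).
#' @param seed integer seed.
#' @param frame_rate frames per second (for the shift range).
#' @return List with `mean_correlation`, `null` (vector), `null_95`,
#'   `significant`, `n_excluded`.
#' @export
trial_to_trial_correlation <- function(aligned_trials, n_pairs = 1000,
                                       seed = 1L, frame_rate = 30) {
  stopifnot(is.matrix(aligned_trials))
  nt <- nrow(aligned_trials)
  if (nt < 2) stop("need at least two trials", call. = FALSE)
  nf <- ncol(aligned_trials)
  withr::with_seed(as.integer(seed), {
    i <- sample(nt, n_pairs, replace = TRUE)
    j <- (i + sample(nt - 1L, n_pairs, replace = TRUE) - 1L) %% nt + 1L
    shift_min <- round(0.5 * frame_rate)
    shift_max <- max(shift_min + 1L, nf - shift_min)
    shifts <- sample(seq(shift_min, shift_max), n_pairs, replace = TRUE)

    obs <- numeric(n_pairs)
    nul <- numeric(n_pairs)
    for (k in seq_len(n_pairs)) {
      a <- aligned_trials[i[k], ]
      b <- aligned_trials[j[k], ]
      if (sd(a) == 0 || sd(b) == 0) {
        obs[k] <- NA_real_
        nul[k] <- NA_real_
        next
      }
      obs[k] <- cor(a, b)
      bs <- b[((seq_len(nf) - 1L + shifts[k]) %% nf) + 1L]
      nul[k] <- if (sd(bs) == 0) NA_real_ else cor(a, bs)
    }
    n_excluded <- sum(is.na(obs))
    m <- mean(obs, na.rm = TRUE)
    q95 <- quantile(nul, 0.95, na.rm = TRUE, names = FALSE)
    list(
      mean_correlation = m, null = nul[!is.na(nul)], null_95 = q95,
      significant = is.finite(m) && m > q95, n_excluded = n_excluded
    )
  })
}

#' Classify neurons as stable across sessions
#'
#' A neuron is classified as stable when the mean Pearson correlation of its
#' trial-averaged traces across all session pairs exceeds the 95th percentile
#' of a shuffle null. The default null (`scheme = "repair"`) randomly
#' re-pairs neurons across sessions: each null draw correlates the
#' trial-averaged traces of two different, randomly chosen neurons in two
#' randomly chosen distinct sessions. `scheme = "permute"` instead permutes
#' the neuron labels of whole sessions jointly.
#'
#' @param trial_avg_by_session list (one element per session) of matrices,
#'   neurons x window frames, with identical dimensions.
#' @param n_shuffles number of null draws (default 2000).
#' @param seed integer seed.
#' @param scheme `"repair"` (default) or `"permute"`.
#' @return List with `stable` (logical per neuron), `mean_correlation`
#'   (per neuron), `threshold` (null 95th percentile) and `null`.
#' @export
classify_stable_neurons <- function(trial_avg_by_session, n_shuffles = 2000,
                                    seed = 1L, scheme = c("repair", "permute")) {
  scheme <- match.arg(scheme)
  ns <- length(trial_avg_by_session)
  if (ns < 2) stop("need trial averages from at least two sessions", call. = FALSE)
  dims <- lapply(trial_avg_by_session, dim)
  if (length(unique(dims)) != 1) stop("sessions must have identical dimensions", call. = FALSE)
  nn <- nrow(trial_avg_by_session[[1]])
  pairs <- utils::combn(ns, 2)

  pair_cor <- function(m1, m2, i, j) {
    a <- m1[i, ]; b <- m2[j, ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }
  mean_cor <- vapply(seq_len(nn), function(i) {
    cc <- apply(pairs, 2, function(p) {
      pair_cor(trial_avg_by_session[[p[1]]], trial_avg_by_session[[p[2]]], i, i)
    })
    mean(cc, na.rm = TRUE)
  }, numeric(1))

  withr::with_seed(as.integer(seed), {
    nul <- numeric(n_shuffles)
    if (scheme == "repair") {
      for (k in seq_len(n_shuffles)) {
        cc <- apply(pairs, 2, function(p) {
          ij <- if (nn > 1) sample(nn, 2) else c(1L, 1L)
          pair_cor(
            trial_avg_by_session[[p[1]]], trial_avg_by_session[[p[2]]],
            ij[1], ij[2]
          )
        })
        nul[k] <- mean(cc, na.rm = TRUE)
      }
    } else {
      for (k in seq_len(n_shuffles)) {
        perms <- lapply(seq_len(ns), function(s) sample(nn))
        i0 <- sample(nn, 1)
        cc <- apply(pairs, 2, function(p) {
          pair_cor(
            trial_avg_by_session[[p[1]]], trial_avg_by_session[[p[2]]],
            perms[[p[1]]][i0], perms[[p[2]]][i0]
          )
        })
        nul[k] <- mean(cc, na.rm = TRUE)
      }
    }
    thr <- quantile(nul, 0.95, na.rm = TRUE, names = FALSE)
    list(
      stable = !is.na(mean_cor) & mean_cor > thr,
      mean_correlation = mean_cor, threshold = thr, null = nul
    )
  })
}
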