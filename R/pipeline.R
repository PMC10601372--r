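#' Configuration of an end-to-end synthetic study
#'
#' Bundles every tunable of the pipeline - task constants, simulation sizes,
#' basis, GLM, cross-validation, ranking and decoder parameters, and one
#' explicit seed per stage - into a single validated object that round-trips
#' losslessly through YAML.
#'
#' @param task a [task_config()].
#' @param n_neurons number of simulated neurons (>= 10).
#' @param duration session duration (s).
#' @param skill pull skill in `[0, 1]`.
#' @param rate target positive-frame fraction of the simulated activity.
#' @param snr sd of the ground-truth linear predictor (log-odds).
#' @param frac_stable,frac_noise ground-truth population composition.
#' @param alpha,lambda elastic-net parameters.
#' @param top_band normalized-rank band defining the top group in LS13.
#' @param rank_draws draws of the rank-stability null.
#' @param decode_offsets decoder concatenation offsets (frames at 30 Hz).
#' @param decode_exclusion_s decoder leakage exclusion (s).
#' @param n_controls control populations for the decoding contribution.
#' @param decode_query_step decode every k-th frame (runtime control).
#' @param seeds named integer seeds: `sessions` (4 values), `encode`,
#'   `rank`, `decode`.
#' @return Object of class `study_config`.
#' @export
study_config <- function(task = task_config(),
                         n_neurons = 40,
                         duration = 600,
                         skill = 0.8,
                         rate = 0.01,
                         snr = 2,
                         frac_stable = 0.4,
                         frac_noise = 0.3,
                         alpha = 0.2,
                         lambda = 1e-4,
                         top_band = c(0.8, 1),
                         rank_draws = 10000,
                         decode_offsets = c(-6, -4, -2, 0, 2, 4, 6),
                         decode_exclusion_s = 3.3,
                         n_controls = 100,
                         decode_query_step = 10,
                         seeds = list(
                           sessions = c(101L, 102L, 103L, 104L),
                           encode = 201L, rank = 301L, decode = 401L
                         )) {
  stopifnot(inherits(task, "task_config"))
  if (n_neurons < 10) stop("n_neurons must be at least 10", call. = FALSE)
  if (length(seeds$sessions) != 4) stop("seeds$sessions must hold 4 seeds", call. = FALSE)
  for (nm in c("encode", "rank", "decode")) {
    if (is.null(seeds[[nm]])) stop("missing seed: ", nm, call. = FALSE)
  }
  structure(
    list(
      task = task, n_neurons = as.integer(n_neurons), duration = duration,
      skill = skill, rate = rate, snr = snr,
      frac_stable = frac_stable, frac_noise = frac_noise,
      alpha = alpha, lambda = lambda, top_band = top_band,
      rank_draws = as.integer(rank_draws),
      decode_offsets = as.integer(decode_offsets),
      decode_exclusion_s = decode_exclusion_s,
      n_controls = as.integer(n_controls),
      decode_query_step = as.integer(decode_query_step),
      seeds = lapply(seeds, as.integer)
    ),
    class = "study_config"
  )
}

#' Write / read a study configuration as YAML
#'
#' @param config a [study_config()].
#' @param path file path.
#' @return `write_study_config` returns `path` invisibly;
#'   `read_study_config` returns the `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$task <- unclass(x$task)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  task <- do.call(task_config, x$task)
  x$task <- NULL
  do.call(study_config, c(list(task = task), x))
}

#' Run the end-to-end synthetic study
#'
#' Orchestrates the full analysis on simulated data: (1) simulate the four
#' sessions LS13/LS14/TS1/TS2 with a common ground-truth population;
#' (2) fit the per-neuron encoding models with imbalanced CV in every
#' session; (3) build normalized-rank tables, select the top band of pursued
#' neurons in LS13 and test their rank stability in the later sessions;
#' (4) decode the lever trajectory in TS2 and measure the decoding unique
#' contribution of the top group against random controls. Deterministic
#' given the configuration.
#'
#' @param config a [study_config()].
#' @param verbose print stage progress.
#' @return List with `study` (simulated sessions + truth), `encodings`
#'   (per-session `encode_session()` results), `rank_tables`, `top_group`,
#'   `stability` (per later session), `decoding` (TS2
#'   `decoding_contribution`), and `config`.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating 4 sessions (%d neurons, %g s each)", config$n_neurons, config$duration)
  study <- simulate_study(
    config$task, config$n_neurons, config$seeds$sessions,
    duration = config$duration, skill = config$skill,
    rate = config$rate, snr = config$snr,
    frac_stable = config$frac_stable, frac_noise = config$frac_noise
  )

  encodings <- list()
  rank_tables <- list()
  for (sid in names(study$sessions)) {
    say("encoding session %s", sid)
    b <- study$sessions[[sid]]
    d <- expand_design(b$behavior, study$basis)
    enc <- encode_session(b, d,
      alpha = config$alpha, lambda = config$lambda,
      seed = config$seeds$encode
    )
    encodings[[sid]] <- enc
    rank_tables[[sid]] <- normalized_rank(enc$results)
  }

  pursued_ids <- which(study$pursued)
  top_group <- select_top_group(
    rank_tables$LS13, rank_tables$LS13$neuron %in% pursued_ids, config$top_band
  )
  say("top group: %d neurons", length(top_group))

  stability <- list()
  for (sid in c("LS14", "TS1", "TS2")) {
    stability[[sid]] <- if (length(top_group) > 0) {
      rank_stability_test(
        top_group, rank_tables[[sid]],
        pool = rank_tables[[sid]]$neuron,
        n_draws = config$rank_draws, seed = config$seeds$rank
      )
    }
  }

  say("decoding TS2")
  b2 <- study$sessions$TS2
  lib <- likelihood_library(encodings$TS2$p_hat, b2$lever_raw, b2$frame_rate)
  usable <- which(!encodings$TS2$results$skipped)
  full_set <- intersect(pursued_ids, usable)
  decoding <- NULL
  sub <- intersect(top_group, full_set)
  if (length(sub) > 0 && length(sub) < length(full_set)) {
    qf <- seq(1L, b2$n_frames, by = config$decode_query_step)
    decoding <- decoding_unique_contribution(
      b2$activity, lib, full_set, sub,
      n_controls = config$n_controls, seed = config$seeds$decode,
      offsets = config$decode_offsets,
      exclusion_s = config$decode_exclusion_s,
      query_frames = qf
    )
  }

  list(
    study = study, encodings = encodings, rank_tables = rank_tables,
    top_group = top_group, stability = stability, decoding = decoding,
    config = config
  )
}

#' Validate a session bundle
#'
#' Checks the structural invariants every downstream stage assumes: the 20
#' canonical behavior columns, binary activity, strictly increasing trial
#' initiation frames, event frames inside the recording, and non-negative
#' directional velocity columns.
#'
#' @param bundle a `session_bundle` (or a path readable by
#'   [read_session_bundle()]).
#' @return Invisibly, a character vector of violations (empty when valid);
#'   also printed. Throws nothing for a merely invalid bundle.
#' @export
validate_bundle <- function(bundle) {
  if (is.character(bundle)) bundle <- read_session_bundle(bundle)
  stopifnot(inherits(bundle, "session_bundle"))
  bad <- character()
  beh <- bundle$behavior
  missing_cols <- setdiff(lever_variables(), names(beh))
  if (length(missing_cols) > 0) {
    bad <- c(bad, paste("missing behavior columns:", paste(missing_cols, collapse = ", ")))
  }
  vel_cols <- grep("velocity|_v[xy]_", names(beh), value = TRUE)
  for (vc in vel_cols) {
    if (any(beh[[vc]] < 0, na.rm = TRUE)) bad <- c(bad, paste("negative values in", vc))
  }
  for (bc in intersect(c("lick", "reward"), names(beh))) {
    if (!all(beh[[bc]] %in% c(0L, 1L))) bad <- c(bad, paste(bc, "is not binary"))
  }
  if (!is.null(bundle$activity)) {
    if (!all(bundle$activity %in% c(0L, 1L))) bad <- c(bad, "activity is not binary")
    if (ncol(bundle$activity) != bundle$n_frames) {
      bad <- c(bad, "activity frame count differs from n_frames")
    }
  }
  tr <- bundle$trials
  if (nrow(tr) > 1 && any(diff(tr$init_frame) <= 0)) {
    bad <- c(bad, "trial initiation frames are not strictly increasing")
  }
  ev <- c(tr$init_frame, tr$reward_frame)
  ev <- ev[!is.na(ev)]
  if (length(ev) > 0 && (min(ev) < 1 || max(ev) > bundle$n_frames)) {
    bad <- c(bad, "event frames outside the recording")
  }
  if (length(bad) == 0) {
    message("session bundle OK (", bundle$n_frames, " frames, ", nrow(tr), " trials)")
  } else {
    message("session bundle INVALID:\n  - ", paste(bad, collapse = "\n  - "))
  }
  invisible(bad)
}

#' Serialize a session bundle as plain text
#'
#' Writes a session bundle to a directory of portable text files:
#' `behavior.csv` (the 20 canonical columns plus the omitted mask),
#' `activity.mtx` (sparse MatrixMarket, neurons x frames),
#' `trials.csv`, and `meta.json` (frame rate, session id, task, pursued
#' mask, seed). `read_session_bundle()` restores the bundle.
#'
#' @param bundle a `session_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_session_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  beh <- as.data.frame(bundle$behavior)
  beh$omitted <- as.integer(attr(bundle$behavior, "omitted") %||% rep(0L, nrow(beh)))
  utils::write.csv(beh, file.path(dir, "behavior.csv"), row.names = FALSE)
  utils::write.csv(bundle$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  if (!is.null(bundle$activity)) {
    Matrix::writeMM(
      Matrix::Matrix(bundle$activity, sparse = TRUE),
      file.path(dir, "activity.mtx")
    )
  }
  meta <- list(
    frame_rate = bundle$frame_rate, n_frames = bundle$n_frames,
    session_id = bundle$session_id, task = bundle$task,
    pursued = bundle$pursued, seed = bundle$seed,
    lever_raw = bundle$lever_raw
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' @rdname write_session_bundle
#' @export
read_session_bundle <- function(dir) {
  beh <- utils::read.csv(file.path(dir, "behavior.csv"))
  omitted <- as.logical(beh$omitted %||% rep(FALSE, nrow(beh)))
  beh$omitted <- NULL
  beh <- tibble::as_tibble(beh)
  attr(beh, "omitted") <- omitted
  trials <- tibble::as_tibble(utils::read.csv(file.path(dir, "trials.csv")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  activity <- NULL
  mtx <- file.path(dir, "activity.mtx")
  if (file.exists(mtx)) {
    activity <- as.matrix(Matrix::readMM(mtx))
    storage.mode(activity) <- "integer"
  }
  structure(
    list(
      behavior = beh, trials = trials,
      lever_raw = as.numeric(meta$lever_raw),
      activity = activity, truth = NULL,
      pursued = if (!is.null(meta$pursued)) as.logical(meta$pursued) else NULL,
      frame_rate = meta$frame_rate, n_frames = meta$n_frames,
      session_id = meta$session_id %||% NA_character_,
      task = meta$task, config = NULL, seed = meta$seed
    ),
    class = "session_bundle"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
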