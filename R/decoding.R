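#' Likelihood library for the marginalization decoder
#'
#' The decoder marginalizes over the behavioral states actually realized in
#' a session: each library point `s` couples the lever value `x_s` with the
#' per-neuron encoding probabilities `P(r_i | x_s, x~_s)` at that frame. The
#' probabilities are the cross-validated per-frame estimates of the encoding
#' models, so decoding inherits the encoding cross-validation; frames where
#' a neuron lacks an estimate (guarded or omitted) are dropped from the
#' library for any neuron set that includes it.
#'
#' @param p_hat matrix (frames x neurons) of cross-validated encoding
#'   probabilities (NA where unavailable), e.g. `encode_session()$p_hat`.
#' @param lever recorded lever trace, one value per frame.
#' @param frame_rate frames per second.
#' @return Object of class `likelihood_library`.
#' @export
likelihood_library <- function(p_hat, lever, frame_rate = 30) {
  stopifnot(is.matrix(p_hat), nrow(p_hat) == length(lever))
  structure(
    list(p = p_hat, lever = as.numeric(lever), frame_rate = frame_rate),
    class = "likelihood_library"
  )
}

#' @export
print.likelihood_library <- function(x, ...) {
  cat(sprintf(
    "<likelihood_library> %d frames x %d neurons (%.1f%% frames fully estimated)\n",
    nrow(x$p), ncol(x$p), 100 * mean(stats::complete.cases(x$p))
  ))
  invisible(x)
}

#' Likelihood of one observed population vector at one library point
#'
#' The population likelihood is the product over neurons of
#' `1 - |r_i - P(r_i | x, x~)|`: the probability each encoding model assigns
#' to the observed binary activity. Factors are floored at `eps` before
#' taking the product (in log space for numerical stability).
#'
#' @param observed binary activity vector over neurons.
#' @param library_point per-neuron encoding probabilities at the library
#'   point.
#' @param eps floor applied to each factor (default 1e-12).
#' @param log return the log likelihood.
#' @return Likelihood in `[0, 1]` (or its log).
#' @examples
#' frame_likelihood(c(1, 0), c(0.8, 0.3)) # 0.8 * 0.7
#' @export
frame_likelihood <- function(observed, library_point, eps = 1e-12, log = FALSE) {
  stopifnot(length(observed) == length(library_point))
  f <- 1 - abs(observed - library_point)
  ll <- sum(base::log(pmax(f, eps)))
  if (log) ll else exp(ll)
}

#' Decode the lever trajectory from population activity
#'
#' Implements the Bayesian marginalization decoder: with a uniform prior
#' over realized behavioral states, the decoded lever position is the
#' likelihood-weighted average of the library's lever values,
#' `x^_t = sum_s x_s P(r_t | x_s, x~_s) / sum_s P(r_t | x_s, x~_s)`.
#' Neuronal dynamics are incorporated by concatenating population vectors at
#' the frame offsets `offsets` (library probabilities are taken at `s + tau`
#' for offset `tau`), and data leakage is eliminated by excluding library
#' points within `exclusion_s` seconds of the decoded frame. The decoded
#' value is a convex combination of library lever values by construction.
#'
#' Offsets are expressed in frames at 30 Hz and rescaled (rounded to the
#' nearest frame) for other frame rates.
#'
#' @param activity binary activity matrix (neurons x frames) of the decoded
#'   session.
#' @param library a [likelihood_library()] built from the same session.
#' @param neurons neuron indices used for decoding (default all).
#' @param offsets concatenation offsets in frames at 30 Hz.
#' @param exclusion_s half-width of the leakage exclusion window (s).
#' @param query_frames frames to decode (default: all frames whose offset
#'   windows fit inside the session).
#' @param eps per-factor likelihood floor.
#' @param block query chunk size (memory/speed trade-off).
#' @return Object of class `decode_result`: tibble `frames` (`frame`,
#'   `decoded`, `observed`) plus attributes; see also
#'   [decoding_accuracy()].
#' @export
decode_lever <- function(activity, library, neurons = NULL,
                         offsets = c(-6L, -4L, -2L, 0L, 2L, 4L, 6L),
                         exclusion_s = 3.3, query_frames = NULL,
                         eps = 1e-12, block = 512L) {
  stopifnot(inherits(library, "likelihood_library"), is.matrix(activity))
  n_frames <- ncol(activity)
  if (nrow(library$p) != n_frames) {
    stop("activity and library disagree on the number of frames", call. = FALSE)
  }
  if (is.null(neurons)) neurons <- seq_len(nrow(activity))
  rate <- library$frame_rate
  if (rate != 30) offsets <- as.integer(round(offsets * rate / 30))
  offsets <- sort(unique(as.integer(offsets)))
  excl_f <- floor(exclusion_s * rate)

  off_lo <- min(offsets)
  off_hi <- max(offsets)
  frame_ok <- seq_len(n_frames) + off_lo >= 1 & seq_len(n_frames) + off_hi <= n_frames

  P <- library$p[, neurons, drop = FALSE]
  have_p <- !is.na(rowSums(P))
  # library points: every offset in range and estimated for every neuron
  lib_ok <- frame_ok
  for (tau in offsets) {
    idx <- seq_len(n_frames) + tau
    ok <- rep(FALSE, n_frames)
    ok[idx >= 1 & idx <= n_frames] <- have_p[idx[idx >= 1 & idx <= n_frames]]
    lib_ok <- lib_ok & ok
  }
  lib <- which(lib_ok)
  if (length(lib) == 0) stop("empty likelihood library", call. = FALSE)

  if (is.null(query_frames)) query_frames <- which(frame_ok)
  query_frames <- query_frames[frame_ok[query_frames]]
  if (length(query_frames) == 0) stop("no decodable query frames", call. = FALSE)

  # Concatenated log-probability representation:
  # LL[t, s] = sum_tau sum_i [ r_{i,t+tau} * (log p - log(1-p))_{i,s+tau}
  #                            + log(1-p)_{i,s+tau} ]
  #          = (A %*% t(B))[t, s] + c0[s]
  Pc <- pmin(pmax(P, eps), 1 - eps)
  logp1 <- base::log(Pc)
  logp0 <- base::log(1 - Pc)
  nn <- length(neurons)
  A <- matrix(0, length(query_frames), nn * length(offsets))
  B <- matrix(0, length(lib), nn * length(offsets))
  c0 <- numeric(length(lib))
  R <- t(activity[neurons, , drop = FALSE])
  for (k in seq_along(offsets)) {
    cols <- (k - 1L) * nn + seq_len(nn)
    A[, cols] <- R[query_frames + offsets[k], , drop = FALSE]
    B[, cols] <- logp1[lib + offsets[k], , drop = FALSE] -
      logp0[lib + offsets[k], , drop = FALSE]
    c0 <- c0 + rowSums(logp0[lib + offsets[k], , drop = FALSE])
  }

  x_lib <- library$lever[lib]
  decoded <- numeric(length(query_frames))
  for (start in seq(1L, length(query_frames), by = block)) {
    rows <- start:min(start + block - 1L, length(query_frames))
    LL <- A[rows, , drop = FALSE] %*% t(B)
    LL <- sweep(LL, 2, c0, "+")
    # leakage exclusion: drop library points within the window of each query
    tq <- query_frames[rows]
    for (r in seq_along(rows)) {
      LL[r, abs(lib - tq[r]) <= excl_f] <- -Inf
    }
    mx <- apply(LL, 1, max)
    bad <- !is.finite(mx)
    mx[bad] <- 0
    W <- exp(LL - mx)
    decoded[rows] <- drop(W %*% x_lib) / rowSums(W)
    decoded[rows][bad] <- NA_real_ # no admissible library point for this frame
  }

  frames <- tibble::tibble(
    frame = query_frames,
    decoded = decoded,
    observed = library$lever[query_frames]
  )
  n_undecodable <- sum(is.na(decoded))
  frames <- frames[!is.na(frames$decoded), ]
  if (nrow(frames) == 0) stop("empty likelihood library after exclusion", call. = FALSE)
  structure(
    list(
      frames = frames, neurons = neurons, n_library = length(lib),
      n_undecodable = n_undecodable,
      offsets = offsets, exclusion_s = exclusion_s,
      lever_range = range(x_lib)
    ),
    class = "decode_result"
  )
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf(
    "<decode_result> %d frames decoded from %d neurons (library %d points); R^2 = %.3f\n",
    nrow(x$frames), length(x$neurons), x$n_library, decoding_accuracy(x)$r2
  ))
  invisible(x)
}

#' Decoding accuracy
#'
#' Squared Pearson correlation between the decoded and recorded lever
#' trajectories over the decoded frames. A constant decoded trace makes the
#' correlation undefined; accuracy is then 0 with a flag.
#'
#' @param result a [decode_lever()] result.
#' @param min_frames minimum number of decoded frames (default 100).
#' @return List with `r2`, `n_frames`, `degenerate`.
#' @export
decoding_accuracy <- function(result, min_frames = 100) {
  stopifnot(inherits(result, "decode_result"))
  d <- result$frames
  if (nrow(d) < min_frames) {
    stop(sprintf("need at least %d decoded frames", min_frames), call. = FALSE)
  }
  if (sd(d$decoded) == 0 || sd(d$observed) == 0) {
    return(list(r2 = 0, n_frames = nrow(d), degenerate = TRUE))
  }
  list(r2 = cor(d$decoded, d$observed)^2, n_frames = nrow(d), degenerate = FALSE)
}

#' Decoding unique contribution of a neuron subset
#'
#' The decoding unique contribution of a subset (canonically the top-20%
#' neurons) is the drop in decoding accuracy when the subset is removed from
#' the full population: `dR^2 = R^2(full) - R^2(full \ subset)`. To judge
#' whether the subset matters more than any other population of its size,
#' the same statistic is computed for `n_controls` random control
#' populations of the same size drawn from the remaining neurons, giving a
#' comparison distribution.
#'
#' @param activity binary activity matrix (neurons x frames).
#' @param library a [likelihood_library()] for the session.
#' @param full_set neuron indices of the full decoded population.
#' @param subset strict subset of `full_set` whose contribution is tested.
#' @param control_pool pool controls are drawn from (default
#'   `setdiff(full_set, subset)`).
#' @param n_controls number of control populations (default 100).
#' @param seed integer seed.
#' @param ... passed to [decode_lever()] (`query_frames`, `offsets`, ...).
#' @return Object of class `decoding_contribution`: list with `delta_r2`,
#'   `full_r2`, `reduced_r2`, `controls` (vector of `n_controls` control
#'   dR^2 values), `control_q975`.
#' @export
decoding_unique_contribution <- function(activity, library, full_set, subset,
                                         control_pool = NULL, n_controls = 100,
                                         seed = 1L, ...) {
  if (!all(subset %in% full_set)) stop("subset must lie within full_set", call. = FALSE)
  if (length(subset) >= length(full_set)) {
    stop("subset must be a strict subset of full_set", call. = FALSE)
  }
  if (is.null(control_pool)) control_pool <- setdiff(full_set, subset)
  if (length(control_pool) < length(subset)) {
    stop("control pool smaller than the tested subset", call. = FALSE)
  }

  full_r2 <- decoding_accuracy(decode_lever(activity, library, full_set, ...))$r2
  reduced_r2 <- decoding_accuracy(
    decode_lever(activity, library, setdiff(full_set, subset), ...)
  )$r2
  delta <- full_r2 - reduced_r2

  controls <- withr::with_seed(as.integer(seed), {
    ctrl_sets <- lapply(seq_len(n_controls), function(k) sample(control_pool, length(subset)))
    vapply(ctrl_sets, function(cs) {
      r2 <- decoding_accuracy(
        decode_lever(activity, library, setdiff(full_set, cs), ...)
      )$r2
      full_r2 - r2
    }, numeric(1))
  })

  structure(
    list(
      delta_r2 = delta, full_r2 = full_r2, reduced_r2 = reduced_r2,
      controls = controls, control_q975 = quantile(controls, 0.975, names = FALSE),
      subset_size = length(subset), n_controls = n_controls, seed = as.integer(seed)
    ),
    class = "decoding_contribution"
  )
}

#' @export
print.decoding_contribution <- function(x, ...) {
  cat(sprintf(
    "<decoding_contribution> dR^2 = %.4f (full %.3f -> reduced %.3f); control 97.5%% = %.4f over %d draws\n",
    x$delta_r2, x$full_r2, x$reduced_r2, x$control_q975, x$n_controls
  ))
  invisible(x)
}
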