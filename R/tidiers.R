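#' Tidy an encoding model
#'
#' `tidy()` returns the per-variable temporal kernels of the fitted encoding
#' model in long form; `glance()` returns a one-row summary (likelihoods,
#' elusive flag, accuracy).
#'
#' @param x a `neuron_encoding` from [encode_neuron()].
#' @param ... unused.
#' @return A tibble.
#' @method tidy neuron_encoding
#' @export
tidy.neuron_encoding <- function(x, ...) {
  tidy(x$kernels)
}

#' @rdname tidy.neuron_encoding
#' @method glance neuron_encoding
#' @export
glance.neuron_encoding <- function(x, ...) {
  tibble::tibble(
    elusive = x$elusive,
    full_likelihood = x$full_likelihood,
    null_likelihood = x$null_likelihood,
    accuracy = x$accuracy,
    n_positive = x$plan$n_positive,
    n_folds = length(x$plan$folds),
    alpha = x$alpha, lambda = x$lambda
  )
}

#' @rdname tidy.neuron_encoding
#' @method tidy kernel_set
#' @export
tidy.kernel_set <- function(x, ...) {
  tibble::as_tibble(x$kernels) |>
    dplyr::mutate(lag_s = x$lags_s) |>
    tidyr::pivot_longer(-"lag_s", names_to = "variable", values_to = "weight") |>
    dplyr::mutate(
      category = unname(variable_categories()[.data$variable])
    ) |>
    dplyr::arrange(.data$variable, .data$lag_s)
}

#' Tidy a decoding result
#'
#' `tidy()` returns the per-frame decoded and observed lever positions;
#' `glance()` the decoding accuracy summary.
#'
#' @param x a `decode_result` from [decode_lever()].
#' @param ... unused.
#' @return A tibble.
#' @method tidy decode_result
#' @export
tidy.decode_result <- function(x, ...) {
  x$frames
}

#' @rdname tidy.decode_result
#' @method glance decode_result
#' @export
glance.decode_result <- function(x, ...) {
  acc <- decoding_accuracy(x, min_frames = 1)
  tibble::tibble(
    r2 = acc$r2, n_frames = acc$n_frames, degenerate = acc$degenerate,
    n_neurons = length(x$neurons), n_library = x$n_library,
    exclusion_s = x$exclusion_s
  )
}

#' Tidy a rank-stability test
#'
#' `tidy()` returns the null distribution of mean normalized ranks;
#' `glance()` the test summary.
#'
#' @param x a `rank_stability` from [rank_stability_test()].
#' @param ... unused.
#' @return A tibble.
#' @method tidy rank_stability
#' @export
tidy.rank_stability <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$null), null_mean_rank = x$null)
}

#' @rdname tidy.rank_stability
#' @method glance rank_stability
#' @export
glance.rank_stability <- function(x, ...) {
  tibble::tibble(
    mean_rank = x$mean_rank, null_q025 = x$null_q025,
    null_q975 = x$null_q975, significant = x$significant,
    group_size = x$group_size, n_draws = x$n_draws
  )
}

#' Tidy a decoding-contribution analysis
#'
#' `tidy()` returns the control distribution of dR^2 values; `glance()` the
#' observed contribution and control percentile.
#'
#' @param x a `decoding_contribution`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy decoding_contribution
#' @export
tidy.decoding_contribution <- function(x, ...) {
  tibble::tibble(control = seq_along(x$controls), delta_r2 = x$controls)
}

#' @rdname tidy.decoding_contribution
#' @method glance decoding_contribution
#' @export
glance.decoding_contribution <- function(x, ...) {
  tibble::tibble(
    delta_r2 = x$delta_r2, full_r2 = x$full_r2, reduced_r2 = x$reduced_r2,
    control_q975 = x$control_q975, subset_size = x$subset_size,
    n_controls = x$n_controls
  )
}
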