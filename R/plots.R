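#' Plot the temporal kernels of an encoding model
#'
#' One line per behavioral variable, faceted by category, showing the
#' model's dependency on behavior as a function of lag (positive lags:
#' behavior preceding activity).
#'
#' @param object a `kernel_set`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot kernel_set
#' @export
autoplot.kernel_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_s, .data$weight, color = .data$variable)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, color = "grey60") +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(
      x = "lag (s)", y = "kernel weight (log-odds)",
      title = "Encoding-model temporal kernels"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kernel_set
#' @method autoplot neuron_encoding
#' @export
autoplot.neuron_encoding <- function(object, ...) {
  autoplot(object$kernels, ...)
}

#' Plot decoded versus recorded lever trajectory
#'
#' @param object a `decode_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot decode_result
#' @export
autoplot.decode_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$frames, c("decoded", "observed"),
    names_to = "trace", values_to = "position"
  )
  r2 <- decoding_accuracy(object, min_frames = 1)$r2
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$position, color = .data$trace)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(
      x = "frame", y = "lever position (mm)",
      title = sprintf("Decoded lever trajectory (R² = %.2f)", r2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a rank-stability test
#'
#' Histogram of the null distribution of mean normalized ranks with the
#' observed group mean and the 2.5/97.5 percentiles.
#'
#' @param object a `rank_stability`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot rank_stability
#' @export
autoplot.rank_stability <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_mean_rank)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey75") +
    ggplot2::geom_vline(xintercept = c(object$null_q025, object$null_q975), linetype = 2) +
    ggplot2::geom_vline(xintercept = object$mean_rank, color = "red") +
    ggplot2::labs(
      x = "mean normalized rank of random populations", y = "draws",
      title = sprintf(
        "Rank stability: group mean %.3f (%s)",
        object$mean_rank,
        if (object$significant) "significant" else "not significant"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a session's behavior and trials
#'
#' Lever trace with trial initiations and rewards marked; a quick visual
#' check of simulated or imported sessions.
#'
#' @param bundle a `session_bundle`.
#' @param t_range optional time range (s) to display.
#' @return A ggplot object.
#' @export
plot_session <- function(bundle, t_range = NULL) {
  stopifnot(inherits(bundle, "session_bundle"))
  r <- bundle$frame_rate
  df <- tibble::tibble(
    t = seq_len(bundle$n_frames) / r,
    lever = bundle$lever_raw
  )
  tr <- bundle$trials
  if (!is.null(t_range)) {
    df <- dplyr::filter(df, .data$t >= t_range[1], .data$t <= t_range[2])
    tr <- dplyr::filter(
      tr, .data$init_frame / r >= t_range[1],
      .data$init_frame / r <= t_range[2]
    )
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$lever)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(
      yintercept = bundle$config$pull_threshold %||% 2.5,
      linetype = 2, color = "grey50"
    ) +
    ggplot2::labs(x = "time (s)", y = "lever position (mm)") +
    ggplot2::theme_minimal()
  if (nrow(tr) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(
        t = tr$init_frame / r,
        lever = rep(0, nrow(tr)),
        outcome = tr$outcome
      ),
      ggplot2::aes(.data$t, .data$lever, color = .data$outcome), shape = 17
    )
  }
  p
}
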