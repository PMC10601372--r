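#' Normalized encoding-performance ranks
#'
#' Ranks all neurons of a session by encoding accuracy and maps rank `R_i`
#' (1 = best of `N` neurons) to the normalized rank `(N - R_i + 1) / N`, so
#' the best neuron scores 1 and the worst `1/N`. Elusive neurons have their
#' accuracy forced to 0 before ranking, which places them collectively at the
#' smallest normalized ranks (ties, including among elusive neurons, are
#' broken deterministically by neuron index).
#'
#' @param accuracies per-neuron encoding accuracies, or a data frame with
#'   columns `accuracy` and `elusive` (e.g. `encode_session()$results`).
#' @param elusive logical mask (ignored when `accuracies` is a data frame).
#' @param neuron optional neuron ids (default sequence).
#' @return A tibble of class `rank_table`: `neuron`, `accuracy` (after the
#'   elusive floor), `rank`, `normalized_rank`, `elusive`.
#' @examples
#' normalized_rank(c(0.5, 0.2, 0.8), elusive = c(FALSE, FALSE, FALSE))
#' @export
normalized_rank <- function(accuracies, elusive = NULL, neuron = NULL) {
  if (is.data.frame(accuracies)) {
    df <- accuracies
    if (is.null(neuron)) neuron <- if ("neuron" %in% names(df)) df$neuron else seq_len(nrow(df))
    elusive <- df$elusive
    accuracies <- df$accuracy
  }
  n <- length(accuracies)
  if (n < 1) stop("need at least one neuron", call. = FALSE)
  if (is.null(elusive)) elusive <- rep(FALSE, n)
  if (is.null(neuron)) neuron <- seq_len(n)
  acc <- accuracies
  acc[is.na(acc)] <- 0
  acc[which(elusive)] <- 0
  # rank 1 = best; ties broken by neuron index
  ord <- order(-acc, seq_len(n))
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  out <- tibble::tibble(
    neuron = neuron, accuracy = acc, rank = rank,
    normalized_rank = (n - rank + 1) / n,
    elusive = ifelse(is.na(elusive), FALSE, elusive)
  )
  class(out) <- c("rank_table", class(out))
  out
}

#' Select pursued neurons in a normalized-rank band
#'
#' Classifies pursued neurons by their normalized rank in a reference
#' session (canonically LS13): e.g. band `[0.8, 1]` is the top-20% group
#' whose later-session rank stability is tested.
#'
#' @param rank_table a [normalized_rank()] table for the reference session.
#' @param pursued logical mask over the table's neurons.
#' @param band two-element half-open range `(low, high]` of normalized rank,
#'   so adjacent bands partition the population exactly.
#' @return Integer vector of neuron ids (possibly empty).
#' @export
select_top_group <- function(rank_table, pursued, band = c(0.8, 1)) {
  stopifnot(inherits(rank_table, "rank_table"), length(band) == 2)
  if (band[1] < 0 || band[2] > 1 || band[1] >= band[2]) {
    stop("band must be an increasing range within (0, 1]", call. = FALSE)
  }
  nr <- rank_table$normalized_rank
  sel <- pursued & nr > band[1] & nr <= band[2]
  rank_table$neuron[sel]
}

#' Rank-stability significance against resampled populations
#'
#' Tests whether a neuron group selected in a reference session keeps
#' higher-than-chance encoding ranks in a later session: the group's mean
#' normalized rank is compared with the distribution of mean normalized
#' ranks of `n_draws` randomly selected populations of the same size from a
#' pool (all neurons of the session, or all pursued neurons, depending on
#' the analysis). Significant iff the group mean exceeds the null's 97.5th
#' percentile; the 2.5th percentile is reported as the lower band.
#'
#' @param group neuron ids of the tested group (non-empty).
#' @param rank_table the later session's [normalized_rank()] table.
#' @param pool neuron ids forming the resampling pool (default: all neurons
#'   of the table). The group must not be larger than the pool.
#' @param n_draws number of random populations (default 10000).
#' @param seed integer seed.
#' @return Object of class `rank_stability`: list with `mean_rank`,
#'   `null_mean`, `null_q025`, `null_q975`, `significant`, `n_draws`,
#'   `group_size`, `null` (the draw means).
#' @export
rank_stability_test <- function(group, rank_table, pool = NULL,
                                n_draws = 10000, seed = 1L) {
  stopifnot(inherits(rank_table, "rank_table"))
  if (length(group) == 0) stop("group must be non-empty", call. = FALSE)
  if (is.null(pool)) pool <- rank_table$neuron
  if (length(group) > length(pool)) {
    stop("group is larger than the resampling pool", call. = FALSE)
  }
  nr <- rank_table$normalized_rank[match(pool, rank_table$neuron)]
  if (any(is.na(nr))) stop("pool contains neurons absent from the rank table", call. = FALSE)
  if (length(unique(nr)) < 2) stop("degenerate pool: all normalized ranks equal", call. = FALSE)
  g <- rank_table$normalized_rank[match(group, rank_table$neuron)]
  if (any(is.na(g))) stop("group contains neurons absent from the rank table", call. = FALSE)
  m <- mean(g)
  k <- length(group)
  # each draw is a population of k distinct pool members
  null_means <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_draws), function(d) mean(sample(nr, k)), numeric(1))
  })
  q <- quantile(null_means, c(0.025, 0.975), names = FALSE)
  structure(
    list(
      mean_rank = m, null_mean = mean(null_means),
      null_q025 = q[1], null_q975 = q[2],
      significant = m > q[2], n_draws = n_draws,
      group_size = k, null = null_means, seed = as.integer(seed)
    ),
    class = "rank_stability"
  )
}

#' @export
print.rank_stability <- function(x, ...) {
  cat(sprintf(
    "<rank_stability> group of %d: mean normalized rank %.3f vs null [%.3f, %.3f] (%d draws) -> %s\n",
    x$group_size, x$mean_rank, x$null_q025, x$null_q975, x$n_draws,
    if (x$significant) "significant" else "not significant"
  ))
  invisible(x)
}
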