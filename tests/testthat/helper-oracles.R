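# brute-force reference for the marginalization decoder: direct evaluation
# of the product likelihood and the likelihood-weighted average, with plain
# loops and no log-space tricks
brute_force_decode <- function(activity, p, lever, offsets, excl_f, query) {
  n <- ncol(activity)
  vapply(query, function(t) {
    num <- 0
    den <- 0
    for (s in seq_len(n)) {
      if (abs(s - t) <= excl_f) next
      ok <- TRUE
      L <- 1
      for (tau in offsets) {
        if (s + tau < 1 || s + tau > n || t + tau < 1 || t + tau > n) {
          ok <- FALSE
          break
        }
        for (i in seq_len(nrow(activity))) {
          pi <- p[s + tau, i]
          if (is.na(pi)) {
            ok <- FALSE
            break
          }
          pi <- min(max(pi, 1e-12), 1 - 1e-12)
          L <- L * (1 - abs(activity[i, t + tau] - pi))
        }
        if (!ok) break
      }
      if (!ok) next
      num <- num + lever[s] * L
      den <- den + L
    }
    num / den
  }, numeric(1))
}
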