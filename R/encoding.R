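#' Imbalanced cross-validation fold plan for one neuron
#'
#' Binarized activity is extremely sparse (positive-frame fraction around
#' 0.006), so training sets are rebalanced: each of the 10 folds trains on
#' nine-tenths of the positive frames taken in order (fold f holds out the
#' f-th contiguous tenth) together with a fresh random sample of 1% of the
#' negative frames, and is scored on everything else. To limit temporal
#' leakage through the autocorrelated behavior, test frames within
#' `guard_s` seconds of any training frame of that fold are excluded from
#' scoring. Every positive frame is a (candidate) test frame in exactly one
#' fold.
#'
#' @param activity_row binary 0/1 activity of one neuron (one value per
#'   frame); needs at least `n_folds` positive frames.
#' @param frame_rate frames per second.
#' @param n_folds number of folds (default 10).
#' @param neg_fraction fraction of negative frames sampled for training per
#'   fold (default 0.01).
#' @param guard_s temporal guard around training frames (default 2 s).
#' @param seed integer seed for the negative sampling.
#' @param positive_order `"contiguous"` (default: fold f holds out the f-th
#'   ordered tenth of positives) or `"interleaved"` (positives dealt
#'   round-robin to folds).
#' @return Object of class `fold_plan`: list of `folds` (each with `train`,
#'   `test`, `guarded` frame indices and `test_positive`), plus bookkeeping.
#' @export
plan_folds <- function(activity_row, frame_rate = 30, n_folds = 10,
                       neg_fraction = 0.01, guard_s = 2, seed = 1L,
                       positive_order = c("contiguous", "interleaved")) {
  positive_order <- match.arg(positive_order)
  y <- as.integer(activity_row)
  stopifnot(all(y %in% c(0L, 1L)))
  n <- length(y)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (length(pos) < n_folds) {
    stop(sprintf(
      "neuron has %d positive frames; at least %d are required",
      length(pos), n_folds
    ), call. = FALSE)
  }
  guard_f <- round(guard_s * frame_rate)
  blocks <- if (positive_order == "contiguous") {
    split(pos, ceiling(seq_along(pos) / (length(pos) / n_folds)))
  } else {
    split(pos, rep_len(seq_len(n_folds), length(pos)))
  }
  stopifnot(length(blocks) == n_folds)

  n_neg_train <- max(1L, round(neg_fraction * length(neg)))
  folds <- withr::with_seed(as.integer(seed), {
    # one frame permutation per fold; each neuron takes the first 1% of its
    # negatives in permutation order (a uniform without-replacement sample).
    # Seeding by fold rather than by neuron keeps the sampled frames - and
    # with them the 2 s guard zones - aligned across a session's neurons.
    perms <- lapply(seq_len(n_folds), function(f) sample.int(n))
    lapply(seq_len(n_folds), function(f) {
      train_pos <- sort(unlist(blocks[-f], use.names = FALSE))
      pn <- perms[[f]]
      train_neg <- sort(utils::head(pn[y[pn] == 0L], n_neg_train))
      train <- sort(c(train_pos, train_neg))
      candidates <- setdiff(seq_len(n), train)
      # guard: distance to the nearest training frame must exceed guard_f
      d <- nearest_distance(candidates, train)
      guarded <- candidates[d <= guard_f]
      test <- candidates[d > guard_f]
      list(
        train = train, test = test, guarded = guarded,
        test_positive = intersect(blocks[[f]], test)
      )
    })
  })
  structure(
    list(
      folds = folds, n_frames = n, n_positive = length(pos),
      n_neg_train = n_neg_train, guard_f = guard_f, seed = as.integer(seed),
      frame_rate = frame_rate, positive_order = positive_order
    ),
    class = "fold_plan"
  )
}

# internal: for each value in q, distance to the nearest element of ref
nearest_distance <- function(q, ref) {
  ref <- sort(ref)
  i <- findInterval(q, ref)
  d_lo <- ifelse(i >= 1, q - ref[pmax(i, 1L)], Inf)
  d_hi <- ifelse(i < length(ref), ref[pmin(i + 1L, length(ref))] - q, Inf)
  pmin(d_lo, d_hi)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf(
    "<fold_plan> %d folds over %d frames (%d positives; %d training negatives/fold; guard %d frames)\n",
    length(x$folds), x$n_frames, x$n_positive, x$n_neg_train, x$guard_f
  ))
  invisible(x)
}

#' Fit the Bernoulli elastic-net GLM
#'
#' Minimizes the mean Bernoulli negative log-likelihood plus the elastic-net
#' penalty `lambda * (alpha * ||w||_1 + (1 - alpha)/2 * ||w||_2^2)`, with the
#' intercept unpenalized and columns standardized internally (weights are
#' returned on the original scale). `alpha = 0.2`, `lambda = 1e-4` are the
#' standard settings: mostly ridge-like to tolerate the strong correlations
#' the basis expansion induces, with enough L1 to prune useless regressors.
#'
#' @param x numeric design matrix (training rows).
#' @param y binary response (same number of rows).
#' @param alpha elastic-net mixing parameter in `[0, 1]`.
#' @param lambda penalty strength (>= 0).
#' @param standardize standardize columns before penalization (default TRUE).
#' @return Object of class `encoding_fit`: list with `intercept`, `weights`
#'   (named), `alpha`, `lambda`.
#' @export
fit_encoding_glm <- function(x, y, alpha = 0.2, lambda = 1e-4,
                             standardize = TRUE) {
  y <- as.integer(y)
  if (sum(y == 1L) < 1 || sum(y == 0L) < 1) {
    stop("training data must contain at least one positive and one negative frame", call. = FALSE)
  }
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0)
  # glmnet warms up along a decreasing lambda path ending at the target;
  # if the target is not reached (glmnet drops unconverged path points), a
  # denser path is tried once before giving up
  run_path <- function(path, maxit) {
    suppressWarnings(glmnet::glmnet(
      x, y,
      family = "binomial", alpha = alpha, lambda = path,
      standardize = standardize, thresh = 1e-7, maxit = maxit
    ))
  }
  path <- lambda * c(3000, 1000, 300, 100, 30, 10, 3, 1)
  fit <- run_path(path, 3e5)
  if (length(fit$lambda) < length(path)) {
    fit <- run_path(lambda * 10^seq(4, 0, length.out = 20), 2e6)
    if (fit$lambda[length(fit$lambda)] > lambda * 1.01) {
      stop(sprintf(
        "elastic-net fit did not converge at lambda = %g (reached %g; n = %d, p = %d)",
        lambda, fit$lambda[length(fit$lambda)], nrow(x), ncol(x)
      ), call. = FALSE)
    }
  }
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  names(beta) <- rownames(fit$beta)
  if (any(!is.finite(beta))) stop("GLM fit did not converge to finite weights", call. = FALSE)
  structure(
    list(
      intercept = fit$a0[[length(fit$a0)]], weights = beta,
      alpha = alpha, lambda = lambda
    ),
    class = "encoding_fit"
  )
}

# internal: predicted probabilities of an encoding_fit on design rows
predict_fit <- function(fit, x) {
  plogis(fit$intercept + drop(x %*% fit$weights))
}

# internal: pool per-fold predictions into one probability train.
# preds: list per fold of numeric vectors indexed by frame (NA elsewhere).
# A frame estimated in several folds takes the median of its estimates.
collate_fold_predictions <- function(preds, n) {
  P <- do.call(cbind, preds)
  est <- rowSums(!is.na(P))
  out <- rep(NA_real_, n)
  one <- est == 1L
  out[one] <- rowSums(P[one, , drop = FALSE], na.rm = TRUE)
  multi <- which(est > 1L)
  if (length(multi) > 0) {
    out[multi] <- apply(P[multi, , drop = FALSE], 1, median, na.rm = TRUE)
  }
  out
}

# internal: log sampling-ratio offset of a rebalanced training set.
# Positives are kept with probability s1 (9/10), negatives with s0 (1%), so
# the fitted log-odds are shifted by log(s1/s0) relative to the population;
# subtracting the offset restores probabilities on the session scale
# (slopes are unaffected by outcome-dependent sampling).
case_control_offset <- function(y, train) {
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  s1 <- sum(y[train] == 1L) / n_pos
  s0 <- sum(y[train] == 0L) / n_neg
  log(s1 / s0)
}

#' Cross-validated probability train for one neuron
#'
#' Fits the encoding model on every fold of the plan, predicts on that
#' fold's non-guarded test frames, and concatenates the predictions into a
#' single cross-validated probability train. Negative frames predicted in
#' several folds take the median of their estimates.
#'
#' Two scales are kept. `p_hat_raw` holds the models' native estimates on
#' the rebalanced training scale; the per-frame likelihood `1 - |r - p|`
#' and its arithmetic mean -- the statistic on which full and null models
#' are compared for the elusive classification -- are evaluated there,
#' where the two models are directly comparable as fitted. `p_hat` holds
#' the session-scale probability train: fold log-odds minus the log
#' sampling ratio (the standard case-control intercept correction; slopes,
#' and with them the kernels, are unaffected by the rebalanced sampling),
#' then prevalence-matched by a single intercept shift so the fold's mean
#' estimate equals the session positive rate, countering the mean inflation
#' that out-of-fold log-odds noise causes in the small-probability regime.
#' Decoding and trial-averaged accuracy use `p_hat`: the decoder's product
#' likelihood degenerates to winner-take-all unless the probabilities are
#' on the calibrated session scale.
#'
#' @param activity_row binary activity of the neuron.
#' @param design a `design_matrix` (or a plain numeric matrix).
#' @param plan a [plan_folds()] object for this neuron.
#' @param alpha,lambda elastic-net parameters (see [fit_encoding_glm()]).
#' @return Object of class `cv_estimate`: list with `p_hat` (per frame, NA
#'   where no fold produced an estimate), `likelihood`, `mean_likelihood`,
#'   `fits` (per-fold `encoding_fit`s) and the plan.
#' @export
cv_estimate <- function(activity_row, design, plan, alpha = 0.2, lambda = 1e-4) {
  X <- if (inherits(design, "design_matrix")) design$X else design
  y <- as.integer(activity_row)
  stopifnot(inherits(plan, "fold_plan"), nrow(X) == length(y))
  row_ok <- if (inherits(design, "design_matrix")) design$row_mask else rep(TRUE, nrow(X))

  preds <- vector("list", length(plan$folds))
  fits <- vector("list", length(plan$folds))
  rate <- mean(y)
  preds_raw <- vector("list", length(plan$folds))
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    tr <- fold$train[row_ok[fold$train]]
    te <- fold$test[row_ok[fold$test]]
    fit <- fit_encoding_glm(X[tr, , drop = FALSE], y[tr], alpha, lambda)
    offset <- case_control_offset(y, tr)
    eta_raw <- fit$intercept + drop(X[te, , drop = FALSE] %*% fit$weights)
    p_raw <- rep(NA_real_, length(y))
    p_raw[te] <- plogis(eta_raw)
    p <- rep(NA_real_, length(y))
    p[te] <- calibrate_to_rate(eta_raw - offset, rate)
    preds_raw[[f]] <- p_raw
    preds[[f]] <- p
    fits[[f]] <- fit
  }
  new_cv_estimate(
    y,
    p_hat = collate_fold_predictions(preds, length(y)),
    p_hat_raw = collate_fold_predictions(preds_raw, length(y)),
    fits = fits, plan = plan
  )
}

# internal: prevalence matching. Out-of-fold log-odds carry estimation
# noise whose spread inflates the mean probability (E[e^z] grows with the
# variance of z in the small-p regime); a single intercept shift restores
# mean(p) = session positive rate. Uses only the predictions and the
# session prevalence, never per-frame test labels.
calibrate_to_rate <- function(eta, rate) {
  if (length(eta) == 0) return(numeric(0))
  f <- function(d) mean(plogis(eta + d)) - rate
  if (f(-30) > 0 || f(30) < 0) return(plogis(eta)) # degenerate; leave as-is
  plogis(eta + uniroot(f, c(-30, 30), tol = 1e-10)$root)
}

# internal: assemble a cv_estimate.
# Two probability trains are kept: `p_hat` on the session scale
# (case-control corrected + prevalence matched; what the decoder and
# accuracy use) and `p_hat_raw` on the rebalanced training scale (what the
# models natively estimate). The per-frame likelihood 1 - |r - p| and its
# arithmetic mean -- the model-comparison statistic for the elusive
# classification -- are evaluated on the rebalanced scale, where full and
# null models are directly comparable as fitted.
new_cv_estimate <- function(y, p_hat, p_hat_raw, fits, plan) {
  lik <- 1 - abs(y - p_hat_raw)
  structure(
    list(
      p_hat = p_hat, p_hat_raw = p_hat_raw, likelihood = lik,
      mean_likelihood = mean(lik, na.rm = TRUE),
      n_estimated = sum(!is.na(p_hat)), fits = fits, plan = plan
    ),
    class = "cv_estimate"
  )
}

#' Intercept-only null model under the same cross-validation
#'
#' The null model fits a single constant to each fold's training set (the
#' training positive fraction) and is scored exactly like the full model,
#' on both scales (see [cv_estimate()]). A neuron whose full model does not
#' outperform this null in mean cross-validated likelihood is classified as
#' *elusive* and excluded from accuracy-based analyses.
#'
#' @inheritParams cv_estimate
#' @return A `cv_estimate` whose per-fold "fit" is the constant training
#'   mean.
#' @export
cv_null <- function(activity_row, plan) {
  y <- as.integer(activity_row)
  stopifnot(inherits(plan, "fold_plan"))
  rate <- mean(y)
  preds <- vector("list", length(plan$folds))
  preds_raw <- vector("list", length(plan$folds))
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    train_frac <- mean(y[fold$train])
    offset <- case_control_offset(y, fold$train)
    p_raw <- rep(NA_real_, length(y))
    p_raw[fold$test] <- train_frac
    p <- rep(NA_real_, length(y))
    p[fold$test] <- calibrate_to_rate(
      rep(qlogis(train_frac) - offset, length(fold$test)), rate
    )
    preds_raw[[f]] <- p_raw
    preds[[f]] <- p
  }
  new_cv_estimate(
    y,
    p_hat = collate_fold_predictions(preds, length(y)),
    p_hat_raw = collate_fold_predictions(preds_raw, length(y)),
    fits = NULL, plan = plan
  )
}

#' Elusive-neuron classification
#'
#' @inheritParams cv_estimate
#' @param cv optional precomputed full-model [cv_estimate()].
#' @return List with `elusive` (TRUE iff the full model's mean CV likelihood
#'   does not exceed the null's), `full_likelihood`, `null_likelihood` and
#'   the null `cv_estimate`.
#' @export
fit_null_and_classify <- function(activity_row, design, plan,
                                  alpha = 0.2, lambda = 1e-4, cv = NULL) {
  if (is.null(cv)) cv <- cv_estimate(activity_row, design, plan, alpha, lambda)
  null_cv <- cv_null(activity_row, plan)
  list(
    elusive = cv$mean_likelihood <= null_cv$mean_likelihood,
    full_likelihood = cv$mean_likelihood,
    null_likelihood = null_cv$mean_likelihood,
    null = null_cv, cv = cv
  )
}

#' Trial-averaged prediction accuracy
#'
#' The encoding accuracy of a neuron is the squared Pearson correlation
#' between its trial-averaged binarized activity and the trial-averaged
#' cross-validated probability train, within the task-related window around
#' successful pull initiations. Frames without a CV estimate are excluded
#' from both averages. A constant trial average makes the correlation
#' undefined; the accuracy is then 0 with a `degenerate` flag.
#'
#' @param cv a [cv_estimate()].
#' @param activity_row the neuron's binary activity.
#' @param events successful pull initiation frames.
#' @param window task-related window in seconds (default `c(-1, 3)`).
#' @param frame_rate frames per second.
#' @return List with `r2`, `n_events`, `degenerate`.
#' @export
prediction_accuracy <- function(cv, activity_row, events, window = c(-1, 3),
                                frame_rate = 30) {
  stopifnot(inherits(cv, "cv_estimate"))
  y <- as.numeric(activity_row)
  p <- cv$p_hat
  n <- length(y)
  lo <- round(window[1] * frame_rate)
  hi <- round(window[2] * frame_rate)
  usable <- events[events + lo >= 1 & events + hi <= n]
  if (length(usable) < 2) stop("need at least two usable events", call. = FALSE)
  lags <- lo:hi
  avg_y <- numeric(length(lags))
  avg_p <- numeric(length(lags))
  cnt <- numeric(length(lags))
  for (ev in usable) {
    idx <- ev + lags
    ok <- !is.na(p[idx])
    avg_y[ok] <- avg_y[ok] + y[idx][ok]
    avg_p[ok] <- avg_p[ok] + p[idx][ok]
    cnt[ok] <- cnt[ok] + 1
  }
  good <- cnt > 0
  avg_y <- avg_y[good] / cnt[good]
  avg_p <- avg_p[good] / cnt[good]
  if (sd(avg_y) == 0 || sd(avg_p) == 0) {
    return(list(r2 = 0, n_events = length(usable), degenerate = TRUE))
  }
  list(
    r2 = cor(avg_y, avg_p)^2, n_events = length(usable), degenerate = FALSE
  )
}

#' Encoding unique contribution of a category
#'
#' The minimum contribution of a variable category: the drop in
#' cross-validated accuracy when the category is removed from the full
#' model, floored at zero.
#'
#' @param full_r2 full-model accuracy.
#' @param reduced_r2 accuracy of the model without the category.
#' @return `max(full_r2 - reduced_r2, 0)`.
#' @examples
#' unique_contribution(0.5, 0.3) # 0.2
#' unique_contribution(0.3, 0.5) # 0
#' @export
unique_contribution <- function(full_r2, reduced_r2) {
  pmax(full_r2 - reduced_r2, 0)
}

#' Fit the full encoding model of one neuron, with optional category models
#'
#' Convenience wrapper running the whole per-neuron encoding analysis: fold
#' planning, full-model CV, null model and elusive classification,
#' trial-averaged accuracy, and (optionally) the six single-category and six
#' leave-one-category-out models with their unique contributions. All models
#' of a neuron share the same fold plan.
#'
#' @param activity_row binary activity of the neuron.
#' @param design the full `design_matrix`.
#' @param events successful pull initiation frames.
#' @param alpha,lambda elastic-net parameters.
#' @param categories compute per-category models (slow: 12 extra CV runs).
#' @param seed seed for the fold plan.
#' @param window,frame_rate accuracy window (see [prediction_accuracy()]).
#' @return Object of class `neuron_encoding`: list with `cv`, `null`,
#'   `elusive`, `accuracy`, `kernels`, and (if requested) `category` (tibble
#'   of single-category/leave-out accuracies and unique contributions).
#' @export
encode_neuron <- function(activity_row, design, events,
                          alpha = 0.2, lambda = 1e-4,
                          categories = FALSE, seed = 1L,
                          window = c(-1, 3), frame_rate = 30) {
  plan <- plan_folds(activity_row, frame_rate = frame_rate, seed = seed)
  cls <- fit_null_and_classify(activity_row, design, plan, alpha, lambda)
  cv <- cls$cv
  acc <- prediction_accuracy(cv, activity_row, events, window, frame_rate)
  kernels <- extract_kernels(cv$fits, design$basis, design)

  cat_tbl <- NULL
  if (isTRUE(categories)) {
    cats <- intersect(category_levels(), unique(unname(design$categories)))
    rows <- lapply(cats, function(ct) {
      d_single <- subset_design(design, ct, keep = TRUE)
      d_loo <- subset_design(design, ct, keep = FALSE)
      cv_s <- cv_estimate(activity_row, d_single, plan, alpha, lambda)
      cv_l <- cv_estimate(activity_row, d_loo, plan, alpha, lambda)
      acc_s <- prediction_accuracy(cv_s, activity_row, events, window, frame_rate)
      acc_l <- prediction_accuracy(cv_l, activity_row, events, window, frame_rate)
      tibble::tibble(
        category = ct,
        single_r2 = acc_s$r2,
        leave_out_r2 = acc_l$r2,
        delta_r2 = unique_contribution(acc$r2, acc_l$r2)
      )
    })
    cat_tbl <- dplyr::bind_rows(rows)
  }

  structure(
    list(
      cv = cv, null = cls$null, elusive = cls$elusive,
      full_likelihood = cls$full_likelihood,
      null_likelihood = cls$null_likelihood,
      accuracy = acc$r2, accuracy_degenerate = acc$degenerate,
      kernels = kernels, category = cat_tbl, plan = plan,
      alpha = alpha, lambda = lambda
    ),
    class = "neuron_encoding"
  )
}

#' @export
print.neuron_encoding <- function(x, ...) {
  cat(sprintf(
    "<neuron_encoding> %s; CV likelihood %.4f (null %.4f); accuracy R^2 = %.3f\n",
    if (x$elusive) "elusive" else "modelable",
    x$full_likelihood, x$null_likelihood, x$accuracy
  ))
  invisible(x)
}

#' Encode every neuron of a session
#'
#' Runs [encode_neuron()] over all rows of a session's activity matrix.
#' Neurons with fewer than 10 positive frames are skipped with a logged
#' reason (their accuracy is NA and they are flagged).
#'
#' @param bundle a `session_bundle` with activity.
#' @param design the session's full `design_matrix`.
#' @param alpha,lambda,categories,seed,window passed to [encode_neuron()].
#' @param verbose print a per-neuron progress line.
#' @return List with `results` (tibble: one row per neuron with accuracy,
#'   likelihoods, elusive/skipped flags), `encodings` (list of
#'   `neuron_encoding` or NULL), `p_hat` (frames x neurons matrix of CV
#'   probability trains) and `events`.
#' @export
encode_session <- function(bundle, design, alpha = 0.2, lambda = 1e-4,
                           categories = FALSE, seed = 1L,
                           window = c(-1, 3), verbose = FALSE) {
  stopifnot(inherits(bundle, "session_bundle"), !is.null(bundle$activity))
  A <- bundle$activity
  events <- bundle$trials$init_frame[bundle$trials$outcome == "success"]
  nn <- nrow(A)
  encodings <- vector("list", nn)
  p_hat <- matrix(NA_real_, bundle$n_frames, nn)
  rows <- vector("list", nn)
  for (i in seq_len(nn)) {
    y <- A[i, ]
    if (sum(y) < 10) {
      rows[[i]] <- tibble::tibble(
        neuron = i, n_positive = sum(y), skipped = TRUE,
        skip_reason = "fewer than 10 positive frames",
        elusive = NA, full_likelihood = NA_real_, null_likelihood = NA_real_,
        accuracy = NA_real_
      )
      next
    }
    # one shared seed: negative training draws (hence guard windows) align
    # across neurons, so downstream decoding keeps a usable library of
    # frames estimated for every neuron
    enc <- encode_neuron(
      y, design, events,
      alpha = alpha, lambda = lambda,
      categories = categories, seed = seed,
      window = window, frame_rate = bundle$frame_rate
    )
    encodings[[i]] <- enc
    p_hat[, i] <- enc$cv$p_hat
    rows[[i]] <- tibble::tibble(
      neuron = i, n_positive = sum(y), skipped = FALSE, skip_reason = NA_character_,
      elusive = enc$elusive, full_likelihood = enc$full_likelihood,
      null_likelihood = enc$null_likelihood, accuracy = enc$accuracy
    )
    if (verbose) {
      message(sprintf(
        "neuron %d/%d: %s, R^2 = %.3f", i, nn,
        if (enc$elusive) "elusive" else "modelable", enc$accuracy
      ))
    }
  }
  list(
    results = dplyr::bind_rows(rows), encodings = encodings,
    p_hat = p_hat, events = events, session_id = bundle$session_id
  )
}

# internal: kernel set (lag x variable matrix) from one weight vector
kernel_set_from_weights <- function(weights, variables, basis,
                                    variable_of = NULL) {
  nb <- ncol(basis$kernels)
  if (is.null(variable_of)) variable_of <- rep(variables, each = nb)
  K <- matrix(0, nrow(basis$kernels), length(variables),
    dimnames = list(NULL, variables)
  )
  for (vi in seq_along(variables)) {
    w <- weights[variable_of == variables[vi]]
    K[, vi] <- basis$kernels %*% w
  }
  structure(
    list(kernels = K, lags_s = basis$lags_s, variables = variables),
    class = "kernel_set"
  )
}

#' Temporal kernels of an encoding model
#'
#' For each behavioral variable, the kernel is the weight-summed combination
#' of the Gaussian basis functions - the model's temporal dependency on that
#' variable as a function of lag. With the 10 per-fold fits of a session, the
#' session kernel is the elementwise median across folds.
#'
#' @param fits a list of `encoding_fit` objects (the per-fold fits), or a
#'   single fit.
#' @param basis the [gaussian_basis()] the design was built with.
#' @param design the `design_matrix` (for the column-to-variable map).
#' @return Object of class `kernel_set`: list with `kernels` (lags x
#'   variables matrix), `lags_s`, `variables`.
#' @export
extract_kernels <- function(fits, basis, design) {
  stopifnot(inherits(basis, "basis_set"), inherits(design, "design_matrix"))
  if (inherits(fits, "encoding_fit")) fits <- list(fits)
  sets <- lapply(fits, function(f) {
    kernel_set_from_weights(f$weights, design$variables, basis, design$variable_of)$kernels
  })
  K <- apply(simplify2array(sets), c(1, 2), median)
  structure(
    list(kernels = K, lags_s = basis$lags_s, variables = design$variables),
    class = "kernel_set"
  )
}

#' @export
print.kernel_set <- function(x, ...) {
  cat(sprintf(
    "<kernel_set> %d variables x %d lags (%.1f..%.1f s)\n",
    ncol(x$kernels), nrow(x$kernels), min(x$lags_s), max(x$lags_s)
  ))
  invisible(x)
}

#' Correlation of a kernel set with another (e.g. ground truth)
#'
#' @param ks1,ks2 `kernel_set` objects on the same lag grid.
#' @param flatten correlate the concatenated kernels of all variables
#'   (default) rather than per variable.
#' @return A single correlation (flatten = TRUE) or a named vector per
#'   variable (NA where either kernel is identically zero).
#' @export
kernel_correlation <- function(ks1, ks2, flatten = TRUE) {
  stopifnot(inherits(ks1, "kernel_set"), inherits(ks2, "kernel_set"))
  common <- intersect(ks1$variables, ks2$variables)
  A <- ks1$kernels[, common, drop = FALSE]
  B <- ks2$kernels[, common, drop = FALSE]
  if (flatten) {
    if (sd(A) == 0 || sd(B) == 0) return(NA_real_)
    return(cor(as.vector(A), as.vector(B)))
  }
  vapply(common, function(v) {
    if (sd(A[, v]) == 0 || sd(B[, v]) == 0) NA_real_ else cor(A[, v], B[, v])
  }, numeric(1))
}

#' Between-session kernel consistency
#'
#' How consistently a variable shapes a neuron's encoding model across
#' sessions: for every session pair and every variable, the Pearson
#' correlation between the neuron's session kernels, averaged within neuron
#' groups. Pairs where either kernel is identically zero are excluded and
#' counted.
#'
#' @param kernels_by_session list (one per session) of lists of `kernel_set`
#'   objects (one per neuron, same order).
#' @param groups factor/character vector assigning each neuron to a group
#'   (e.g. `"top20"` vs `"other"`); default one group.
#' @return Tibble with columns `group`, `variable`, `mean_correlation`,
#'   `n_pairs`, `n_excluded`.
#' @export
kernel_consistency <- function(kernels_by_session, groups = NULL) {
  ns <- length(kernels_by_session)
  if (ns < 2) stop("need kernels from at least two sessions", call. = FALSE)
  nn <- length(kernels_by_session[[1]])
  if (is.null(groups)) groups <- rep("all", nn)
  stopifnot(length(groups) == nn)
  pairs <- utils::combn(ns, 2)
  variables <- kernels_by_session[[1]][[1]]$variables

  rows <- list()
  for (g in unique(groups)) {
    members <- which(groups == g & !vapply(kernels_by_session[[1]], is.null, logical(1)))
    for (v in variables) {
      cc <- c()
      n_excl <- 0L
      for (i in members) {
        for (p in seq_len(ncol(pairs))) {
          k1 <- kernels_by_session[[pairs[1, p]]][[i]]
          k2 <- kernels_by_session[[pairs[2, p]]][[i]]
          if (is.null(k1) || is.null(k2)) next
          a <- k1$kernels[, v]
          b <- k2$kernels[, v]
          if (sd(a) == 0 || sd(b) == 0) {
            n_excl <- n_excl + 1L
            next
          }
          cc <- c(cc, cor(a, b))
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, variable = v,
        mean_correlation = if (length(cc) > 0) mean(cc) else NA_real_,
        n_pairs = length(cc), n_excluded = n_excl
      )
    }
  }
  dplyr::bind_rows(rows)
}
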