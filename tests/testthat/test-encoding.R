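test_that("fold plans rebalance training and test every positive exactly once", {
  withr::with_seed(8, {
    n <- 20000
    y <- integer(n)
    y[sort(sample(n, 100))] <- 1L
  })
  plan <- plan_folds(y, seed = 3)
  expect_length(plan$folds, 10)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  for (fold in plan$folds) {
    expect_equal(sum(y[fold$train]), 90) # nine-tenths of the positives
    expect_equal(sum(y[fold$train] == 0L), round(0.01 * length(neg)))
    expect_length(intersect(fold$train, fold$test), 0)
  }
  # candidate test positives across folds partition all positives
  test_pos <- lapply(plan$folds, function(f) intersect(pos, c(f$test, f$guarded)))
  expect_setequal(unlist(test_pos), pos)
  expect_equal(sum(lengths(test_pos)), length(pos))

  expect_error(plan_folds(integer(100)), "positive frames")
})

test_that("the 2 s guard removes test frames near training frames", {
  withr::with_seed(9, {
    y <- integer(5000)
    y[sort(sample(5000, 40))] <- 1L
  })
  plan <- plan_folds(y, frame_rate = 30, guard_s = 2, seed = 4)
  for (fold in plan$folds) {
    d_test <- levercode:::nearest_distance(fold$test, fold$train)
    expect_true(all(d_test > 60))
    if (length(fold$guarded) > 0) {
      d_guard <- levercode:::nearest_distance(fold$guarded, fold$train)
      expect_true(all(d_guard <= 60))
    }
  }
})

test_that("full shrinkage collapses the GLM to the intercept-only model", {
  withr::with_seed(10, {
    X <- matrix(rnorm(400 * 30), 400)
    y <- rbinom(400, 1, 0.3)
  })
  fit <- fit_encoding_glm(X, y, alpha = 0.2, lambda = 1e4)
  expect_true(all(abs(fit$weights) < 1e-6))
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-3)
  expect_error(fit_encoding_glm(X, rep(0L, 400)), "positive and")
})

test_that("the GLM solves the stated elastic-net objective (proximal-gradient oracle)", {
  # independent oracle: proximal gradient descent on
  #   mean NLL + lambda * (alpha ||w||_1 + (1 - alpha)/2 ||w||_2^2)
  # with unpenalized intercept, on raw (unstandardized) columns
  withr::with_seed(12, {
    n <- 300
    X <- cbind(rnorm(n), rnorm(n), rnorm(n))
    eta <- 1.2 * X[, 1] - 0.5
    y <- rbinom(n, 1, plogis(eta))
  })
  alpha <- 0.2
  lambda <- 1e-3
  prox <- function(w, t) sign(w) * pmax(abs(w) - t, 0)
  w <- numeric(3)
  b0 <- 0
  step <- 0.5
  for (it in 1:20000) {
    p <- plogis(b0 + drop(X %*% w))
    g_w <- drop(crossprod(X, p - y)) / n + lambda * (1 - alpha) * w
    g_b <- mean(p - y)
    w <- prox(w - step * g_w, step * lambda * alpha)
    b0 <- b0 - step * g_b
  }
  fit <- fit_encoding_glm(X, y, alpha = alpha, lambda = lambda, standardize = FALSE)
  expect_equal(unname(fit$weights), w, tolerance = 1e-4)
  expect_equal(fit$intercept, b0, tolerance = 1e-4)
  expect_gt(fit$weights[1], 0) # informative column recovered with its sign
})

test_that("fold predictions collate with the median rule", {
  preds <- list(
    c(0.1, NA, NA, 0.4),
    c(0.2, 0.7, NA, NA),
    c(0.9, NA, NA, 0.6)
  )
  out <- levercode:::collate_fold_predictions(preds, 4)
  expect_equal(out[1], median(c(0.1, 0.2, 0.9))) # 0.2
  expect_equal(out[2], 0.7)
  expect_true(is.na(out[3]))
  expect_equal(out[4], 0.5)
})

test_that("per-frame likelihood is 1 - |r - p|", {
  y <- c(1L, 0L, 1L, 0L)
  p <- c(1, 0, 0.5, 0.5)
  expect_equal(1 - abs(y - p), c(1, 1, 0.5, 0.5))
  # a perfect probability train gives mean likelihood 1, a coin gives 0.5
  # (checked through cv_null on a degenerate constant-rate neuron below)
})

test_that("the null model predicts a constant near the session rate", {
  withr::with_seed(13, {
    y <- integer(3000)
    y[sort(sample(3000, 30))] <- 1L
  })
  plan <- plan_folds(y, seed = 5)
  null_cv <- cv_null(y, plan)
  est <- null_cv$p_hat[!is.na(null_cv$p_hat)]
  # per fold, the corrected constant: training fraction mapped back through
  # the log sampling-ratio offset, which lands near the population rate
  consts <- vapply(plan$folds, function(f) {
    plogis(qlogis(mean(y[f$train])) - levercode:::case_control_offset(y, f$train))
  }, numeric(1))
  expect_true(all(est >= min(consts) - 1e-12 & est <= max(consts) + 1e-12))
  expect_equal(mean(est), mean(y), tolerance = 0.5)
})

test_that("cross-validated estimates cover the non-guarded frames", {
  enc <- fx_encoding()
  sess <- fx_session()
  for (i in c(1, 5)) {
    cv <- if (!is.null(enc$encodings[[i]])) enc$encodings[[i]]$cv else next
    expect_true(all(cv$p_hat >= 0 & cv$p_hat <= 1, na.rm = TRUE))
    expect_gt(cv$n_estimated / sess$n_frames, 0.3)
    # no frame is both trained on and scored in the same fold
    for (fold in cv$plan$folds) {
      expect_length(intersect(fold$train, fold$test), 0)
    }
  }
})

test_that("lever-driven neurons are modelable, and recover their kernels", {
  enc <- fx_encoding()
  sess <- fx_session()
  res <- enc$results
  # strong neurons (1-4): modelable, with far higher accuracy than noise
  expect_true(all(!res$elusive[1:4]))
  expect_gt(mean(res$accuracy[1:4]), 5 * mean(res$accuracy[5:8]))
  # their fitted kernels correlate with ground truth on informative variables
  basis <- fx_basis()
  inf <- c("lever_position", "lever_velocity_pull")
  for (i in 1:4) {
    kt <- truth_kernels(sess$truth, i, basis)
    pv <- kernel_correlation(enc$encodings[[i]]$kernels, kt, flatten = FALSE)
    expect_gt(mean(pv[inf]), 0.4)
  }
})

test_that("noise neurons score near-zero accuracy", {
  enc <- fx_encoding()
  res <- enc$results
  expect_lt(max(res$accuracy[5:8], na.rm = TRUE), 0.05)
})

test_that("trial-averaged accuracy is affine invariant and null for noise", {
  sess <- fx_session()
  enc <- fx_encoding()
  events <- sess$trials$init_frame[sess$trials$outcome == "success"]
  i <- 1
  cv <- enc$encodings[[i]]$cv
  y <- sess$activity[i, ]

  # estimate identical to the recorded trace: perfect accuracy
  cv_perfect <- cv
  cv_perfect$p_hat <- as.numeric(y)
  out <- prediction_accuracy(cv_perfect, y, events)
  expect_equal(out$r2, 1)

  # affine transform of the recorded average leaves the accuracy at 1
  cv_affine <- cv
  cv_affine$p_hat <- 0.2 + 0.5 * as.numeric(y)
  expect_equal(prediction_accuracy(cv_affine, y, events)$r2, 1)

  # estimate independent of the recording: near-zero accuracy
  withr::with_seed(14, {
    cv_rand <- cv
    cv_rand$p_hat <- runif(length(y))
    expect_lt(prediction_accuracy(cv_rand, y, events)$r2, 0.2)
  })

  # constant estimate: degenerate, accuracy 0 with a flag
  cv_const <- cv
  cv_const$p_hat <- rep(0.3, length(y))
  out_const <- prediction_accuracy(cv_const, y, events)
  expect_equal(out_const$r2, 0)
  expect_true(out_const$degenerate)
})

test_that("unique contribution subtracts and floors at zero", {
  expect_equal(unique_contribution(0.5, 0.3), 0.2)
  expect_equal(unique_contribution(0.3, 0.5), 0)
  expect_equal(unique_contribution(c(0.4, 0.1), c(0.1, 0.4)), c(0.3, 0))
})

test_that("kernel extraction maps weights through the basis", {
  basis <- fx_basis()
  d <- fx_design()
  nb <- ncol(basis$kernels)

  # all-zero weights give identically zero kernels
  f0 <- structure(
    list(intercept = 0, weights = numeric(420), alpha = 0.2, lambda = 1e-4),
    class = "encoding_fit"
  )
  ks0 <- extract_kernels(f0, basis, d)
  expect_true(all(ks0$kernels == 0))

  # a unit weight on one basis reproduces that basis function
  w <- numeric(420)
  j_var <- which(d$variables == "jaw_position")
  w[(j_var - 1) * nb + 11] <- 1
  f1 <- structure(
    list(intercept = 0, weights = w, alpha = 0.2, lambda = 1e-4),
    class = "encoding_fit"
  )
  ks1 <- extract_kernels(f1, basis, d)
  expect_equal(ks1$kernels[, "jaw_position"], unname(basis$kernels[, 11]))
  expect_true(all(ks1$kernels[, colnames(ks1$kernels) != "jaw_position"] == 0))

  # the session kernel is the elementwise median across fold fits
  f2 <- f1
  f2$weights <- 3 * w
  ks_med <- extract_kernels(list(f1, f1, f2), basis, d)
  expect_equal(ks_med$kernels[, "jaw_position"], unname(basis$kernels[, 11]))
})

test_that("kernel consistency is 1 for identical and -1 for flipped kernels", {
  basis <- fx_basis()
  d <- fx_design()
  w <- withr::with_seed(15, rnorm(420))
  ks <- levercode:::kernel_set_from_weights(w, d$variables, basis, d$variable_of)
  ks_flip <- ks
  ks_flip$kernels <- -ks$kernels

  by_session <- list(list(ks, ks), list(ks, ks_flip))
  out <- kernel_consistency(by_session, groups = c("same", "flipped"))
  same <- out[out$group == "same", ]
  flipped <- out[out$group == "flipped", ]
  expect_true(all(abs(same$mean_correlation - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(flipped$mean_correlation + 1) < 1e-12, na.rm = TRUE))

  # zero-kernel variables are excluded with a count
  ks0 <- ks
  ks0$kernels[, "lick"] <- 0
  out0 <- kernel_consistency(list(list(ks0), list(ks0)))
  lick_row <- out0[out0$variable == "lick", ]
  expect_equal(lick_row$n_pairs, 0)
  expect_equal(lick_row$n_excluded, 1)
})

test_that("category models use the right designs and lever dominates for lever neurons", {
  encs <- fixture("encoding_cat", function() {
    # the two most accurate lever-driven fixture neurons
    b <- fx_session()
    d <- fx_design()
    ev <- b$trials$init_frame[b$trials$outcome == "success"]
    lapply(3:4, function(i) {
      encode_neuron(b$activity[i, ], d, ev, categories = TRUE, seed = 31)
    })
  })
  for (enc in encs) {
    expect_equal(nrow(enc$category), 6)
    expect_setequal(enc$category$category, category_levels())
    expect_true(all(enc$category$delta_r2 >= 0))
  }
  # lever-only ground-truth neurons: the single-category lever model far
  # outperforms the single-category models of variables the neuron does not
  # depend on, and approaches the full model (the maximum-contribution
  # bound). The minimum-contribution bound (delta R^2) is not asserted per
  # neuron: reward-locked regressors span any success-aligned average, so
  # leave-one-out differences sit at the fit-noise floor by construction.
  cat_tbl <- dplyr::bind_rows(lapply(encs, `[[`, "category")) |>
    dplyr::group_by(category) |>
    dplyr::summarise(delta_r2 = mean(delta_r2), single_r2 = mean(single_r2))
  lever_single <- cat_tbl$single_r2[cat_tbl$category == "lever"]
  expect_gt(lever_single, 3 * cat_tbl$single_r2[cat_tbl$category == "rf_lever_minus"])
  expect_gt(lever_single, 3 * cat_tbl$single_r2[cat_tbl$category == "lf"])
  expect_gt(lever_single, 0.5 * mean(vapply(encs, `[[`, numeric(1), "accuracy")))
})

test_that("tidiers expose encoding results as tibbles", {
  enc <- fx_encoding()
  ne <- enc$encodings[[1]]
  td <- tidy(ne)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$variable), lever_variables())
  gl <- glance(ne)
  expect_equal(nrow(gl), 1)
  expect_false(gl$elusive)
})
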