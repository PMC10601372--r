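#' Gaussian temporal basis for the encoding model
#'
#' Builds the canonical set of 21 unit-peak Gaussian basis functions with
#' centers from -3.0 to +3.0 s in 0.3 s steps, sampled on the imaging frame
#' clock. The width is parameterized by the half-width at half-height
#' (0.52 s), i.e. `sigma = hwhm / sqrt(2 * log(2))`. Each function is
#' truncated beyond `trunc_sigma` standard deviations from its center.
#'
#' Convolving the 20 behavioral variables with these functions lets the GLM
#' express dependencies of activity at time t on behavior up to 3 s in the
#' past or future. A basis centered at +c seconds reaches `c` seconds into the
#' *past* of behavior (behavior preceding activity); flip `center_sign` to
#' reverse the convention.
#'
#' @param frame_rate frames per second of the imaging clock (default 30).
#' @param centers basis centers in seconds.
#' @param hwhm half-width at half-height in seconds.
#' @param trunc_sigma truncation radius in standard deviations.
#' @param center_sign +1 (default): positive centers look into the past of
#'   behavior; -1 reverses the lag convention.
#' @return An object of class `basis_set`: a list with the sampled kernel
#'   matrix `kernels` (lags x n_basis), `lags_s`, `centers`, `sigma`, `hwhm`
#'   and `frame_rate`.
#' @examples
#' b <- gaussian_basis(30)
#' ncol(b$kernels) # 21
#' max(b$kernels[, 11]) # unit peak
#' @export
gaussian_basis <- function(frame_rate = 30,
                           centers = seq(-3, 3, by = 0.3),
                           hwhm = 0.52,
                           trunc_sigma = 3,
                           center_sign = 1) {
  stopifnot(frame_rate > 0, hwhm > 0, trunc_sigma > 0)
  centers <- sort(centers)
  if (any(diff(centers) <= 0)) stop("basis centers must be strictly increasing", call. = FALSE)
  sigma <- hwhm / sqrt(2 * log(2))
  centers_eff <- center_sign * centers
  lag_min <- floor((min(centers_eff) - trunc_sigma * sigma) * frame_rate)
  lag_max <- ceiling((max(centers_eff) + trunc_sigma * sigma) * frame_rate)
  lags_s <- seq(lag_min, lag_max) / frame_rate
  K <- vapply(centers_eff, function(c0) {
    g <- exp(-(lags_s - c0)^2 / (2 * sigma^2))
    g[abs(lags_s - c0) > trunc_sigma * sigma] <- 0
    g
  }, numeric(length(lags_s)))
  colnames(K) <- sprintf("b%+.1f", centers)
  structure(
    list(
      kernels = K, lags_s = lags_s, centers = centers, sigma = sigma,
      hwhm = hwhm, frame_rate = frame_rate, trunc_sigma = trunc_sigma,
      center_sign = center_sign
    ),
    class = "basis_set"
  )
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf(
    "<basis_set> %d Gaussian functions, centers %.1f..%.1f s (step %.2g s), HWHM %.2f s, %g Hz\n",
    ncol(x$kernels), min(x$centers), max(x$centers),
    if (length(x$centers) > 1) diff(x$centers)[1] else NA, x$hwhm, x$frame_rate
  ))
  invisible(x)
}

# internal: compact support of each sampled basis kernel
kernel_support <- function(basis) {
  lapply(seq_len(ncol(basis$kernels)), function(j) {
    kj <- basis$kernels[, j]
    nz <- which(kj != 0)
    list(
      k = kj[nz[1]:nz[length(nz)]],
      lag0 = round(basis$lags_s[nz[1]] * basis$frame_rate)
    )
  })
}

# internal: convolve one trace with one sampled kernel.
# out[t] = sum_l k[l] * x[t - lag_frames[l]]  (zero padding outside the trace)
convolve_lagged <- function(x, kernel, lags_s, frame_rate) {
  n <- length(x)
  nz <- which(kernel != 0)
  if (length(nz) == 0) return(numeric(n))
  k <- kernel[nz[1]:nz[length(nz)]]
  lag0 <- round(lags_s[nz[1]] * frame_rate) # lag (frames) of k[1]
  # full convolution z[m] = sum_l k[l] x[m - l + 1]; out[t] = z[t - lag0]
  z <- stats::convolve(c(x, numeric(length(k))), rev(k), type = "open")
  idx <- seq_len(n) - lag0
  out <- numeric(n)
  ok <- idx >= 1 & idx <= length(z)
  out[ok] <- z[idx[ok]]
  out
}

#' Expand behavioral variables into the GLM design matrix
#'
#' Convolves each behavioral variable with every basis function, producing the
#' `n_variables x n_basis` regressor matrix the encoding model is fitted on
#' (420 columns for the full 20-variable scheme). Frames flagged in the
#' omitted-frame mask propagate: any design row to which an omitted frame
#' contributes is masked and excluded from fits and scores.
#'
#' @param behavior data frame with the canonical behavioral columns (see
#'   [lever_variables()]), or a subset via `variables`.
#' @param basis a [gaussian_basis()] object.
#' @param variables variables to expand (default: all canonical columns).
#' @param omitted optional logical vector (one per frame) of omitted frames;
#'   defaults to the `omitted` attribute of `behavior`, else none.
#' @return An object of class `design_matrix`: list with the numeric matrix
#'   `X` (frames x regressors, named `<variable>|<center>`), `variables`,
#'   `variable_of` (column -> variable), `row_mask` (TRUE = usable frame) and
#'   the basis.
#' @examples
#' beh <- tibble::tibble(lever_position = c(numeric(50), 1, numeric(50)))
#' d <- expand_design(beh, gaussian_basis(30), variables = "lever_position")
#' dim(d$X) # 101 x 21
#' @export
expand_design <- function(behavior, basis, variables = lever_variables(),
                          omitted = NULL) {
  stopifnot(inherits(basis, "basis_set"))
  behavior <- as.data.frame(behavior)
  missing_cols <- setdiff(variables, names(behavior))
  if (length(missing_cols) > 0) {
    stop("behavior is missing canonical column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(omitted)) omitted <- attr(behavior, "omitted")
  n <- nrow(behavior)
  if (is.null(omitted)) omitted <- rep(FALSE, n)
  stopifnot(length(omitted) == n)

  nb <- ncol(basis$kernels)
  # FFT convolution with the trace transform shared across the 21 bases
  supp <- kernel_support(basis)
  max_k <- max(vapply(supp, function(s) length(s$k), integer(1)))
  N <- stats::nextn(n + max_k - 1L)
  fk <- lapply(supp, function(s) stats::fft(c(s$k, numeric(N - length(s$k)))))
  X <- matrix(0, n, length(variables) * nb)
  cn <- character(ncol(X))
  variable_of <- character(ncol(X))
  for (vi in seq_along(variables)) {
    x <- behavior[[variables[vi]]]
    x[is.na(x)] <- 0
    fx <- stats::fft(c(x, numeric(N - n)))
    for (bi in seq_len(nb)) {
      j <- (vi - 1L) * nb + bi
      z <- Re(stats::fft(fx * fk[[bi]], inverse = TRUE)) / N
      idx <- seq_len(n) - supp[[bi]]$lag0
      col <- numeric(n)
      ok <- idx >= 1 & idx <= N
      col[ok] <- z[idx[ok]]
      X[, j] <- col
      cn[j] <- paste0(variables[vi], "|", colnames(basis$kernels)[bi])
      variable_of[j] <- variables[vi]
    }
  }
  colnames(X) <- cn

  row_mask <- !omitted
  if (any(omitted)) {
    # an omitted frame contaminates every design row its kernel support reaches
    reach <- range(round(basis$lags_s * basis$frame_rate))
    bad <- which(omitted)
    touched <- unique(unlist(lapply(bad, function(f) (f + reach[1]):(f + reach[2]))))
    touched <- touched[touched >= 1 & touched <= n]
    row_mask[touched] <- FALSE
  }

  structure(
    list(
      X = X, variables = variables, variable_of = variable_of,
      row_mask = row_mask, basis = basis,
      categories = variable_categories()[variables]
    ),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf(
    "<design_matrix> %d frames x %d regressors (%d variables x %d bases), %d masked frames\n",
    nrow(x$X), ncol(x$X), length(x$variables), ncol(x$basis$kernels),
    sum(!x$row_mask)
  ))
  invisible(x)
}

#' Restrict a design matrix to a category of variables
#'
#' Returns the single-category design (`keep = TRUE`) or the
#' leave-one-category-out design (`keep = FALSE`) used to bound each
#' category's contribution to the encoding model.
#'
#' @param design a [expand_design()] result.
#' @param category one of `category_levels()`.
#' @param keep keep (`TRUE`) or drop (`FALSE`) the category's columns.
#' @return A `design_matrix` with the subset of columns.
#' @export
subset_design <- function(design, category, keep = TRUE) {
  stopifnot(inherits(design, "design_matrix"))
  vars <- category_variables(category)
  sel_vars <- if (keep) intersect(design$variables, vars) else setdiff(design$variables, vars)
  if (length(sel_vars) == 0) stop("empty design after subsetting", call. = FALSE)
  cols <- design$variable_of %in% sel_vars
  out <- design
  out$X <- design$X[, cols, drop = FALSE]
  out$variable_of <- design$variable_of[cols]
  out$variables <- sel_vars
  out$categories <- variable_categories()[sel_vars]
  out
}
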