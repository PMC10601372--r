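#' Canonical behavioral variables and their categories
#'
#' The encoding and decoding models operate on a fixed scheme of 20 behavioral
#' variables sampled on the imaging frame clock: lever position plus its
#' pull/return velocities (3), the lever-independent right-forepaw position on
#' two axes plus four directional velocities (6), the left-forepaw equivalents
#' (6), jaw position plus two directional velocities (3), a binary lick train
#' (1) and a binary reward train (1). Directional velocities are the positive
#' and negative parts of the signed finite-difference velocity, so each is
#' non-negative and the pair reconstructs the signed signal.
#'
#' `lever_variables()` returns the 20 canonical column names in order;
#' `variable_categories()` maps each variable to one of the six categories
#' used for single-category and leave-one-category-out models.
#'
#' @return `lever_variables()`: character vector of length 20.
#'   `variable_categories()`: named character vector (names = variables,
#'   values = categories, in canonical order).
#' @examples
#' lever_variables()
#' table(variable_categories())
#' @export
lever_variables <- function() {
  c(
    "lever_position", "lever_velocity_pull", "lever_velocity_return",
    "rf_x", "rf_y",
    "rf_vx_plus", "rf_vx_minus", "rf_vy_plus", "rf_vy_minus",
    "lf_x", "lf_y",
    "lf_vx_plus", "lf_vx_minus", "lf_vy_plus", "lf_vy_minus",
    "jaw_position", "jaw_velocity_open", "jaw_velocity_close",
    "lick", "reward"
  )
}

#' @rdname lever_variables
#' @export
variable_categories <- function() {
  v <- lever_variables()
  cat <- c(
    rep("lever", 3L),
    rep("rf_lever_minus", 6L),
    rep("lf", 6L),
    rep("jaw", 3L),
    "lick", "reward"
  )
  stats::setNames(cat, v)
}

#' @rdname lever_variables
#' @export
category_levels <- function() {
  c("lever", "rf_lever_minus", "lf", "jaw", "lick", "reward")
}

# internal: variables belonging to one category
category_variables <- function(category) {
  map <- variable_categories()
  if (!category %in% category_levels()) {
    stop("unknown category: ", category, call. = FALSE)
  }
  names(map)[map == category]
}
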