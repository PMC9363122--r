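#' Age-dependent serum estrogen input
#'
#' The exogenous driver of aging and menopause: relative serum estrogen,
#' normalized to 1 at the premenopausal plateau, declining as a logistic
#' sigmoid centered at the menopause age to a postmenopausal floor. The
#' curve is a fixed literature-style input, not a fitted quantity; its
#' parameters live in the parameter registry flagged fixed.
#'
#' @param premenopausal_level Relative premenopausal plateau (default 1).
#' @param postmenopausal_floor Relative postmenopausal plateau in (0, 1).
#' @param menopause_age Logistic midpoint in years.
#' @param transition_width Logistic scale of the decline, years.
#' @return An object of class `estrogen_curve`.
#' @examples
#' ec <- estrogen_curve()
#' estrogen_level(ec, c(25, 51, 80))
#' @export
estrogen_curve <- function(premenopausal_level = 1,
                           postmenopausal_floor = 0.1,
                           menopause_age = 51,
                           transition_width = 2) {
  stopifnot(premenopausal_level > 0,
            postmenopausal_floor > 0,
            postmenopausal_floor < premenopausal_level,
            menopause_age > 0, transition_width > 0)
  structure(list(premenopausal_level = premenopausal_level,
                 postmenopausal_floor = postmenopausal_floor,
                 menopause_age = menopause_age,
                 transition_width = transition_width),
            class = "estrogen_curve")
}

#' Build the estrogen curve from a parameter registry
#'
#' Convenience constructor reading `est_floor`, `est_menopause_age` and
#' `est_width` from an `osteo_params` registry.
#'
#' @param params An `osteo_params` registry.
#' @return An `estrogen_curve`.
#' @export
estrogen_curve_from_params <- function(params) {
  v <- param_value(params, c("est_floor", "est_menopause_age", "est_width"))
  estrogen_curve(postmenopausal_floor = v[["est_floor"]],
                 menopause_age = v[["est_menopause_age"]],
                 transition_width = v[["est_width"]])
}

#' Evaluate relative estrogen at a given age
#'
#' @param curve An `estrogen_curve`.
#' @param age Age(s) in years, nonnegative; vectorised.
#' @return Relative estrogen level(s), nonincreasing in age, bounded by the
#'   two plateaus; equal to the plateau midpoint at `menopause_age`.
#' @export
estrogen_level <- function(curve, age) {
  stopifnot(inherits(curve, "estrogen_curve"), all(age >= 0))
  span <- curve$premenopausal_level - curve$postmenopausal_floor
  curve$postmenopausal_floor +
    span * stats::plogis(-(age - curve$menopause_age) / curve$transition_width)
}

#' @export
print.estrogen_curve <- function(x, ...) {
  cat("<estrogen_curve> plateau ", x$premenopausal_level, " -> floor ",
      x$postmenopausal_floor, ", menopause at ", x$menopause_age,
      " yr (width ", x$transition_width, " yr)\n", sep = "")
  invisible(x)
}
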