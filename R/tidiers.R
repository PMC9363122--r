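#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulated trajectory
#'
#' @param x A `bone_sim` object.
#' @param ... Unused.
#' @return The trajectory tibble (age, state components, BMD and marker
#'   observables).
#' @export
tidy.bone_sim <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a simulation
#'
#' @param x A `bone_sim` object.
#' @param ... Unused.
#' @return Tibble with the age span, number of dose events, final relative
#'   BMD, minimum relative BMD, and peak CTX suppression/elevation.
#' @export
glance.bone_sim <- function(x, ...) {
  tr <- x$trajectory
  tibble::tibble(
    from_age = x$from_age, to_age = x$to_age,
    n_doses = nrow(x$regimen),
    bmd_relative_final = utils::tail(tr$bmd_relative, 1),
    bmd_relative_min = min(tr$bmd_relative),
    ctx_change_min = min(tr$ctx_change),
    ctx_change_max = max(tr$ctx_change))
}

#' Tidy a calibration fit
#'
#' @param x An `osteo_fit` object.
#' @param ... Unused.
#' @return Per-fitted-parameter tibble: `name`, `estimate`, `lower`,
#'   `upper`.
#' @export
tidy.osteo_fit <- function(x, ...) {
  free <- x$free_names %||% x$params$name[x$params$free]
  idx <- match(free, x$params$name)
  tibble::tibble(name = free,
                 estimate = x$params$value[idx],
                 lower = x$params$lower[idx],
                 upper = x$params$upper[idx])
}

#' One-row summary of a calibration fit
#'
#' @param x An `osteo_fit` object.
#' @param ... Unused.
#' @return Tibble with the best loss, start counts, and the worst per-dataset
#'   BMD MAPE of the fitted model.
#' @export
glance.osteo_fit <- function(x, ...) {
  bmd_rows <- x$report[x$report$observable == "bmd", ]
  tibble::tibble(
    best_loss = x$best_loss,
    n_starts = max(1L, nrow(x$starts)),
    n_converged = if (nrow(x$starts)) sum(x$starts$converged) else 1L,
    n_free = length(x$free_names %||% character()),
    max_bmd_mape = max(bmd_rows$mape))
}
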