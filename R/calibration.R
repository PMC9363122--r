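#' Mean absolute percentage error
#'
#' The primary goodness-of-fit measure: `100 * mean(|sim - obs| / |obs|)`.
#' Scale-invariant under joint rescaling of both series. Observed zeros are
#' refused — for near-zero baseline-change series use
#' [btm_direction_concordance()] instead.
#'
#' @param simulated,observed Numeric series of equal length (>= 1).
#' @return MAPE in percent (>= 0).
#' @examples
#' mape(c(1.0, 1.1), c(1.0, 1.0)) # 5
#' @export
mape <- function(simulated, observed) {
  stopifnot(length(simulated) == length(observed), length(observed) >= 1)
  if (any(observed == 0)) {
    stop("observed series contains zeros; MAPE undefined ",
         "(use excursion concordance for near-zero series)", call. = FALSE)
  }
  100 * mean(abs(simulated - observed) / abs(observed))
}

#' Direction concordance of bone-turnover-marker excursions
#'
#' Compares the qualitative behavior of a baseline-change series: `TRUE` iff
#' the sign of the maximum-magnitude excursion from baseline agrees between
#' simulation and data; `NA` if the observed series is identically zero.
#'
#' @param simulated,observed Baseline-change series of equal length.
#' @return `TRUE`, `FALSE`, or `NA` (not applicable).
#' @export
btm_direction_concordance <- function(simulated, observed) {
  stopifnot(length(simulated) == length(observed))
  if (all(observed == 0)) return(NA)
  dom_sign <- function(x) sign(x[which.max(abs(x))])
  if (all(simulated == 0)) return(NA)
  dom_sign(simulated) == dom_sign(observed)
}

#' Default calibration configuration
#'
#' Residual weights (BMD 1 per point, BTM down-weighted to 0.2), the
#' near-zero BTM exclusion threshold (|observed change| < 0.05 excluded from
#' MAPE and residuals), multi-start settings, solver tolerances used inside
#' the objective, and the age at which calibration simulations start (40,
#' on the premenopausal plateau, where the homeostatic state is the natural
#' initial condition).
#'
#' @param ... Overrides of the defaults.
#' @return Named list of configuration values.
#' @export
calibration_config <- function(...) {
  cfg <- list(weight_bmd = 1, weight_btm = 0.2, btm_exclude = 0.05,
              n_starts = 32, seed = 42, sim_from_age = 40,
              rtol = 1e-8, atol = 1e-10, grid_step = 0.1,
              penalty = 1e6, maxiter = 100)
  utils::modifyList(cfg, list(...))
}

## Simulated counterparts of one hybrid dataset: model BMD (relative to the
## earliest aging anchor) at the data ages, and model BTM changes at the
## data ages.
simulate_for_dataset <- function(params, hybrid, config,
                                 estrogen = estrogen_curve_from_params(params)) {
  anchors <- hybrid$aging_anchors
  ref_age <- min(anchors$age)
  from_age <- min(config$sim_from_age, ref_age)
  to_age <- max(anchors$age, hybrid$treatment$age,
                if (!is.null(hybrid$btm)) hybrid$btm$age) + 0.5
  ## measurement ages are solver output points: no interpolation error
  grid <- sort(unique(c(seq(from_age, to_age, by = config$grid_step),
                        to_age, ref_age, hybrid$treatment_start_age,
                        hybrid$treatment$age,
                        if (!is.null(hybrid$btm)) hybrid$btm$age)))
  sim <- simulate_bmd(params, regimen = hybrid$regimen, estrogen = estrogen,
                      from_age = from_age, to_age = to_age,
                      output_ages = grid,
                      reference_age = ref_age,
                      baseline_age = hybrid$treatment_start_age,
                      rtol = config$rtol, atol = config$atol)
  tr <- sim$trajectory
  out <- list(
    bmd_at = function(ages) stats::approx(tr$age, tr$bmd_relative,
                                          xout = ages)$y,
    btm_at = function(marker, ages) {
      col <- paste0(marker, "_change")
      stats::approx(tr$age, tr[[col]], xout = ages)$y
    },
    sim = sim)
  out
}

## Residual vector for one hybrid dataset (weighted).
dataset_residuals <- function(pred, hybrid, config) {
  res <- sqrt(config$weight_bmd) *
    (pred$bmd_at(hybrid$treatment$age) - hybrid$treatment$bmd_rel)
  if (!is.null(hybrid$btm)) {
    keep <- abs(hybrid$btm$change) >= config$btm_exclude
    if (any(keep)) {
      b <- hybrid$btm[keep, ]
      sim_b <- vapply(seq_len(nrow(b)), function(i) {
        pred$btm_at(b$marker[i], b$age[i])
      }, numeric(1))
      res <- c(res, sqrt(config$weight_btm) * (sim_b - b$change))
    }
  }
  res
}

## Residuals of the aging anchors under the drug-free model.
aging_residuals <- function(params, anchors, config,
                            estrogen = estrogen_curve_from_params(params)) {
  ref_age <- min(anchors$age)
  from_age <- min(config$sim_from_age, ref_age)
  to_age <- max(anchors$age) + 0.5
  grid <- sort(unique(c(seq(from_age, to_age, by = config$grid_step),
                        to_age, anchors$age)))
  sim <- simulate_bmd(params, regimen = NULL, estrogen = estrogen,
                      from_age = from_age, to_age = to_age,
                      output_ages = grid, reference_age = ref_age,
                      rtol = config$rtol, atol = config$atol)
  tr <- sim$trajectory
  model <- stats::approx(tr$age, tr$bmd_relative, xout = anchors$age)$y
  sqrt(config$weight_bmd) * (model - anchors$bmd_rel)
}

collection_hybrids <- function(collection) {
  if (inherits(collection, "osteo_hybrid")) return(list(collection))
  hy <- collection$calibration %||% collection
  if (inherits(hy, "osteo_hybrid")) hy <- list(hy)
  hy
}

## Full weighted residual vector over a collection of hybrid datasets.
collection_residuals <- function(params, collection, config) {
  hybrids <- collection_hybrids(collection)
  if (length(hybrids) == 0) stop("empty dataset collection", call. = FALSE)
  anchors <- hybrids[[1]]$aging_anchors
  est <- estrogen_curve_from_params(params)
  res <- aging_residuals(params, anchors, config, est)
  for (h in hybrids) {
    pred <- simulate_for_dataset(params, h, config, est)
    res <- c(res, dataset_residuals(pred, h, config))
  }
  res
}

#' Calibration objective
#'
#' The scalar loss minimized during calibration: the weighted sum of squared
#' residuals between model simulations and a collection of hybrid
#' aging/treatment datasets — aging-anchor BMD residuals plus, per dataset,
#' treatment BMD residuals and (down-weighted) BTM baseline-change
#' residuals, all from simulations run at the candidate parameter values.
#' Deterministic for fixed inputs. A simulation failure at a parameter point
#' yields a large finite penalty (with a message), not an exception.
#'
#' @param free_values Named numeric vector of values for the free parameters
#'   being probed (a subset of registry names).
#' @param params The full `osteo_params` registry supplying everything not
#'   in `free_values`.
#' @param collection A list with `calibration` hybrids (see
#'   [load_study_collection()]), a plain list of `osteo_hybrid`, or a single
#'   hybrid.
#' @param config See [calibration_config()].
#' @return Scalar loss (sum of squared weighted residuals).
#' @export
objective <- function(free_values, params, collection,
                      config = calibration_config()) {
  r <- objective_residuals(free_values, params, collection, config)
  sum(r^2)
}

objective_residuals <- function(free_values, params, collection, config) {
  if (length(collection_hybrids(collection)) == 0) {
    stop("empty dataset collection", call. = FALSE)
  }
  p <- tryCatch(set_param_values(params, free_values),
                error = function(e) NULL)
  if (is.null(p)) return(sqrt(config$penalty))
  tryCatch(collection_residuals(p, collection, config),
           error = function(e) {
             message("simulation failed during objective evaluation: ",
                     conditionMessage(e))
             sqrt(config$penalty)
           })
}

#' Goodness-of-fit report
#'
#' Per dataset and observable: MAPE (percent), normalized RMSE (RMSE over
#' the mean absolute observed value) and, for each BTM series, the
#' excursion-direction concordance. BTM points with near-zero observed
#' change (below `config$btm_exclude`) are excluded from MAPE. The global
#' weighted loss is attached as the `global_loss` attribute.
#'
#' @inheritParams objective
#' @return A tibble with columns `dataset`, `observable`, `n`, `mape`,
#'   `nrmse`, `concordant`.
#' @export
goodness_report <- function(params, collection,
                            config = calibration_config()) {
  hybrids <- collection_hybrids(collection)
  if (length(hybrids) == 0) stop("empty dataset collection", call. = FALSE)
  est <- estrogen_curve_from_params(params)
  anchors <- hybrids[[1]]$aging_anchors

  rows <- list()
  ref_age <- min(anchors$age)
  to_age0 <- max(anchors$age) + 0.5
  from_age0 <- min(config$sim_from_age, ref_age)
  grid0 <- sort(unique(c(seq(from_age0, to_age0, by = config$grid_step),
                         to_age0, anchors$age)))
  sim0 <- simulate_bmd(params, regimen = NULL, estrogen = est,
                       from_age = from_age0, to_age = to_age0,
                       output_ages = grid0, reference_age = ref_age,
                       rtol = config$rtol, atol = config$atol)
  model0 <- stats::approx(sim0$trajectory$age, sim0$trajectory$bmd_relative,
                          xout = anchors$age)$y
  rows[["aging"]] <- tibble::tibble(
    dataset = "aging", observable = "bmd", n = nrow(anchors),
    mape = mape(model0, anchors$bmd_rel),
    nrmse = sqrt(mean((model0 - anchors$bmd_rel)^2)) /
      mean(abs(anchors$bmd_rel)),
    concordant = NA)
  resids <- sqrt(config$weight_bmd) * (model0 - anchors$bmd_rel)

  for (h in hybrids) {
    pred <- simulate_for_dataset(params, h, config, est)
    resids <- c(resids, dataset_residuals(pred, h, config))
    sim_bmd <- pred$bmd_at(h$treatment$age)
    rows[[paste0(h$label, "_bmd")]] <- tibble::tibble(
      dataset = h$label, observable = "bmd", n = nrow(h$treatment),
      mape = mape(sim_bmd, h$treatment$bmd_rel),
      nrmse = sqrt(mean((sim_bmd - h$treatment$bmd_rel)^2)) /
        mean(abs(h$treatment$bmd_rel)),
      concordant = NA)
    if (!is.null(h$btm)) {
      for (mk in unique(h$btm$marker)) {
        b <- h$btm[h$btm$marker == mk, ]
        sim_b <- pred$btm_at(mk, b$age)
        keep <- abs(b$change) >= config$btm_exclude
        rows[[paste0(h$label, "_", mk)]] <- tibble::tibble(
          dataset = h$label, observable = mk, n = nrow(b),
          mape = if (any(keep)) mape(sim_b[keep], b$change[keep]) else
            NA_real_,
          nrmse = sqrt(mean((sim_b - b$change)^2)) /
            max(mean(abs(b$change)), .Machine$double.eps),
          concordant = btm_direction_concordance(sim_b, b$change))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "global_loss") <- sum(resids^2)
  out
}

#' Fit free model parameters to a study collection
#'
#' Bounded least-squares calibration: Levenberg–Marquardt
#' (`minpack.lm::nls.lm`) on the weighted residual vector, with box bounds
#' from the registry, from multiple starting points — the registry's current
#' values plus `n_starts - 1` Latin-hypercube samples of the free-parameter
#' box (seeded; the start set for `k` starts is always the first `k` rows of
#' the same seeded stream, so adding starts can only improve the returned
#' best loss). With zero free parameters the registry is returned unchanged
#' with its goodness report.
#'
#' @param params An `osteo_params` registry; rows with `free = TRUE` (or the
#'   subset named in `free_names`) are fitted.
#' @param collection Hybrid dataset collection (see [objective()]).
#' @param config See [calibration_config()]; `n_starts` and `seed` control
#'   the multi-start.
#' @param free_names Optional character subset of free parameter names to
#'   fit (others stay at their registry values).
#' @return An `osteo_fit` object: list with `params` (fitted registry),
#'   `report` (goodness report of the best fit), `starts` (per-start
#'   diagnostics tibble), `best_loss`, `config`.
#' @export
fit_bone_model <- function(params, collection,
                           config = calibration_config(),
                           free_names = NULL) {
  validate_parameters(params)
  if (is.null(free_names)) free_names <- params$name[params$free]
  stopifnot(all(free_names %in% params$name))

  if (length(free_names) == 0) {
    report <- goodness_report(params, collection, config)
    return(structure(list(params = params, report = report,
                          starts = tibble::tibble(),
                          best_loss = attr(report, "global_loss"),
                          config = config),
                     class = "osteo_fit"))
  }

  idx <- match(free_names, params$name)
  lower <- params$lower[idx]
  upper <- params$upper[idx]
  x0 <- params$value[idx]

  starts <- matrix(x0, nrow = 1)
  if (config$n_starts > 1) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(config$seed)
    u <- lhs::randomLHS(config$n_starts - 1, length(free_names))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    lhs_pts <- sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
    starts <- rbind(starts, lhs_pts)
  }

  ## nls.lm requires a residual vector of constant length: measure it once
  ## and map failed simulations to a constant-length penalty vector
  ref_res <- objective_residuals(stats::setNames(x0, free_names), params,
                                 collection, config)
  ref_len <- length(ref_res)
  resid_fn <- function(v) {
    r <- objective_residuals(stats::setNames(v, free_names), params,
                             collection, config)
    if (length(r) != ref_len || anyNA(r) || any(!is.finite(r))) {
      r <- rep(sqrt(config$penalty / ref_len), ref_len)
    }
    r
  }

  run_start <- function(i) {
    x <- pmin(pmax(starts[i, ], lower), upper)
    fitres <- tryCatch(
      minpack.lm::nls.lm(
        par = x,
        lower = lower, upper = upper,
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = config$maxiter)),
      error = function(e) NULL)
    if (is.null(fitres)) {
      return(list(ok = FALSE, loss = Inf, par = x, info = NA_integer_))
    }
    list(ok = TRUE, loss = fitres$deviance,
         par = stats::setNames(fitres$par, free_names), info = fitres$info)
  }
  results <- lapply(seq_len(nrow(starts)), run_start)

  losses <- vapply(results, function(r) r$loss, numeric(1))
  if (all(!vapply(results, function(r) r$ok, logical(1)))) {
    stop("all optimization starts failed", call. = FALSE)
  }
  best <- results[[which.min(losses)]]
  fitted <- set_param_values(params, best$par)
  report <- goodness_report(fitted, collection, config)
  diag <- tibble::tibble(start = seq_along(results),
                         loss = losses,
                         converged = vapply(results, function(r)
                           isTRUE(r$ok), logical(1)))
  structure(list(params = fitted, report = report, starts = diag,
                 best_loss = best$loss, config = config,
                 free_names = free_names),
            class = "osteo_fit")
}

#' @export
print.osteo_fit <- function(x, ...) {
  cat("<osteo_fit> ", length(x$free_names %||% character()),
      " free parameters, best loss ", format(x$best_loss, digits = 6),
      " over ", max(1L, nrow(x$starts)), " start(s)\n", sep = "")
  invisible(x)
}
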