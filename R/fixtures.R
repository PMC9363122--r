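#' Synthetic clinical-style dataset specification
#'
#' Describes how to generate one synthetic treatment dataset from a known
#' (generating) parameter set: the regimen, the clinic-visit schedule, and
#' an independent additive Gaussian noise model on the relative BMD
#' (default sd 0.004) and on the BTM fractional baseline changes (default
#' sd 0.05). Noise is independent across visits, emulating digitised
#' study-population-average series; with sd 0 the dataset reproduces the
#' model output exactly. All randomness is governed by `seed`.
#'
#' @param params Generating `osteo_params` registry.
#' @param regimen `osteo_regimen` with dose times as ages (years).
#' @param visit_times Visit times in years since treatment start (first
#'   visit 0 = baseline).
#' @param baseline_age_mean Mean baseline age of the notional study
#'   population; defaults to 65, which lies on an aging bin center so the
#'   hybrid merge is interpolation-exact.
#' @param markers Character subset of `c("ctx", "p1np", "bsap")` to report.
#' @param noise_bmd,noise_btm Gaussian noise standard deviations (>= 0).
#' @param n_subjects Notional study size (metadata only).
#' @param label Dataset label.
#' @param seed Integer seed.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(params, regimen, visit_times,
                         baseline_age_mean = 65,
                         markers = c("ctx", "p1np"),
                         noise_bmd = 0.004, noise_btm = 0.05,
                         n_subjects = 25L, label = "synthetic",
                         seed = 1L) {
  stopifnot(noise_bmd >= 0, noise_btm >= 0,
            abs(visit_times[1]) < 1e-9,
            all(markers %in% c("ctx", "p1np", "bsap")))
  structure(list(params = params, regimen = regimen,
                 visit_times = visit_times,
                 baseline_age_mean = baseline_age_mean,
                 markers = markers, noise_bmd = noise_bmd,
                 noise_btm = noise_btm, n_subjects = n_subjects,
                 label = label, seed = seed),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Generate a synthetic aging dataset
#'
#' Simulates the drug-free life course of the generating model and reports
#' mean BMD in the standard 10-year age bins from 20 to "80 and older"
#' (bin-center convention; open-ended top bin treated as 10 years wide),
#' with optional additive Gaussian noise on the bin means.
#'
#' @param params Generating `osteo_params` registry.
#' @param noise_sd Additive Gaussian sd on the (relative-scale) bin means.
#' @param seed Integer seed.
#' @return An `osteo_aging` dataset (synthetic).
#' @export
generate_aging_dataset <- function(params, noise_sd = 0, seed = 1L) {
  centers <- seq(25, 85, by = 10)
  grid <- sort(unique(c(seq(25, 86, by = 0.25), centers)))
  sim <- simulate_bmd(params, from_age = 25, to_age = 86,
                      output_ages = grid, reference_age = 25)
  vals <- stats::approx(sim$trajectory$age, sim$trajectory$bmd,
                        xout = centers)$y
  if (noise_sd > 0) {
    vals <- vals + with_seed(seed, stats::rnorm(length(vals), 0, noise_sd))
  }
  aging_dataset(
    tibble::tibble(low = centers - 5,
                   high = c(centers[-length(centers)] + 5, NA),
                   mean_bmd = vals),
    cohort = "synthetic reference population")
}

#' Generate a synthetic treatment dataset
#'
#' Simulates the generating model under the spec's regimen, samples the
#' clinical observables at the visit schedule, adds the seeded noise, and
#' returns a treatment dataset in the package's dataset dialect (BMD
#' relative to the baseline visit; BTMs as fractional baseline changes).
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional directory: if given, the dataset files are also
#'   written there (see [write_treatment_dataset()]).
#' @param role Metadata role recorded when writing (`"calibration"` or
#'   `"validation"`).
#' @return An `osteo_treatment` (synthetic).
#' @export
generate_dataset <- function(spec, out_dir = NULL, role = "calibration") {
  stopifnot(inherits(spec, "fixture_spec"))
  start_age <- round(spec$baseline_age_mean)
  visit_ages <- start_age + spec$visit_times
  span <- regimen_span(spec$regimen)
  from_age <- min(40, start_age - 1, if (!is.na(span[1])) span[1])
  to_age <- max(visit_ages, if (!is.na(span[2])) span[2]) + 0.5
  grid <- sort(unique(c(seq(from_age, to_age, by = 0.05), to_age,
                        start_age, visit_ages)))
  sim <- simulate_bmd(spec$params, regimen = spec$regimen,
                      from_age = from_age, to_age = to_age,
                      output_ages = grid, reference_age = from_age,
                      baseline_age = start_age)
  tr <- sim$trajectory
  bmd_base <- stats::approx(tr$age, tr$bmd, xout = start_age)$y
  bmd_vals <- stats::approx(tr$age, tr$bmd, xout = visit_ages)$y / bmd_base

  nv <- length(visit_ages)
  noise <- with_seed(spec$seed, list(
    bmd = stats::rnorm(nv, 0, spec$noise_bmd),
    btm = stats::rnorm(nv * length(spec$markers), 0, spec$noise_btm)))
  ## the baseline visit defines the scales; keep it noise-free
  noise$bmd[1] <- 0
  bmd_tbl <- tibble::tibble(time = spec$visit_times,
                            value = bmd_vals + noise$bmd)

  btm_tbl <- NULL
  if (length(spec$markers) > 0) {
    btm_tbl <- purrr::imap_dfr(spec$markers, function(mk, k) {
      col <- paste0(mk, "_change")
      vals <- stats::approx(tr$age, tr[[col]], xout = visit_ages)$y
      eps <- noise$btm[((k - 1) * nv + 1):(k * nv)]
      eps[1] <- 0
      tibble::tibble(marker = mk, time = spec$visit_times,
                     value = vals + eps)
    })
  }

  trt <- treatment_dataset(label = spec$label,
                           baseline_age_mean = spec$baseline_age_mean,
                           bmd = bmd_tbl, btm = btm_tbl,
                           regimen = spec$regimen,
                           n_subjects = spec$n_subjects,
                           btm_normalized = TRUE)
  if (!is.null(out_dir)) write_treatment_dataset(trt, out_dir, role = role)
  trt
}

#' Generate the synthetic study collection
#'
#' The package's reference set of synthetic clinical-style datasets,
#' emulating the kinds of series digitised from published trials: an aging
#' dataset plus four single-drug calibration datasets (denosumab 60 mg
#' every 6 months for 3 years; alendronate 70 mg weekly for 2 years;
#' romosozumab 140 mg monthly for 1 year; teriparatide 20 ug daily for
#' 18 months) and two combination validation datasets (the sequential
#' alendronate -> romosozumab -> denosumab year-blocks, and teriparatide +
#' denosumab in parallel for a year followed by denosumab alone). All
#' treatments start at age 65 (an aging bin center); visits are at typical
#' clinic intervals. These are synthetic stand-ins generated by the model
#' itself, for pipeline testing and parameter-recovery studies.
#'
#' @param params Generating `osteo_params` registry.
#' @param noise Logical: apply the default noise model (BMD sd 0.004, BTM
#'   sd 0.05), or generate noise-free.
#' @param seed Integer base seed (per-dataset seeds derive from it).
#' @param out_dir Optional directory to write all files to.
#' @return List with `aging` (`osteo_aging`), `calibration` and
#'   `validation` (named lists of `osteo_treatment`).
#' @export
generate_study_collection <- function(params, noise = TRUE, seed = 1L,
                                      out_dir = NULL) {
  sd_bmd <- if (noise) 0.004 else 0
  sd_btm <- if (noise) 0.05 else 0
  start <- 65
  blk <- function(drug, dose, every, dur, start_age = start) {
    make_block_regimen(tibble::tibble(drug_id = drug, dose = dose,
                                      interval = every, duration = dur),
                       start_age = start_age)
  }
  cal_specs <- list(
    denosumab_3y = fixture_spec(
      params, blk("denosumab", 60, "6mo", "3yr"),
      visit_times = seq(0, 4.5, by = 0.5), label = "denosumab_3y",
      markers = c("ctx", "p1np"), noise_bmd = sd_bmd, noise_btm = sd_btm,
      seed = seed + 11L),
    alendronate_2y = fixture_spec(
      params, blk("alendronate", 70, "1w", "2yr"),
      visit_times = seq(0, 3, by = 0.5), label = "alendronate_2y",
      markers = c("ctx", "p1np"), noise_bmd = sd_bmd, noise_btm = sd_btm,
      seed = seed + 12L),
    romosozumab_1y = fixture_spec(
      params, blk("romosozumab", 140, "1mo", "1yr"),
      visit_times = seq(0, 2, by = 0.25), label = "romosozumab_1y",
      markers = c("ctx", "p1np"), noise_bmd = sd_bmd, noise_btm = sd_btm,
      seed = seed + 13L),
    teriparatide_18m = fixture_spec(
      params, blk("teriparatide", 0.02, "1d", "18mo"),
      visit_times = seq(0, 2, by = 0.25), label = "teriparatide_18m",
      markers = c("ctx", "p1np", "bsap"), noise_bmd = sd_bmd,
      noise_btm = sd_btm, seed = seed + 14L))

  ard <- make_block_regimen(tibble::tibble(
    drug_id = c("alendronate", "romosozumab", "denosumab"),
    dose = c(70, 140, 60),
    interval = c("1w", "1mo", "6mo"),
    duration = c("1yr", "1yr", "1yr")), start_age = start)
  teri_deno <- make_block_regimen(tibble::tibble(
    drug_id = c("teriparatide", "denosumab", "denosumab"),
    dose = c(0.02, 60, 60),
    interval = c("1d", "6mo", "6mo"),
    duration = c("1yr", "1yr", "1yr"),
    start = c(start, start, start + 1)), start_age = start)
  val_specs <- list(
    seq_ard = fixture_spec(
      params, ard, visit_times = seq(0, 4, by = 0.5), label = "seq_ard",
      markers = c("ctx", "p1np"), noise_bmd = sd_bmd, noise_btm = sd_btm,
      seed = seed + 21L),
    teri_deno_parallel = fixture_spec(
      params, teri_deno, visit_times = seq(0, 3, by = 0.5),
      label = "teri_deno_parallel", markers = c("ctx", "p1np"),
      noise_bmd = sd_bmd, noise_btm = sd_btm, seed = seed + 22L))

  aging <- generate_aging_dataset(params, noise_sd = sd_bmd,
                                  seed = seed + 1L)
  out <- list(
    aging = aging,
    calibration = purrr::map(cal_specs, generate_dataset),
    validation = purrr::map(val_specs, generate_dataset, role = "validation"))
  if (!is.null(out_dir)) {
    write_aging_dataset(aging, out_dir)
    purrr::walk(out$calibration, write_treatment_dataset, dir = out_dir,
                role = "calibration")
    purrr::walk(out$validation, write_treatment_dataset, dir = out_dir,
                role = "validation")
  }
  out
}

#' Build hybrid datasets from a generated collection
#'
#' @param collection Output of [generate_study_collection()].
#' @return List with `calibration` and `validation`: named lists of
#'   `osteo_hybrid`.
#' @export
hybridize_collection <- function(collection) {
  list(calibration = purrr::map(collection$calibration,
                                ~build_hybrid(collection$aging, .x)),
       validation = purrr::map(collection$validation,
                               ~build_hybrid(collection$aging, .x)))
}

#' Parameter-recovery experiment
#'
#' Generates noise-free synthetic data from the supplied registry, perturbs
#' a chosen subset of free parameters, refits them, and reports relative
#' recovery errors. The fit starts at the perturbed values (a local
#' recovery; set `config$n_starts > 1` for a globalized refit).
#'
#' @param params Generating (true) `osteo_params` registry.
#' @param free_names Character vector of free parameter names to perturb
#'   and recover.
#' @param hybrids Optional list of `osteo_hybrid` to fit against; default
#'   is a compact noise-free collection (denosumab + romosozumab datasets).
#' @param perturb Relative perturbation magnitude (uniform in
#'   `[-perturb, perturb]`, seeded).
#' @param config See [calibration_config()].
#' @param seed Seed for the perturbation draw.
#' @return An `osteo_recovery` object: tibble with `name`, `true`, `start`,
#'   `fitted`, `rel_error`, carrying the fit as attribute `fit`.
#' @export
recovery_experiment <- function(params, free_names,
                                hybrids = NULL,
                                perturb = 0.15,
                                config = calibration_config(n_starts = 1),
                                seed = 7L) {
  stopifnot(all(free_names %in% params$name[params$free]))
  if (is.null(hybrids)) {
    blk <- function(drug, dose, every, dur) {
      make_block_regimen(tibble::tibble(drug_id = drug, dose = dose,
                                        interval = every, duration = dur),
                         start_age = 65)
    }
    aging <- generate_aging_dataset(params, noise_sd = 0)
    specs <- list(
      fixture_spec(params, blk("denosumab", 60, "6mo", "2yr"),
                   visit_times = seq(0, 3, by = 0.5), label = "rec_deno",
                   markers = c("ctx", "p1np"), noise_bmd = 0,
                   noise_btm = 0),
      fixture_spec(params, blk("romosozumab", 140, "1mo", "1yr"),
                   visit_times = seq(0, 2, by = 0.5), label = "rec_romo",
                   markers = c("ctx", "p1np"), noise_bmd = 0,
                   noise_btm = 0))
    hybrids <- purrr::map(specs, ~build_hybrid(aging,
                                               generate_dataset(.x)))
  }

  true_vals <- param_value(params, free_names)
  fac <- 1 + with_seed(seed,
                       stats::runif(length(free_names), -perturb, perturb))
  idx <- match(free_names, params$name)
  start_vals <- pmin(pmax(true_vals * fac, params$lower[idx]),
                     params$upper[idx])
  start_params <- set_param_values(params, start_vals)

  fit <- fit_bone_model(start_params, list(calibration = hybrids),
                        config = config, free_names = free_names)
  fitted_vals <- param_value(fit$params, free_names)
  out <- tibble::tibble(name = free_names,
                        true = unname(true_vals),
                        start = unname(start_vals),
                        fitted = unname(fitted_vals),
                        rel_error = abs(fitted_vals - true_vals) /
                          abs(true_vals))
  attr(out, "fit") <- fit
  class(out) <- c("osteo_recovery", class(out))
  out
}
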