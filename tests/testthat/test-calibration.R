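# Small noise-free collection shared by the calibration tests: one short
# denosumab study over a coarse aging curve, cheap enough to re-simulate
# inside optimizer iterations.
local_tiny_collection <- function(params) {
  aging <- generate_aging_dataset(params, noise_sd = 0)
  spec <- fixture_spec(params, deno_regimen("1yr"),
                       visit_times = c(0, 0.5, 1, 1.5),
                       markers = "ctx", noise_bmd = 0, noise_btm = 0,
                       label = "tiny_deno")
  list(calibration = list(
    tiny_deno = build_hybrid(aging, generate_dataset(spec))))
}

test_that("MAPE matches hand computation and is scale invariant", {
  expect_equal(mape(c(1.0, 1.1), c(1.0, 1.0)), 5.0)
  expect_equal(mape(c(0.9, 1.2), c(0.9, 1.2)), 0)
  sim <- c(1.02, 0.97, 1.10)
  obs <- c(1.00, 1.00, 1.00)
  expect_equal(mape(3.7 * sim, 3.7 * obs), mape(sim, obs))
  expect_error(mape(c(1, 1), c(1, 0)), "zero")
  expect_error(mape(1, c(1, 2)))
})

test_that("excursion-direction concordance compares dominant excursions", {
  expect_true(btm_direction_concordance(c(0, -0.5, -0.2), c(0, -0.7, -0.1)))
  expect_false(btm_direction_concordance(c(0, -0.5), c(0, 0.4)))
  expect_true(is.na(btm_direction_concordance(c(0, 0.1), c(0, 0))))
  ## dominant excursion wins even when the series changes sign
  expect_true(btm_direction_concordance(c(0.2, -0.8), c(0.1, -0.9)))
})

test_that("the objective vanishes at the generating parameters and rises nearby", {
  p <- default_parameters()
  coll <- local_tiny_collection(p)
  cfg <- calibration_config()
  free <- "rate_resorption"
  loss0 <- objective(param_value(p, free), p, coll, cfg)
  expect_lt(loss0, 1e-6)
  loss1 <- objective(c(rate_resorption = 0.055 * 1.05), p, coll, cfg)
  expect_gt(loss1, loss0 * 100)
  expect_error(objective(param_value(p, free), p,
                         list(calibration = list()), cfg), "empty")
})

test_that("zero free parameters is a no-op fit with a report", {
  p <- default_parameters()
  coll <- local_tiny_collection(p)
  fit <- fit_bone_model(p, coll, free_names = character(0))
  expect_identical(fit$params$value, p$value)
  expect_s3_class(fit$report, "tbl_df")
  expect_true(all(c("dataset", "mape", "nrmse") %in% names(fit$report)))
  expect_true(all(fit$report$mape[fit$report$observable == "bmd"] < 0.01))
})

test_that("fits are deterministic and improve monotonically with more starts", {
  p <- default_parameters()
  coll <- local_tiny_collection(p)
  start <- set_param_values(p, c(rate_resorption = 0.065))
  cfg1 <- calibration_config(n_starts = 1, maxiter = 2)
  f1a <- suppressWarnings(
    fit_bone_model(start, coll, cfg1, free_names = "rate_resorption"))
  f1b <- suppressWarnings(
    fit_bone_model(start, coll, cfg1, free_names = "rate_resorption"))
  expect_identical(f1a$params$value, f1b$params$value)
  expect_identical(f1a$best_loss, f1b$best_loss)

  cfg2 <- calibration_config(n_starts = 2, maxiter = 2)
  f2 <- suppressWarnings(
    fit_bone_model(start, coll, cfg2, free_names = "rate_resorption"))
  expect_lte(f2$best_loss, f1a$best_loss)
  ## the k-start set is a prefix of the (k+1)-start seeded stream
  expect_equal(f2$starts$loss[1], f1a$starts$loss[1])
})

test_that("fit tidiers expose estimates and fit quality", {
  p <- default_parameters()
  coll <- local_tiny_collection(p)
  fit <- suppressWarnings(
    fit_bone_model(p, coll, calibration_config(n_starts = 1, maxiter = 1),
                   free_names = "rate_resorption"))
  td <- tidy(fit)
  expect_named(td, c("name", "estimate", "lower", "upper"))
  gl <- glance(fit)
  expect_equal(gl$n_free, 1)
  expect_true(gl$max_bmd_mape >= 0)
})
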