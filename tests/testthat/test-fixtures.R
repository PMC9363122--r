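test_that("noise-free generation reproduces the model observables exactly", {
  p <- default_parameters()
  spec <- fixture_spec(p, deno_regimen("1yr"),
                       visit_times = c(0, 0.5, 1), markers = "ctx",
                       noise_bmd = 0, noise_btm = 0, label = "nf")
  trt <- generate_dataset(spec)
  sim <- simulate_bmd(p, regimen = deno_regimen("1yr"), from_age = 40,
                      to_age = 67,
                      output_ages = sort(unique(c(seq(40, 67, 0.5),
                                                  65, 65.5, 66))),
                      baseline_age = 65)
  tr <- sim$trajectory
  base <- tr$bmd[match(65, tr$age)]
  expect_equal(trt$bmd$value,
               tr$bmd[match(c(65, 65.5, 66), tr$age)] / base,
               tolerance = 1e-8)
  expect_equal(trt$btm$value,
               tr$ctx_change[match(c(65, 65.5, 66), tr$age)],
               tolerance = 1e-6)
  expect_equal(trt$bmd$value[1], 1)
})

test_that("generation is reproducible under a fixed seed", {
  p <- default_parameters()
  mk <- function(seed) generate_dataset(
    fixture_spec(p, deno_regimen("1yr"), visit_times = c(0, 0.5, 1),
                 markers = "ctx", seed = seed, label = "seeded"))
  a <- mk(42); b <- mk(42); c3 <- mk(43)
  expect_identical(a$bmd$value, b$bmd$value)
  expect_identical(a$btm$value, b$btm$value)
  expect_false(identical(a$bmd$value, c3$bmd$value))
  ## baseline visit stays noise-free by construction
  expect_equal(a$bmd$value[1], 1)
})

test_that("generated aging and treatment parts merge consistently", {
  p <- default_parameters()
  aging <- generate_aging_dataset(p, noise_sd = 0)
  spec <- fixture_spec(p, deno_regimen("1yr"),
                       visit_times = c(0, 0.5, 1), markers = "ctx",
                       noise_bmd = 0, noise_btm = 0, label = "consist")
  h <- build_hybrid(aging, generate_dataset(spec))
  anchors <- bin_centers(aging)
  expect_equal(h$treatment$bmd_rel[1],
               stats::approx(anchors$age, anchors$bmd_rel, xout = 65)$y)
  ## end to end: the generating parameters reproduce the hybrid data
  loss <- objective(param_value(p, "rate_resorption"), p,
                    list(calibration = list(h)))
  expect_lt(loss, 1e-6)
})

test_that("a single perturbed parameter is recovered from noise-free data", {
  p <- default_parameters()
  rec <- recovery_experiment(p, "rate_resorption", perturb = 0.15)
  expect_lt(rec$rel_error, 1e-3)
  expect_equal(rec$true, 0.055)
  fit <- attr(rec, "fit")
  expect_s3_class(fit, "osteo_fit")
})

test_that("fixture files land in the dataset dialect", {
  dir <- withr::local_tempdir()
  p <- default_parameters()
  spec <- fixture_spec(p, deno_regimen("1yr"), visit_times = c(0, 1),
                       markers = "ctx", label = "disk")
  generate_dataset(spec, out_dir = dir)
  expect_true(file.exists(file.path(dir, "disk_bmd.csv")))
  expect_true(file.exists(file.path(dir, "disk.json")))
  back <- read_treatment_dataset(dir, "disk")
  expect_equal(back$baseline_age_mean, 65)
  expect_equal(nrow(back$bmd), 2)
})
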