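test_that("the homeostatic trajectory is invariant over 50 years", {
  p <- default_parameters()
  sim <- simulate_bmd(p, estrogen = 1, from_age = 25, to_age = 75,
                      grid_step = 1)
  tr <- sim$trajectory
  for (col in c("pre_oc", "oc", "pre_ob", "ob", "ocy", "scl", "rho", "mc")) {
    expect_lt(max(abs(tr[[col]] - 1)), 1e-3)
  }
})

test_that("an empty regimen equals a zero-length block list bitwise", {
  p <- default_parameters()
  s1 <- simulate_bmd(p, regimen = NULL, from_age = 60, to_age = 65,
                     grid_step = 0.5)
  s2 <- simulate_bmd(p, regimen = make_block_regimen(list()),
                     from_age = 60, to_age = 65, grid_step = 0.5)
  expect_identical(s1$trajectory, s2$trajectory)
})

test_that("identical inputs give identical trajectories", {
  p <- default_parameters()
  reg <- deno_regimen("1yr")
  s1 <- simulate_bmd(p, regimen = reg, from_age = 60, to_age = 67,
                     grid_step = 0.25)
  s2 <- simulate_bmd(p, regimen = reg, from_age = 60, to_age = 67,
                     grid_step = 0.25)
  expect_identical(s1$trajectory, s2$trajectory)
})

test_that("halving the output grid leaves interpolated observables unchanged", {
  p <- default_parameters()
  reg <- deno_regimen("1yr")
  coarse <- simulate_bmd(p, regimen = reg, from_age = 60, to_age = 67,
                         grid_step = 0.2)
  fine <- simulate_bmd(p, regimen = reg, from_age = 60, to_age = 67,
                       grid_step = 0.1)
  shared <- intersect(round(coarse$trajectory$age, 10),
                      round(fine$trajectory$age, 10))
  i1 <- match(shared, round(coarse$trajectory$age, 10))
  i2 <- match(shared, round(fine$trajectory$age, 10))
  expect_lt(max(abs(coarse$trajectory$bmd_relative[i1] -
                      fine$trajectory$bmd_relative[i2])), 1e-6)
})

test_that("BMD is the product of bone density and mineral content", {
  p <- default_parameters()
  sim <- simulate_bmd(p, regimen = deno_regimen("1yr"), from_age = 60,
                      to_age = 67, grid_step = 0.25)
  tr <- sim$trajectory
  expect_equal(tr$bmd, tr$rho * tr$mc)
  expect_equal(bmd(bone_state(rho = 0.9, mc = 1.0)), 0.9)
  expect_equal(bmd(bone_state(rho = 1.8, mc = 2.0)),
               4 * bmd(bone_state(rho = 0.9, mc = 1.0)))
  rel <- bmd_relative(sim, reference_age = 62)
  expect_equal(rel$bmd_relative[match(62, rel$age)], 1)
  expect_error(bmd_relative(sim, reference_age = 10), "outside")
})

test_that("markers move in the drug's direction of action", {
  p <- default_parameters()
  deno <- simulate_bmd(p, regimen = deno_regimen("2yr"), from_age = 60,
                       to_age = 68, grid_step = 0.1)
  ## the dominant CTX excursion under a RANKL antibody is suppression
  ## (partial recovery near the end of each 6-month dosing interval is
  ## expected and clinically documented)
  during <- deno$trajectory$age > 65 & deno$trajectory$age < 67
  ctx <- deno$trajectory$ctx_change[during]
  expect_lt(min(ctx), -0.5)
  expect_gt(abs(min(ctx)), abs(max(ctx)))

  teri <- simulate_bmd(
    p, regimen = make_block_regimen(
      tibble::tibble(drug_id = "teriparatide", dose = 0.02,
                     interval = "1d", duration = "1yr"), start_age = 65),
    from_age = 60, to_age = 66.5, grid_step = 0.1)
  during <- teri$trajectory$age > 65.2 & teri$trajectory$age < 66
  expect_true(all(teri$trajectory$p1np_change[during] > 0))

  ## baseline: all markers are zero change at an unperturbed steady state
  flat <- simulate_bmd(p, estrogen = 1, from_age = 25, to_age = 30,
                       grid_step = 0.5)
  expect_lt(max(abs(flat$trajectory$ctx_change)), 1e-6)
  expect_lt(max(abs(flat$trajectory$p1np_change)), 1e-6)
})

test_that("denosumab cessation produces precursor build-up then rebound", {
  p <- default_parameters()
  sim <- simulate_bmd(p, regimen = deno_regimen("3yr"), from_age = 55,
                      to_age = 71, grid_step = 0.02)
  tr <- sim$trajectory
  pre_treat_oc <- tr$oc[max(which(tr$age <= 65))]
  during <- tr$age >= 65 & tr$age <= 68
  post2y <- tr$age > 68 & tr$age <= 70
  ## precursor pool accumulates above its homeostatic level under blockade
  expect_gt(max(tr$pre_oc[during]), 1.5)
  ## osteoclasts overshoot their pre-treatment level within two years
  expect_gt(max(tr$oc[post2y]), pre_treat_oc)
})

test_that("dose events outside the age span are refused", {
  p <- default_parameters()
  expect_error(simulate_bmd(p, regimen = deno_regimen("1yr"),
                            from_age = 66, to_age = 70), "cover")
})

test_that("trajectories and metadata round trip to disk", {
  p <- default_parameters()
  sim <- simulate_bmd(p, from_age = 60, to_age = 62, grid_step = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(sim, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$bmd_relative, sim$trajectory$bmd_relative)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$rtol, sim$rtol)
})
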