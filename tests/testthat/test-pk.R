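test_that("undosed pharmacokinetics stay at zero", {
  pars <- derived_parameters(default_parameters())
  d <- pk_derivatives(pk_zero_state(), pars)
  expect_equal(unname(d), rep(0, 11))
  expect_error(pk_derivatives(pk_zero_state() - 1, pars), "nonnegative")
})

test_that("a single bolus follows the closed-form two-exponential curve", {
  p <- default_parameters()
  reg <- make_block_regimen(
    tibble::tibble(drug_id = "romosozumab", dose = 140, interval = "1yr",
                   duration = "1yr"), start_age = 60)
  sim <- simulate_bmd(p, regimen = reg, from_age = 59.5, to_age = 61,
                      output_ages = seq(60, 61, by = 0.01),
                      rtol = 1e-11, atol = 1e-14)
  pars <- derived_parameters(p)
  analytic <- bateman_central(sim$drug_levels$age - 60, 140,
                              pars[["romo_ka"]], pars[["romo_ke"]])
  err <- max(abs(sim$drug_levels$central_romo - analytic)) / max(analytic)
  expect_lt(err, 1e-8)
})

test_that("dose sequences superpose linearly", {
  p <- default_parameters()
  pars <- derived_parameters(p)
  reg2 <- make_block_regimen(
    tibble::tibble(drug_id = "denosumab", dose = 60, interval = "6mo",
                   duration = "1yr"), start_age = 60)
  sim <- simulate_bmd(p, regimen = reg2, from_age = 59.5, to_age = 61.5,
                      output_ages = seq(60, 61.5, by = 0.01),
                      rtol = 1e-11, atol = 1e-14)
  t <- sim$drug_levels$age
  analytic <- bateman_central(t - 60, 60, pars[["dmab_ka"]],
                              pars[["dmab_ke"]]) +
    bateman_central(t - 60.5, 60, pars[["dmab_ka"]], pars[["dmab_ke"]])
  err <- max(abs(sim$drug_levels$central_dmab - analytic)) / max(analytic)
  expect_lt(err, 1e-8)
})

test_that("effect multipliers are neutral at zero, half-way at EC50, and bounded", {
  p <- default_parameters()
  pars <- derived_parameters(p)
  expect_equal(unname(unlist(drug_effects(pk_zero_state(), pars))),
               rep(1, 6))

  at_ec50 <- pk_zero_state()
  at_ec50[["central_dmab"]] <- pars[["dmab_ec50"]]
  eff <- drug_effects(at_ec50, pars)
  expect_equal(eff$diff_poc, 1 - pars[["dmab_emax"]] / 2)

  sat <- pk_zero_state()
  sat[["central_dmab"]] <- 1e9
  sat[["central_teri"]] <- 1e9
  sat[["bone_aln"]] <- 1e9
  eff <- drug_effects(sat, pars)
  expect_equal(eff$diff_poc, 1 - pars[["dmab_emax"]], tolerance = 1e-6)
  expect_equal(eff$recruit_ob, 1 + pars[["teri_emax"]], tolerance = 1e-6)
  expect_equal(eff$apop_oc, 1 + pars[["aln_emax_apop"]], tolerance = 1e-6)

  ## bounds hold for arbitrary nonnegative states
  set.seed(3)
  for (i in 1:200) {
    s <- pk_zero_state()
    s[] <- stats::rexp(11, rate = 1 / 50)
    e <- drug_effects(s, pars)
    expect_true(e$diff_poc > 0 && e$diff_poc <= 1)
    expect_true(e$scl_free > 0 && e$scl_free <= 1)
    expect_true(e$resorption > 0 && e$resorption <= 1)
    expect_true(e$apop_oc >= 1 && e$apop_oc <= 1 + pars[["aln_emax_apop"]])
    expect_true(e$recruit_ob >= 1 &&
                  e$recruit_ob <= 1 + pars[["teri_emax"]])
    expect_true(e$mc_target >= 1)
  }
})

test_that("short-term CTX suppression is monotone in denosumab dose", {
  p <- default_parameters()
  ctx_at_3mo <- vapply(c(15, 30, 60, 120), function(dose) {
    reg <- make_block_regimen(
      tibble::tibble(drug_id = "denosumab", dose = dose, interval = "1yr",
                     duration = "1yr"), start_age = 65)
    sim <- simulate_bmd(p, regimen = reg, from_age = 60, to_age = 65.5,
                        output_ages = c(65, 65.25, 65.5))
    sim$trajectory$ctx_change[2]
  }, numeric(1))
  expect_true(all(diff(ctx_at_3mo) < 0))
})
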