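test_that("the nondimensionalized reference state is an exact fixed point", {
  p <- default_parameters()
  d <- bone_rhs(bone_state(), params = p)
  expect_lt(max(abs(d)), 1e-9)
  st <- steady_state(p, estrogen = 1)
  expect_equal(unname(st), rep(1, 8))
})

test_that("boundary states cannot be driven negative", {
  set.seed(21)
  p <- default_parameters()
  free <- p$name[p$free]
  for (i in 1:25) {
    idx <- match(free, p$name)
    vals <- stats::runif(length(free), p$lower[idx], p$upper[idx])
    names(vals) <- free
    ## keep the osteoblast exit-rate constraint satisfiable
    vals["diff_ob_ocy"] <- min(vals[["diff_ob_ocy"]],
                               0.9 * vals[["diff_pob"]])
    pr <- set_param_values(p, vals)
    st <- bone_state()
    zero_field <- sample(bone_state_names()[1:6], 1)
    st[zero_field] <- 0
    d <- bone_rhs(st, params = pr,
                  estrogen = stats::runif(1, 0.1, 1))
    expect_gte(d[[zero_field]], 0)
  }
})

test_that("the resorption signal is proportional to osteoclast activity", {
  p <- default_parameters()
  st <- bone_state()
  expect_equal(resorption_signal(st, p), 1)
  st0 <- bone_state(oc = 0)
  expect_equal(resorption_signal(st0, p), 0)
  st2 <- bone_state(oc = 2)
  expect_equal(resorption_signal(st2, p),
               2 * resorption_signal(st, p))
  expect_error(bone_rhs(c(bone_state()[-1], pre_oc = -0.1), params = p),
               "nonnegative")
})

test_that("sclerostin antibody activity raises net bone density gain", {
  p <- default_parameters()
  pars <- derived_parameters(p)
  eff_on <- neutral_drug_effects()
  eff_on$scl_free <- 0.3
  d_off <- bone_rhs(bone_state(), params = p)
  d_on <- bone_rhs(bone_state(), params = p, effects = eff_on)
  expect_gt(d_on[["rho"]], d_off[["rho"]])
})

test_that("estrogen withdrawal shifts the fixed point toward resorption", {
  p <- default_parameters()
  st_pre <- steady_state(p, estrogen = 1)
  st_post <- steady_state(p, estrogen = 0.1)
  expect_lt(max(abs(bone_rhs(st_post, params = p, estrogen = 0.1))), 1e-10)
  expect_gt(st_post[["oc"]] / st_post[["ob"]],
            st_pre[["oc"]] / st_pre[["ob"]])
  expect_lt(st_post[["rho"]], 1)
})

test_that("turnover fluxes balance at homeostasis", {
  p <- default_parameters()
  fl <- turnover_fluxes(bone_state(), p)
  expect_equal(fl[["resorption"]], fl[["formation"]])
  expect_equal(fl[["resorption"]],
               unname(param_value(p, "rate_resorption")))
})
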