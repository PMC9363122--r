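#' Physiological state of the representative bone remodeling unit
#'
#' Constructs the named state vector of the model's eight dynamic
#' components. Cell pools and sclerostin are dimensionless, normalized so
#' the premenopausal drug-free homeostatic value of each is 1; `rho` (bone
#' density) is a fraction of the young-adult reference and `mc` (bone
#' mineral content) a fraction of its unperturbed steady state. Bone mineral
#' density is the product `rho * mc` (see [bmd()]).
#'
#' @param pre_oc,oc Pre-osteoclast and osteoclast densities.
#' @param pre_ob,ob Pre-osteoblast and osteoblast densities.
#' @param ocy Osteocyte density.
#' @param scl Sclerostin concentration.
#' @param rho Bone density.
#' @param mc Bone mineral content.
#' @return Named numeric vector of length 8.
#' @export
bone_state <- function(pre_oc = 1, oc = 1, pre_ob = 1, ob = 1, ocy = 1,
                       scl = 1, rho = 1, mc = 1) {
  out <- c(pre_oc = pre_oc, oc = oc, pre_ob = pre_ob, ob = ob, ocy = ocy,
           scl = scl, rho = rho, mc = mc)
  if (any(out < 0)) stop("state components must be nonnegative",
                         call. = FALSE)
  out
}

bone_state_names <- function() {
  c("pre_oc", "oc", "pre_ob", "ob", "ocy", "scl", "rho", "mc")
}

## Regulatory multipliers evaluated at a state. s_eff is the free sclerostin
## seen by regulation (total sclerostin times the antibody multiplier).
regulatory_multipliers <- function(state, estrogen, effects, pars) {
  s_eff <- state[["scl"]] * effects$scl_free
  phi_r <- reg_act(s_eff, pars[["K_scl_res"]], pars[["n_scl_res"]],
                   pars[["amp_scl_res"]]) * effects$resorption
  rs <- phi_r * state[["oc"]] * state[["rho"]]
  list(
    s_eff = s_eff,
    ## pre-osteoclast -> osteoclast differentiation (sclerostin up,
    ## RANKL-antibody down)
    diff_poc = reg_act(s_eff, pars[["K_scl_oc"]], pars[["n_scl_oc"]],
                       pars[["amp_scl_oc"]]) * effects$diff_poc,
    ## osteoclast apoptosis (estrogen up, bisphosphonate up)
    apop_oc = reg_act(estrogen, pars[["K_est_apop"]], pars[["n_est_apop"]],
                      pars[["amp_est_apop"]]) * effects$apop_oc,
    ## pre-osteoblast -> osteoblast differentiation (sclerostin down,
    ## resorption signal up, PTH analog up)
    diff_pob = reg_rep(s_eff, pars[["K_scl_ob"]], pars[["n_scl_ob"]],
                       pars[["amp_scl_ob"]]) *
               reg_act(rs, pars[["K_rs_ob"]], pars[["n_rs_ob"]],
                       pars[["amp_rs_ob"]]) * effects$recruit_ob,
    ## sclerostin secretion (estrogen down)
    secr_scl = reg_rep(estrogen, pars[["K_est_scl"]], pars[["n_est_scl"]],
                       pars[["amp_est_scl"]]),
    ## bone formation rate (sclerostin down)
    form = reg_rep(s_eff, pars[["K_scl_form"]], pars[["n_scl_form"]],
                   pars[["amp_scl_form"]]),
    ## bone resorption rate (sclerostin up, bisphosphonate down)
    res = phi_r,
    resorption_signal = rs
  )
}

#' Quasi-steady resorption signal
#'
#' The bone-matrix-derived signaling factor released in proportion to the
#' instantaneous bone resorption rate. It is algebraic (fast-equilibrating),
#' normalized to 1 at the homeostatic reference: the osteoclast-proportional
#' resorption flux relative to its homeostatic value. Zero when there are no
#' osteoclasts; linear in the osteoclast density at fixed bone density.
#'
#' @param state Named state vector from [bone_state()].
#' @param params An `osteo_params` registry (or the list from
#'   [derived_parameters()]).
#' @param estrogen Relative estrogen level.
#' @param effects Drug effect multipliers, see [drug_effects()].
#' @return Nonnegative scalar.
#' @export
resorption_signal <- function(state, params, estrogen = 1,
                              effects = neutral_drug_effects()) {
  pars <- as_par_list(params)
  regulatory_multipliers(state, estrogen, effects, pars)$resorption_signal
}

as_par_list <- function(params) {
  if (is.data.frame(params)) derived_parameters(params) else params
}

#' Model right-hand side (physiological components)
#'
#' Time derivatives (per year) of the eight-component bone state under given
#' regulatory inputs: constant progenitor sources with differentiation and
#' apoptosis, regulated maturation of osteoclasts and osteoblasts,
#' osteocyte formation from osteoblasts, sclerostin secretion by osteocytes
#' with first-order clearance, bone density gain proportional to osteoblasts
#' and loss proportional to osteoclasts, and first-order relaxation of the
#' bone mineral content toward its (drug-shiftable) target. At the all-ones
#' premenopausal reference with estrogen 1 and no drugs the derivative is
#' the zero vector by construction of the nondimensionalization.
#'
#' @inheritParams resorption_signal
#' @param age Age in years (enters only through time-dependent inputs the
#'   caller supplies; kept for interface symmetry).
#' @return Named numeric derivative vector over the 8 state components.
#' @export
bone_rhs <- function(state, age = NA_real_, params = default_parameters(),
                     estrogen = 1, effects = neutral_drug_effects()) {
  if (any(state[bone_state_names()] < 0)) {
    stop("state components must be nonnegative", call. = FALSE)
  }
  pars <- as_par_list(params)
  core_rhs(state, estrogen, effects, pars)
}

## Internal fast path: pars is the derived named vector.
core_rhs <- function(state, estrogen, effects, pars) {
  m <- regulatory_multipliers(state, estrogen, effects, pars)
  u <- state[["pre_oc"]]; cc <- state[["oc"]]
  v <- state[["pre_ob"]]; b <- state[["ob"]]
  y <- state[["ocy"]]; s <- state[["scl"]]
  rho <- state[["rho"]]; mcn <- state[["mc"]]

  diff_uc <- pars[["diff_poc"]] * m$diff_poc * u
  diff_vb <- pars[["diff_pob"]] * m$diff_pob * v

  c(pre_oc = pars[["src_poc"]] - diff_uc - pars[["apop_poc"]] * u,
    oc = diff_uc - pars[["apop_oc"]] * m$apop_oc * cc,
    pre_ob = pars[["src_pob"]] - diff_vb - pars[["apop_pob"]] * v,
    ob = diff_vb - pars[["diff_ob_ocy"]] * b - pars[["apop_ob"]] * b,
    ocy = pars[["diff_ob_ocy"]] * b - pars[["apop_ocy"]] * y,
    scl = pars[["secr_scl"]] * m$secr_scl * y - pars[["clear_scl"]] * s,
    rho = pars[["rate_formation"]] * m$form * b -
          pars[["rate_resorption"]] * m$res * cc * rho,
    mc = pars[["rate_mineralization"]] * (effects$mc_target - mcn))
}

#' Instantaneous bone resorption and formation rates
#'
#' The fluxes that gain and lose bone density, used for the bone turnover
#' markers: resorption flux `rate_resorption * res_mult * oc * rho` and
#' formation flux `rate_formation * form_mult * ob` (units of bone density
#' fraction per year). Both equal the homeostatic turnover rate constant at
#' the reference state.
#'
#' @inheritParams resorption_signal
#' @return Named numeric vector `c(resorption, formation)`.
#' @export
turnover_fluxes <- function(state, params, estrogen = 1,
                            effects = neutral_drug_effects()) {
  pars <- as_par_list(params)
  m <- regulatory_multipliers(state, estrogen, effects, pars)
  c(resorption = pars[["rate_resorption"]] * m$res * state[["oc"]] *
      state[["rho"]],
    formation = pars[["rate_formation"]] * m$form * state[["ob"]])
}

#' Homeostatic steady state at a given estrogen level
#'
#' Solves the drug-free fixed point of the physiological system. At
#' estrogen 1 the nondimensionalization makes the solution the all-ones
#' state exactly; at other estrogen levels a damped least-squares root solve
#' (Levenberg–Marquardt on the right-hand side residuals) is started from
#' the all-ones state. The solve fails loudly, with the residual norm, if
#' the fixed-point residual cannot be pushed below `tol`.
#'
#' @param params An `osteo_params` registry.
#' @param estrogen Relative estrogen level, > 0.
#' @param tol Maximum-norm residual tolerance (per year).
#' @return A [bone_state()] vector with `max(abs(bone_rhs(.))) < tol`.
#' @export
steady_state <- function(params, estrogen = 1, tol = 1e-10) {
  stopifnot(estrogen > 0)
  pars <- as_par_list(params)
  eff <- neutral_drug_effects()
  nm <- bone_state_names()
  resid_fn <- function(x) {
    unname(core_rhs(stats::setNames(x, nm), estrogen, eff, pars))
  }
  ## damped Newton with central-difference Jacobian, started at the
  ## homeostatic all-ones state (exact solution when estrogen = 1)
  x <- rep(1, 8)
  f <- resid_fn(x)
  for (iter in seq_len(200)) {
    if (max(abs(f)) < tol) break
    J <- matrix(0, 8, 8)
    h <- pmax(1e-7 * abs(x), 1e-9)
    for (j in 1:8) {
      xp <- x; xp[j] <- x[j] + h[j]
      xm <- x; xm[j] <- max(x[j] - h[j], 0)
      J[, j] <- (resid_fn(xp) - resid_fn(xm)) / (xp[j] - xm[j])
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) {
      stop("steady-state solve failed: singular Jacobian", call. = FALSE)
    }
    lambda <- 1
    repeat {
      x_new <- pmax(x + lambda * step, 1e-12)
      f_new <- resid_fn(x_new)
      if (sum(f_new^2) < sum(f^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- x_new
    f <- f_new
  }
  if (max(abs(f)) >= tol) {
    stop(sprintf(
      "steady-state solve did not converge: max |rhs| = %.3e (tol %.1e)",
      max(abs(f)), tol), call. = FALSE)
  }
  stats::setNames(x, nm)
}
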