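# Independent oracles used across tests.

# Closed-form central amount after a single bolus into the depot at t = 0:
# first-order absorption ka, first-order elimination ke (Bateman solution
# of the linear two-compartment chain).
bateman_central <- function(t, dose, ka, ke) {
  ifelse(t < 0, 0, dose * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t)))
}

# Brute-force fixed-step classical Runge-Kutta integration of the full
# coupled system (8 physiological + 11 PK states), segmenting exactly at
# dose events and at every requested output time. Independent of the
# adaptive solver used by simulate_bmd(); shares only the model's exported
# derivative functions.
rk4_reference <- function(params, init, from_age, to_age, h,
                          regimen = empty_regimen(),
                          estrogen = estrogen_curve_from_params(params),
                          output_ages) {
  pars <- derived_parameters(params)
  est <- function(a) estrogen_level(estrogen, a)
  core_nm <- names(init)
  pk_nm <- pk_state_names()
  y <- c(init, pk_zero_state())
  n_core <- length(core_nm)

  f <- function(t, y) {
    st <- stats::setNames(pmax(y[1:n_core], 0), core_nm)
    pk <- stats::setNames(pmax(y[(n_core + 1):length(y)], 0), pk_nm)
    eff <- drug_effects(pk, pars)
    c(bone_rhs(st, age = t, params = pars, estrogen = est(t),
               effects = eff),
      pk_derivatives(pk, pars))
  }

  dose_times <- sort(unique(regimen$time))
  stops <- sort(unique(c(from_age, to_age, dose_times, output_ages)))
  out <- matrix(NA_real_, nrow = length(output_ages),
                ncol = length(y), dimnames = list(NULL, names(y)))
  record <- function(t, y) {
    hit <- which(abs(output_ages - t) < 1e-12)
    if (length(hit)) out[hit, ] <<- rep(y, each = length(hit))
  }
  record(stops[1], y)
  for (k in seq_len(length(stops) - 1)) {
    t0 <- stops[k]; t1 <- stops[k + 1]
    ## apply boluses scheduled at the segment start
    if (any(abs(dose_times - t0) < 1e-12)) {
      ev <- regimen[abs(regimen$time - t0) < 1e-12, ]
      for (i in seq_len(nrow(ev))) {
        d <- osteosim:::dose_to_depot(ev$drug_id[i], ev$dose[i], pars)
        y[[d$var]] <- y[[d$var]] + d$amount
      }
    }
    n_steps <- max(1L, ceiling((t1 - t0) / h))
    hh <- (t1 - t0) / n_steps
    t <- t0
    for (s in seq_len(n_steps)) {
      k1 <- f(t, y)
      k2 <- f(t + hh / 2, y + hh / 2 * k1)
      k3 <- f(t + hh / 2, y + hh / 2 * k2)
      k4 <- f(t + hh, y + hh * k3)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t0 + s * hh
    }
    record(t1, y)
  }
  out
}

# A short clinic-style denosumab regimen reused by several tests.
deno_regimen <- function(duration = "2yr", start_age = 65) {
  make_block_regimen(
    tibble::tibble(drug_id = "denosumab", dose = 60, interval = "6mo",
                   duration = duration),
    start_age = start_age)
}
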