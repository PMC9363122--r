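## Pharmacokinetics and pharmacodynamics of the five modeled drugs.
##
## Each drug has a linear two-compartment chain: subcutaneous/oral depot ->
## central (first-order absorption ka), central -> elimination (first-order
## ke). Alendronate additionally exchanges central <-> bone-bound matrix
## (binding aln_kbone, slow release aln_krel), which carries its long
## skeletal retention; its oral dose enters the depot scaled by the
## bioavailability fraction. Doses are instantaneous boluses into the depot.

drug_short <- c(denosumab = "dmab", romosozumab = "romo", blosozumab = "blos",
                teriparatide = "teri", alendronate = "aln")

#' Names of the pharmacokinetic state variables
#'
#' Depot and central amounts (mg) for each drug, plus the bone-bound
#' alendronate amount. This fixed layout is appended to the physiological
#' state vector during integration.
#'
#' @return Character vector of state names.
#' @export
pk_state_names <- function() {
  c(as.vector(rbind(paste0("depot_", drug_short),
                    paste0("central_", drug_short))),
    "bone_aln")
}

#' Zero pharmacokinetic state
#' @return Named numeric vector of zeros over [pk_state_names()].
#' @export
pk_zero_state <- function() {
  stats::setNames(numeric(length(pk_state_names())), pk_state_names())
}

#' Pharmacokinetic right-hand side
#'
#' Time derivatives (mg/yr) of all drug compartments: first-order absorption
#' depot to central, first-order elimination from central, and for
#' alendronate central/bone-matrix exchange with slow release. Dose events
#' are impulses handled by the integrator, not part of this smooth field.
#'
#' @param pk_state Named numeric vector over [pk_state_names()], amounts in
#'   mg, all nonnegative.
#' @param pars Full parameter list from [derived_parameters()] (a named
#'   numeric vector also works).
#' @return Named numeric vector of derivatives in the same layout.
#' @export
pk_derivatives <- function(pk_state, pars) {
  if (any(pk_state < 0)) {
    stop("drug amounts must be nonnegative", call. = FALSE)
  }
  ## layout: depot/central pairs in drug order, bone_aln last
  dep_idx <- c(1L, 3L, 5L, 7L, 9L)
  cen_idx <- dep_idx + 1L
  ka <- c(pars[["dmab_ka"]], pars[["romo_ka"]], pars[["blos_ka"]],
          pars[["teri_ka"]], pars[["aln_ka"]])
  ke <- c(pars[["dmab_ke"]], pars[["romo_ke"]], pars[["blos_ke"]],
          pars[["teri_ke"]], pars[["aln_ke"]])
  absorb <- ka * pk_state[dep_idx]
  d <- numeric(11L)
  d[dep_idx] <- -absorb
  d[cen_idx] <- absorb - ke * pk_state[cen_idx]
  ## alendronate skeletal binding and slow release
  bind <- pars[["aln_kbone"]] * pk_state[[10L]]
  rel <- pars[["aln_krel"]] * pk_state[[11L]]
  d[10L] <- d[10L] - bind + rel
  d[11L] <- bind - rel
  stats::setNames(d, names(pk_state))
}

## Dose impulse: amount entering the depot for one administered dose (mg).
## Oral alendronate is scaled by its bioavailability fraction.
dose_to_depot <- function(drug_id, dose, pars) {
  check_drug_id(drug_id)
  f <- if (drug_id == "alendronate") pars[["aln_bioavail"]] else 1
  list(var = paste0("depot_", drug_short[[drug_id]]), amount = dose * f)
}

#' Drug effect multipliers
#'
#' Maps the current drug amounts to the neutral-at-1 effect multipliers that
#' enter the model's regulatory terms, each a saturating Emax/Hill response:
#' \describe{
#'   \item{diff_poc}{denosumab (RANKL antibody) inhibition of
#'     pre-osteoclast differentiation, `1 - emax * hill_up(C)`, in (0, 1].}
#'   \item{scl_free}{fraction of sclerostin left free by the sclerostin
#'     antibodies (romosozumab, blosozumab; multiplicative across both).}
#'   \item{apop_oc}{alendronate enhancement of osteoclast apoptosis,
#'     `1 + emax * hill_up(bone-bound)`, >= 1.}
#'   \item{resorption}{alendronate reduction of resorption efficiency,
#'     `1 - emax * hill_up(bone-bound)`, in (0, 1].}
#'   \item{recruit_ob}{teriparatide (anabolic PTH analog) enhancement of
#'     osteoblast recruitment, `1 + emax * hill_up(C)`, >= 1.}
#'   \item{mc_target}{target bone mineral content, 1 plus antiresorptive
#'     upshifts (denosumab, alendronate).}
#' }
#' At zero drug every multiplier equals 1; at the EC50 a target shows its
#' half-maximal deviation from 1; at saturating amounts the multiplier pins
#' at the class's maximal-effect bound.
#'
#' @param pk_state Named numeric PK state over [pk_state_names()].
#' @param pars Full parameter list from [derived_parameters()].
#' @return Named list of multipliers.
#' @export
drug_effects <- function(pk_state, pars) {
  C_dmab <- pk_state[["central_dmab"]]
  C_romo <- pk_state[["central_romo"]]
  C_blos <- pk_state[["central_blos"]]
  C_teri <- pk_state[["central_teri"]]
  A_bone <- pk_state[["bone_aln"]]

  h_dmab <- hill_up(C_dmab, pars[["dmab_ec50"]], pars[["dmab_n"]])
  h_romo <- hill_up(C_romo, pars[["sclab_ec50"]], pars[["sclab_n"]])
  h_blos <- hill_up(C_blos, pars[["sclab_ec50"]], pars[["sclab_n"]])
  h_teri <- hill_up(C_teri, pars[["teri_ec50"]], pars[["teri_n"]])
  h_aln <- hill_up(A_bone, pars[["aln_ec50"]], pars[["aln_n"]])

  list(
    diff_poc = 1 - pars[["dmab_emax"]] * h_dmab,
    scl_free = (1 - pars[["sclab_emax"]] * h_romo) *
               (1 - pars[["sclab_emax"]] * h_blos),
    apop_oc = 1 + pars[["aln_emax_apop"]] * h_aln,
    resorption = 1 - pars[["aln_emax_res"]] * h_aln,
    recruit_ob = 1 + pars[["teri_emax"]] * h_teri,
    mc_target = 1 + pars[["mc_shift_dmab"]] * h_dmab +
                    pars[["mc_shift_aln"]] * h_aln
  )
}

neutral_drug_effects <- function() {
  list(diff_poc = 1, scl_free = 1, apop_oc = 1, resorption = 1,
       recruit_ob = 1, mc_target = 1)
}
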