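#' Reference model parameter registry
#'
#' Returns the reference configuration of the bone-remodeling model as a
#' tibble registry: one row per named parameter with its value, a `free`
#' flag (whether the parameter participates in calibration), box bounds,
#' unit, group and a one-line description. The reference configuration
#' exposes exactly 31 free parameters: 8 core rate constants, 2 (threshold,
#' amplitude) per regulatory coupling for the 7 estrogen / sclerostin /
#' resorption-signal couplings, and 9 drug pharmacodynamic constants.
#'
#' All cell pools and the sclerostin concentration are nondimensionalized so
#' the premenopausal, drug-free homeostatic state is exactly 1; source and
#' clearance constants that are pinned by the fixed-point conditions are not
#' free rows here but are derived by [derived_parameters()]:
#' \describe{
#'   \item{src_poc}{pre-osteoclast formation = diff_poc + apop_poc}
#'   \item{apop_oc}{osteoclast apoptosis = diff_poc}
#'   \item{src_pob}{pre-osteoblast formation = diff_pob + apop_pob}
#'   \item{apop_ob}{osteoblast apoptosis = diff_pob - diff_ob_ocy}
#'   \item{apop_ocy}{osteocyte apoptosis = diff_ob_ocy}
#'   \item{secr_scl}{sclerostin secretion = clear_scl}
#'   \item{rate_formation}{bone formation rate constant = rate_resorption}
#' }
#'
#' Hill exponents of the regulatory couplings and all pharmacokinetic
#' constants are present in the registry flagged fixed. Defaults are the
#' package's reference parameter set (design targets are documented in the
#' methods vignette); units are per-year or dimensionless unless stated.
#'
#' @return A tibble of class `osteo_params` with columns `name`, `value`,
#'   `free`, `lower`, `upper`, `unit`, `group`, `description`.
#' @examples
#' p <- default_parameters()
#' sum(p$free) # 31
#' @export
default_parameters <- function() {
  row <- function(name, value, free, lower, upper, unit, group, description) {
    tibble::tibble(name = name, value = value, free = free, lower = lower,
                   upper = upper, unit = unit, group = group,
                   description = description)
  }
  reg <- dplyr::bind_rows(
    ## -- core rate constants (free) ------------------------------------
    row("diff_poc", 20, TRUE, 2, 100, "1/yr", "core_rates",
        "pre-osteoclast -> osteoclast differentiation rate"),
    row("apop_poc", 10, TRUE, 1, 50, "1/yr", "core_rates",
        "pre-osteoclast apoptosis rate"),
    row("diff_pob", 8, TRUE, 2, 40, "1/yr", "core_rates",
        "pre-osteoblast -> osteoblast differentiation rate"),
    row("apop_pob", 10, TRUE, 1, 50, "1/yr", "core_rates",
        "pre-osteoblast apoptosis rate"),
    row("diff_ob_ocy", 0.5, TRUE, 0.05, 1.9, "1/yr", "core_rates",
        "osteoblast -> osteocyte differentiation rate (< diff_pob)"),
    row("clear_scl", 50, TRUE, 5, 200, "1/yr", "core_rates",
        "first-order sclerostin clearance rate"),
    row("rate_resorption", 0.055, TRUE, 0.01, 0.2, "1/yr", "core_rates",
        "bone resorption rate constant (homeostatic turnover rate)"),
    row("rate_mineralization", 0.7, TRUE, 0.1, 5, "1/yr", "core_rates",
        "relaxation rate of bone mineral content toward its target"),

    ## -- regulatory couplings: threshold K + amplitude amp (free), ------
    ##    Hill exponent n (fixed)
    row("K_scl_oc", 1, TRUE, 0.2, 5, "-", "coupling",
        "sclerostin threshold, osteoclastogenesis activation"),
    row("amp_scl_oc", 0.8, TRUE, 0, 5, "-", "coupling",
        "sclerostin amplitude, osteoclastogenesis activation"),
    row("n_scl_oc", 2, FALSE, 1, 6, "-", "coupling",
        "sclerostin exponent, osteoclastogenesis activation"),
    row("K_scl_ob", 1, TRUE, 0.2, 5, "-", "coupling",
        "sclerostin threshold, osteoblastogenesis repression"),
    row("amp_scl_ob", 0.8, TRUE, 0, 5, "-", "coupling",
        "sclerostin amplitude, osteoblastogenesis repression"),
    row("n_scl_ob", 2, FALSE, 1, 6, "-", "coupling",
        "sclerostin exponent, osteoblastogenesis repression"),
    row("K_scl_form", 1, TRUE, 0.2, 5, "-", "coupling",
        "sclerostin threshold, bone-formation repression"),
    row("amp_scl_form", 0.6, TRUE, 0, 5, "-", "coupling",
        "sclerostin amplitude, bone-formation repression"),
    row("n_scl_form", 2, FALSE, 1, 6, "-", "coupling",
        "sclerostin exponent, bone-formation repression"),
    row("K_scl_res", 1, TRUE, 0.2, 5, "-", "coupling",
        "sclerostin threshold, bone-resorption activation"),
    row("amp_scl_res", 0.6, TRUE, 0, 5, "-", "coupling",
        "sclerostin amplitude, bone-resorption activation"),
    row("n_scl_res", 2, FALSE, 1, 6, "-", "coupling",
        "sclerostin exponent, bone-resorption activation"),
    row("K_est_apop", 0.5, TRUE, 0.05, 2, "-", "coupling",
        "estrogen threshold, osteoclast-apoptosis activation"),
    row("amp_est_apop", 0.35, TRUE, 0, 5, "-", "coupling",
        "estrogen amplitude, osteoclast-apoptosis activation"),
    row("n_est_apop", 2, FALSE, 1, 6, "-", "coupling",
        "estrogen exponent, osteoclast-apoptosis activation"),
    row("K_est_scl", 0.5, TRUE, 0.05, 2, "-", "coupling",
        "estrogen threshold, sclerostin-secretion repression"),
    row("amp_est_scl", 0.6, TRUE, 0, 5, "-", "coupling",
        "estrogen amplitude, sclerostin-secretion repression"),
    row("n_est_scl", 2, FALSE, 1, 6, "-", "coupling",
        "estrogen exponent, sclerostin-secretion repression"),
    row("K_rs_ob", 1, TRUE, 0.2, 5, "-", "coupling",
        "resorption-signal threshold, osteoblast-recruitment activation"),
    row("amp_rs_ob", 1.0, TRUE, 0, 5, "-", "coupling",
        "resorption-signal amplitude, osteoblast-recruitment activation"),
    row("n_rs_ob", 2, FALSE, 1, 6, "-", "coupling",
        "resorption-signal exponent, osteoblast-recruitment activation"),

    ## -- drug pharmacodynamics (free) ----------------------------------
    row("dmab_ec50", 5, TRUE, 0.1, 100, "mg", "drug_pd",
        "denosumab half-effect central amount (RANKL inhibition)"),
    row("dmab_emax", 0.95, TRUE, 0, 1, "-", "drug_pd",
        "denosumab maximal inhibition of pre-osteoclast differentiation"),
    row("sclab_ec50", 30, TRUE, 1, 500, "mg", "drug_pd",
        "sclerostin-antibody half-effect central amount (romosozumab/blosozumab)"),
    row("sclab_emax", 0.90, TRUE, 0, 1, "-", "drug_pd",
        "sclerostin-antibody maximal reduction of free sclerostin"),
    row("teri_ec50", 0.1, TRUE, 0.005, 5, "mg", "drug_pd",
        "teriparatide half-effect central amount (anabolic regime)"),
    row("teri_emax", 2, TRUE, 0, 10, "-", "drug_pd",
        "teriparatide maximal fold-increase of osteoblast recruitment"),
    row("aln_ec50", 5, TRUE, 0.1, 100, "mg", "drug_pd",
        "alendronate half-effect bone-bound amount"),
    row("aln_emax_apop", 1, TRUE, 0, 5, "-", "drug_pd",
        "alendronate maximal fold-increase of osteoclast apoptosis"),
    row("aln_emax_res", 0.5, TRUE, 0, 1, "-", "drug_pd",
        "alendronate maximal reduction of resorption efficiency"),

    ## -- drug pharmacodynamic exponents (fixed) ------------------------
    row("dmab_n", 2, FALSE, 1, 6, "-", "drug_pd", "denosumab Hill exponent"),
    row("sclab_n", 2, FALSE, 1, 6, "-", "drug_pd",
        "sclerostin-antibody Hill exponent"),
    row("teri_n", 2, FALSE, 1, 6, "-", "drug_pd", "teriparatide Hill exponent"),
    row("aln_n", 2, FALSE, 1, 6, "-", "drug_pd", "alendronate Hill exponent"),

    ## -- pharmacokinetics (fixed; literature-scale half-lives) ----------
    row("dmab_ka", 30, FALSE, 1, 1000, "1/yr", "drug_pk",
        "denosumab subcutaneous absorption rate"),
    row("dmab_ke", 9, FALSE, 0.5, 1000, "1/yr", "drug_pk",
        "denosumab elimination rate (~4 wk half-life)"),
    row("romo_ka", 30, FALSE, 1, 1000, "1/yr", "drug_pk",
        "romosozumab subcutaneous absorption rate"),
    row("romo_ke", 20, FALSE, 0.5, 1000, "1/yr", "drug_pk",
        "romosozumab elimination rate (~2 wk half-life)"),
    row("blos_ka", 30, FALSE, 1, 1000, "1/yr", "drug_pk",
        "blosozumab subcutaneous absorption rate"),
    row("blos_ke", 25, FALSE, 0.5, 1000, "1/yr", "drug_pk",
        "blosozumab elimination rate"),
    row("teri_ka", 100, FALSE, 1, 10000, "1/yr", "drug_pk",
        "teriparatide effective absorption rate"),
    row("teri_ke", 30, FALSE, 0.5, 10000, "1/yr", "drug_pk",
        "teriparatide effective elimination rate (effect compartment)"),
    row("aln_ka", 200, FALSE, 1, 10000, "1/yr", "drug_pk",
        "alendronate oral absorption rate"),
    row("aln_ke", 100, FALSE, 0.5, 10000, "1/yr", "drug_pk",
        "alendronate plasma elimination rate"),
    row("aln_kbone", 50, FALSE, 0.5, 1000, "1/yr", "drug_pk",
        "alendronate central -> bone-matrix binding rate"),
    row("aln_krel", 0.4, FALSE, 0.01, 10, "1/yr", "drug_pk",
        "alendronate bone-matrix release rate (~2 yr skeletal half-life)"),
    row("aln_bioavail", 0.006, FALSE, 1e-4, 1, "-", "drug_pk",
        "alendronate oral bioavailability fraction"),

    ## -- mineral-content target shifts (fixed) --------------------------
    row("mc_shift_dmab", 0.04, FALSE, 0, 0.2, "-", "mineralization",
        "maximal denosumab-driven upshift of the BMC target"),
    row("mc_shift_aln", 0.05, FALSE, 0, 0.2, "-", "mineralization",
        "maximal alendronate-driven upshift of the BMC target"),

    ## -- estrogen curve (fixed; literature input, not fitted) -----------
    row("est_floor", 0.1, FALSE, 0.01, 0.9, "-", "estrogen",
        "postmenopausal relative estrogen plateau"),
    row("est_menopause_age", 51, FALSE, 40, 60, "yr", "estrogen",
        "age at menopause (logistic midpoint)"),
    row("est_width", 2, FALSE, 0.25, 10, "yr", "estrogen",
        "logistic transition width of the menopausal decline"),

    ## -- bone-turnover-marker mappings (fixed identity exponents) -------
    row("ctx_exp", 1, FALSE, 0.2, 5, "-", "btm",
        "CTX power exponent on the relative resorption rate"),
    row("p1np_exp", 1, FALSE, 0.2, 5, "-", "btm",
        "P1NP power exponent on the relative formation rate"),
    row("bsap_exp", 1, FALSE, 0.2, 5, "-", "btm",
        "BSAP power exponent on the relative formation rate")
  )
  class(reg) <- c("osteo_params", class(reg))
  validate_parameters(reg)
  reg
}

#' Validate a parameter registry
#'
#' Checks structural invariants of an `osteo_params` registry: unique names,
#' positive rate constants, Hill exponents at least 1, and every value inside
#' its declared bounds.
#'
#' @param params An `osteo_params` tibble as returned by
#'   [default_parameters()].
#' @return `params`, invisibly; errors on violation.
#' @export
validate_parameters <- function(params) {
  stopifnot(is.data.frame(params))
  need <- c("name", "value", "free", "lower", "upper", "unit", "group",
            "description")
  missing_cols <- setdiff(need, names(params))
  if (length(missing_cols) > 0) {
    stop("parameter registry lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(params$name)) {
    stop("duplicate parameter names in registry", call. = FALSE)
  }
  rates <- params$group %in% c("core_rates", "drug_pk")
  if (any(params$value[rates] <= 0)) {
    stop("all rate constants must be > 0", call. = FALSE)
  }
  hills <- grepl("^n_", params$name) | params$name %in%
    c("dmab_n", "sclab_n", "teri_n", "aln_n")
  if (any(params$value[hills] < 1)) {
    stop("all Hill exponents must be >= 1", call. = FALSE)
  }
  bad <- params$value < params$lower | params$value > params$upper
  if (any(bad)) {
    stop("parameter(s) outside bounds: ",
         paste(params$name[bad], collapse = ", "), call. = FALSE)
  }
  dp <- param_value(params, "diff_pob") - param_value(params, "diff_ob_ocy")
  if (dp <= 0) {
    stop("diff_ob_ocy must be smaller than diff_pob ",
         "(osteoblast apoptosis = diff_pob - diff_ob_ocy must stay > 0)",
         call. = FALSE)
  }
  invisible(params)
}

#' Look up or modify parameter values
#'
#' `param_value()` extracts the numeric value(s) of named parameters;
#' `set_param_values()` returns a registry with the given named values
#' replaced (bounds are re-checked).
#'
#' @param params An `osteo_params` registry.
#' @param name Character vector of parameter names.
#' @param values Named numeric vector of replacement values.
#' @return `param_value()`: numeric vector named by `name`;
#'   `set_param_values()`: the modified registry.
#' @export
param_value <- function(params, name) {
  idx <- match(name, params$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ", paste(name[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(params$value[idx], name)
}

#' @rdname param_value
#' @export
set_param_values <- function(params, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  idx <- match(names(values), params$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ",
         paste(names(values)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  params$value[idx] <- unname(values)
  validate_parameters(params)
  params
}

#' Derived (fixed-point-pinned) rate constants
#'
#' The nondimensionalization pins several source/clearance constants to the
#' homeostatic fixed point where all normalized pools equal 1. This returns
#' the full parameter list (named numeric) including those derived entries,
#' which is what the model right-hand side consumes.
#'
#' @param params An `osteo_params` registry.
#' @return Named numeric vector: all registry values plus `src_poc`,
#'   `apop_oc`, `src_pob`, `apop_ob`, `apop_ocy`, `secr_scl`,
#'   `rate_formation`.
#' @export
derived_parameters <- function(params) {
  p <- stats::setNames(params$value, params$name)
  c(p,
    src_poc = unname(p["diff_poc"] + p["apop_poc"]),
    apop_oc = unname(p["diff_poc"]),
    src_pob = unname(p["diff_pob"] + p["apop_pob"]),
    apop_ob = unname(p["diff_pob"] - p["diff_ob_ocy"]),
    apop_ocy = unname(p["diff_ob_ocy"]),
    secr_scl = unname(p["clear_scl"]),
    rate_formation = unname(p["rate_resorption"]))
}

#' Read and write parameter registries
#'
#' The on-disk format is a flat, tab-separated text table with one row per
#' parameter and columns `name`, `value`, `free`, `lower`, `upper`, `unit`,
#' `group`, `description`. Numeric fields are written with 17 significant
#' digits so a write/read round trip is lossless.
#'
#' @param params An `osteo_params` registry.
#' @param path File path.
#' @return `read_parameters()`: an `osteo_params` tibble;
#'   `write_parameters()`: `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  out <- params
  for (col in c("value", "lower", "upper")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           name = "c", value = "c", free = "l",
                           lower = "c", upper = "c", unit = "c",
                           group = "c", description = "c"))
  for (col in c("value", "lower", "upper")) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  class(raw) <- c("osteo_params", class(raw))
  validate_parameters(raw)
  raw
}

#' @export
print.osteo_params <- function(x, ...) {
  cat("<osteo_params> ", nrow(x), " parameters (", sum(x$free), " free)\n",
      sep = "")
  NextMethod()
}
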