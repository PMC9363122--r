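---
title: "A bone remodeling model for osteoporosis pharmacotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bone remodeling model for osteoporosis pharmacotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteosim)
```

## The model and its assumptions

`osteosim` describes a *representative bone remodeling unit*: a single
well-mixed compartment standing in for the skeleton's population of
remodeling sites. Its eight dynamic components are pre-osteoclast and
osteoclast densities, pre-osteoblast and osteoblast densities, osteocyte
density, sclerostin concentration, bone density ρ, and bone mineral
content m. Bone mineral density is the product BMD = ρ·m, and only
*relative* BMD and baseline-normalized marker changes are modeled —
absolute cell densities are unidentifiable from such data, so every cell
pool and sclerostin are nondimensionalized to equal 1 at the
premenopausal, drug-free homeostatic state. Source and clearance constants
that the fixed point then pins down (progenitor formation rates, mature
pool apoptosis rates, sclerostin secretion, the formation rate constant)
are derived from the free rates by `derived_parameters()` rather than
carried as independent entries; a consequence worth noting is that the
normalized osteocyte pool inherits a turnover rate from the
osteoblast→osteocyte flux, so its dynamics are faster than the
decades-long lifespan of real osteocytes (the normalization absorbs the
pool-size ratio).

Structurally, each equation follows the same contract:

- progenitor pools: constant source − regulated differentiation −
  apoptosis;
- mature pools: differentiation inflow × regulatory multipliers −
  apoptosis × regulatory multipliers;
- osteocytes from osteoblasts; sclerostin secreted by osteocytes with
  first-order clearance;
- dρ/dt = a_f·φ_f·b − a_r·φ_r·c·ρ — gain proportional to osteoblasts,
  loss proportional to osteoclasts. The loss also carries a factor ρ
  (resorption removes a fraction of the matrix that exists), which makes
  the turnover rate (resorption flux per unit bone density) well defined
  and lets late-life bone loss saturate instead of drifting linearly
  forever;
- dm/dt = λ_m·(m\*(drugs) − m): first-order relaxation of mineral content
  toward a target that antiresorptive drugs shift upward, a coarse-grained
  stand-in for secondary mineralization.

Three regulatory inputs modulate the rates: estrogen (exogenous,
age-dependent), sclerostin (endogenous), and a *resorption signal* — the
melange of matrix-stored factors (TGFβ, BMPs, IGFs) released in proportion
to the instantaneous resorption flux. The signal is treated as algebraic
(quasi-steady) because only its release proportionality is specified; a
fast-equilibrating signal is the minimal consistent choice. It feeds back
positively on osteoblast recruitment, which is the coupling that makes
formation follow resorption.

Every regulatory multiplier has the normalized, amplitude-bounded Hill
form

&nbsp;&nbsp;&nbsp;&nbsp;(1 + amp·H(x)) / (1 + amp·H(1)),

where H is `hill_up` (activation) or `hill_down` (repression). The
division by the value at the homeostatic input x = 1 makes every
multiplier exactly neutral at the reference state — so the all-ones state
is an *exact* fixed point, which anchors the whole nondimensionalization —
while `amp` bounds the physiological fold-change a coupling can exert.
Each coupling therefore carries a free threshold K and amplitude amp with
a fixed Hill exponent (n = 2 throughout); with amplitudes free, the
exponents add little identifiable flexibility, and fixing them keeps the
reference configuration at exactly 31 free parameters (8 core rates +
7 couplings × 2 + 9 drug pharmacodynamic constants).

The couplings and their directions: sclerostin promotes
osteoclastogenesis and resorption and represses osteoblastogenesis and
formation; estrogen promotes osteoclast apoptosis and represses sclerostin
secretion (its two established antiresorptive routes); the resorption
signal promotes pre-osteoblast differentiation.

### Aging input

Menopause enters through relative serum estrogen: a logistic decline from
the premenopausal plateau (1) to a floor of 0.1, centered at 51 years
(population average age at menopause) with a 2-year logistic width. The
curve is a fixed literature-style input, not a fitted quantity; its three
parameters sit in the registry flagged fixed.

### Drug modules

All five drugs share linear pharmacokinetics: an instantaneous bolus into
a depot compartment (subcutaneous for the antibodies and the PTH analog,
oral with a 0.6 % bioavailability factor for alendronate), first-order
absorption to a central compartment, first-order elimination. Clinical
dosing (weekly to 6-monthly) is impulsive relative to the model's time
scales, which justifies the bolus treatment. Alendronate additionally
exchanges with a bone-bound compartment (fast binding, slow ~2-year
release), carrying the bisphosphonate class's long skeletal retention; its
pharmacodynamic input is the bone-bound amount, so its action outlasts
dosing. Teriparatide's sub-day plasma half-life is coarse-grained into an
effect compartment with day-scale kinetics; the module covers only the
anabolic intermittent regime.

Effects are neutral-at-1 Emax/Hill multipliers on class-specific targets:
denosumab inhibits pre-osteoclast → osteoclast differentiation (RANKL
antibody); romosozumab and blosozumab reduce the *effective free
sclerostin* seen by every regulatory multiplier (the sclerostin mass
balance itself is untouched — antibody binding sequesters rather than
degrades); alendronate raises osteoclast apoptosis and lowers resorption
efficiency; teriparatide raises osteoblast recruitment. Denosumab and
alendronate also shift the mineral-content target up by a few percent.
Simultaneously active drugs hitting the same target compose
multiplicatively — neutral-at-1 multipliers compose naturally and no
interaction data informs anything richer.

### Reference parameter values

Absent a transcribable reference table, the package's default registry was
designed once, from physiological anchors, and then frozen: osteoclast
lifespan of a few weeks and an osteoblast active period of several weeks
set the lineage rates; the homeostatic resorption rate constant is
0.055/yr so that the implied adult-life mean turnover is about 6 %/yr
(cortical-dominated skeletal average); the estrogen coupling amplitudes
give an early-postmenopausal BMD loss on the order of 1 %/yr with CTX
elevation of a few tens of percent; antibody and bisphosphonate
elimination constants correspond to published half-lives (≈4 weeks
denosumab, ≈2 weeks romosozumab, ≈2 years skeletal alendronate); EC50s are
placed so clinical doses operate in the upper half of their dose–response
curves. These anchors, not any test outcome, fixed the defaults.

## What the synthetic data generator emulates

The fixtures module generates clinical-style *study-average* series from a
known parameter set: an aging dataset (mean BMD in 10-year bins, 20 to
"80 and older", bin-center convention with the open-ended bin treated as
10 years wide) and treatment datasets (relative total-hip BMD at clinic
visits plus CTX/P1NP/BSAP fractional baseline changes), with independent
additive Gaussian noise — sd 0.004 on relative BMD, matching the
reproducibility of DXA population means, and sd 0.05 on marker changes.
Treatments start at age 65, which lies on an aging bin center so the
hybrid merge is interpolation-exact and noise-free generation closes the
loop to solver precision (the end-to-end objective at the generating
parameters is ~1e−9).

The default collection comprises four single-drug calibration datasets
(denosumab 60 mg q6mo × 3 yr; alendronate 70 mg weekly × 2 yr;
romosozumab 140 mg monthly × 1 yr; teriparatide 20 µg daily × 18 mo) and
two combination validation datasets (sequential
alendronate→romosozumab→denosumab year-blocks; teriparatide + denosumab in
parallel then denosumab alone).

What passing tests on these data do and do not show: they verify the full
pipeline — generation, hybrid-dataset construction, simulation, goodness
metrics, parameter recovery — under a *correctly specified* model with
independent noise. They do not show that the model captures real digitised
trial data: real study averages carry autocorrelated digitisation error,
population heterogeneity, and model misspecification, none of which the
generator emulates.

## Hybrid datasets and calibration

A hybrid aging/treatment dataset places a treatment series into the aging
context: treatment start at the study population's mean baseline age
rounded to whole years; treatment BMD rescaled so its baseline equals the
linearly interpolated aging-anchor BMD at that age; markers as fractional
changes from baseline; no extrapolation outside the anchor range.

The calibration objective is a weighted least-squares loss over aging
anchors, treatment BMD, and marker series. BMD residuals carry weight 1,
marker residuals 0.2 — BMD is the primary clinical target while markers
chiefly inform each drug's mode of action — and marker points with
|observed change| < 0.05 are excluded (relative errors on near-zero
baselines are uninformative; direction concordance covers them instead).
Both weights and threshold are exposed in `calibration_config()`.
Optimization is bounded Levenberg–Marquardt on the residual vector
(`minpack.lm::nls.lm`) from the registry's values plus seeded
Latin-hypercube starts; the k-start set is always a prefix of the same
seeded stream, so adding starts can only improve the returned best loss,
and a fixed seed makes fits bit-reproducible. Simulation failures inside
the objective map to a large finite penalty of constant residual length
(the optimizer requires a fixed-length residual).

Goodness is reported per dataset × observable as MAPE and normalized
RMSE, plus excursion-direction concordance per marker series — the sign of
the maximum-magnitude excursion, which is robust exactly where MAPE is
not.

## Numerical choices

- Integration: `deSolve::lsoda` (stiff-capable, adaptive), relative
  tolerance 1e−8, absolute 1e−10. Dose events are exact impulses: the
  integrator stops at each event time and the dose is added to the depot
  before restarting. Requested output times indistinguishably close to an
  event time (< 1e−9 yr) are merged onto the event time and recovered by
  nearest-time matching.
- States are clamped at zero against solver noise; the right-hand side is
  evaluated on the clamped state, and structural nonnegativity (every
  boundary derivative ≥ 0) is property-tested.
- Steady states solve the drug-free fixed point by damped Newton with a
  central-difference Jacobian from the all-ones start, to a residual
  below 1e−10/yr; estrogen = 1 returns the all-ones state exactly.
- Evaluation grids always include the measurement ages, the reference
  age, and the marker baseline age, so data comparisons never interpolate
  between grid points.
- Marker mappings use the identity elementary function (fractional change
  of the flux itself); per-marker power exponents exist in the registry,
  fixed at 1, should calibration ever need them. P1NP and BSAP share the
  formation flux and differ only through these exponents.
- Tie-breaks in regimen ranking: the other criterion, then label order —
  fully deterministic.

## Problem sizes

The shipped tests and the acceptance script use: life-course simulations
of 50–65 years on 0.05–0.25-year output grids; a fixed-step
Runge–Kutta reference at step 1e−4 yr over a 3-year treatment window as
the integrator oracle; pharmacokinetic closed-form comparisons at
tolerance 1e−8 with solver tolerances tightened to 1e−11/1e−14; and
parameter recovery of 1 and 5 free parameters from noise-free synthetic
collections of 2 compact datasets. The six-sequence experiment simulates
six 50-year life courses with ~66 dose events each.

## Known limitations

- The representative-unit abstraction has no spatial structure, no
  cortical/trabecular split, and no explicit RANK–RANKL–OPG species;
  those pathways act implicitly through the fitted couplings.
- Reference parameters are package defaults built from physiological
  anchors, not a transcription of any published fit; quantitative outputs
  should be read as class-typical, not patient- or trial-specific.
- Only relative BMD is modeled; absolute density and fracture risk are out
  of scope, as are mechanical loading, calcium/vitamin D, comorbidities,
  and hormone-replacement therapy.
- Teriparatide's intermittent-versus-continuous PTH dichotomy is not
  mechanistically resolved; only the anabolic regime is represented.
- Population-level means only: no inter-individual variability,
  immunogenicity, or renal-function dependence of clearance.
- Extrapolation far outside calibrated dose ranges, dosing frequencies, or
  age windows inherits no guarantees from any calibration.
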