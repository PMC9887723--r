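---
title: "Tissue dosimetry of endogenous and exogenous formaldehyde DNA adducts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue dosimetry of endogenous and exogenous formaldehyde DNA adducts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Inhaled formaldehyde causes nasal tumors in F344 rats at cytotoxic
concentrations, but formaldehyde is also produced endogenously in every cell
by 1-carbon metabolism. Both sources react with nuclear DNA, producing
N2-hydroxymethyl-deoxyguanosine monoadducts (DG) and DNA-protein crosslinks
(DPX). Because the isotope-labelling experiments that separate endogenous
from exogenous adducts are expensive and sparse, a tissue dosimetry model is
needed to interpolate and extrapolate the measured adduct burdens across
inhaled concentrations, exposure schedules and time — in particular to ask at
what inhaled concentration exogenous adducts begin to exceed the endogenous
background that tissue always carries.

`nasaldosim` implements such a model for the rat nasal mucosa: a single
well-mixed tissue slab at one of two measurement sites, driven by a
site-specific wall flux of inhaled formaldehyde taken from computational
fluid dynamics (CFD) simulations of the rat nose. The CFD step itself is out
of scope; its output enters as two constants, the flux at 1 ppm into the
anterior "high tumor" DPX site (800.3 pmol/mm²/h) and into the larger DG
site (776.6 pmol/mm²/h), assumed linear in the inhaled concentration.

## The model

Nine state variables, all in pmol/mm³ (numerically equal to µM), all per
unit tissue volume:

* `endoF`, `exogF` — free formaldehyde of endogenous and exogenous origin;
* `GSH`, `endoF_GSH`, `exogF_GSH` — free glutathione and the
  S-hydroxymethylglutathione complexes formed from each formaldehyde pool;
* `endoDG`, `exogDG`, `endoDPX`, `exogDPX` — the four adduct pools.

The exogenous source term is the volumetric uptake
`uptake = flux_per_ppm × ppm / thick`, where `thick` is the mucosal
thickness (0.1138 mm); the endogenous source is the zero-order production
rate `kp`. The two formaldehyde pools follow identical kinetics and differ
*only* in their source:

```
d endoF/dt = kp     − (k21 + kDNA_DG + kDNA_DPX)·endoF − k23·endoF·GSH + k32·endoF_GSH
d exogF/dt = uptake − (k21 + kDNA_DG + kDNA_DPX)·exogF − k23·exogF·GSH + k32·exogF_GSH − EC(exogF)
```

Each adduct pool is formation minus first-order repair, e.g.
`d endoDPX/dt = kDNA_DPX·endoF − krep_DPX·endoDPX`, and analogously for the
other three pools. DPX repair is fast (`krep_DPX` = 0.39/h, half-life 1.78 h)
while DG repair is slow (`krep_DG` = 0.0063/h, half-life 110 h) — this
asymmetry drives most of the qualitative dose-response behaviour.

The glutathione subsystem is a design decision of this package. The
formaldehyde–GSH complexes are oxidized by formaldehyde dehydrogenase, a
single saturable enzyme pool for which the endogenous and exogenous
complexes compete:

```
ox_endo = Vmax·endoF_GSH / (Km + endoF_GSH + exogF_GSH)     (ox_exog analogous)
d GSH/dt = −k23·(endoF + exogF)·GSH + k32·(endoF_GSH + exogF_GSH) + ox_endo + ox_exog
```

Oxidation regenerates free GSH, so the glutathione moiety
`GSH + endoF_GSH + exogF_GSH` is conserved exactly — there is no glutathione
synthesis or turnover term. This shared-enzyme, conservative form is the
simplest construction consistent with the biochemistry of
S-hydroxymethylglutathione oxidation and with the coupling terms that appear
in the formaldehyde equations; it is a reconstruction, since only the
formaldehyde and DPX equations are fixed by prior art. Two consistency
checks support it: the model's endogenous fixed point gives
endoDG ≈ 7.1e-4 pmol/mm³, matching both the published initial value
(7.42e-4) and the measured endogenous DG plateau, and the package's test
suite verifies the conservation law to 1e-6 relative along every
trajectory. Where results could depend on the reconstruction (absolute
exogDPX/exogDG predictions), the package's checks use wide factor-of-2/3
tolerances; ratio and property checks carry the stringent tolerances.

An optional extracellular clearance `EC(exogF)` implements the low-dose
variants: `ec_mode = "zero_order"` subtracts a constant rate (smoothly
clipped by the factor `exogF/(exogF + 1e-6)` so the sink cannot drive the
state negative while keeping the right-hand side continuous for the stiff
solver), and `ec_mode = "saturable"` uses a Michaelis–Menten form with
user-supplied `ec_Vmax`, `ec_Km`. The base model has `ec_mode = "off"`.

## Parameters

`kinetic_parameters()` returns the reference calibration for the F344 rat
nasal mucosa (units: hours, pmol/mm³): `kp` = 10835, `k21` = 16.57/h,
`k23` = 0.35 per (pmol/mm³)/h, `k32` = 200/h, `kDNA_DG` = 9.5183e-8/h,
`kDNA_DPX` = 1.8183e-4/h, `krep_DG` = 0.0063/h, `krep_DPX` = 0.39/h,
`Vmax` = 74156, `Km` = 1935, `thick` = 0.1138 mm, plus approximate initial
concentrations. Any value can be overridden by name, and flat key-value
configuration files round-trip bit-exactly through
`write_config()`/`read_config()`.

### Initial conditions and burn-in

The published initial concentrations are approximate, and multi-day
simulations are insensitive to them: the endogenous subsystem relaxes to a
unique fixed point. Simulations therefore start from
`endogenous_steady_state()` by default (computed algebraically by reducing
the fixed point to a scalar root in free endogenous formaldehyde; a burn-in
integration method is available and agrees to solver tolerance). The strict
as-published initialization remains available via `initial = "published"`
in `integrate_model()`.

## Exposure protocols

Exposure is a square wave (instantaneous on/off, no chamber ramp — the
simplest reading of the study designs), with half-open episodes
`[start, end)`:

* `single_exposure(ppm)` — one 6-h episode, sampled at 7 h (1 h
  post-exposure), the single-exposure DG study design;
* `daily_schedule(ppm, n_exposure_days = 28, ...)` — consecutive daily
  episodes; with the default 24-h origin offset, day *n* occupies
  `[24n, 24n + 6)` so that the 28-day study's printed sampling times
  (175, 343, 511, 679 h during exposure; 684, 702, 750, 846 h after) are
  reproduced exactly (e.g. 175 = 24·7 + 7);
* `casanova_schedule(ppm)` — the chronic DPX design: 6 h/day, 5 days/week
  for 11 weeks and 4 days, then a final 3-h exposure with immediate
  sacrifice. Here calendar day *d* starts at `24(d − 1)` (t = 0 at the
  first exposure), because the printed sampling time 1947 h equals
  24·81 + 3: the final 3-h episode runs over `[1944, 1947)`. The two origin
  conventions differ between protocols; both are derived from the printed
  sampling times, which are the only authoritative anchors.
* `leng_schedule(ppm = 0.3)` — 28 days at 6 h/day starting at t = 0,
  sampled at 672 h.

## Units conversion

DG monoadduct data are reported as adducts per 10⁷ deoxyguanosine (DPC per
10⁸), while the model currency is pmol adduct per mm³ tissue.
`per_dg_to_conc()` converts with genome size 3.024e9 bp, G:C fraction 0.41,
cell volume 7.5e-7 mm³ and a ploidy factor. The ploidy/strand convention of
the original conversion is not recoverable from the main text, so ploidy is
an explicit, documented constant (default 2, diploid nucleus) rather than a
buried literal; under these defaults 1 adduct/10⁷ dG ↔ 5.49e-4 pmol/mm³.
The packaged dataset ships the already-converted values verbatim, so this
choice does not touch the calibration currency.

## Calibration

`adduct_cost()` simulates each study design once per (study, concentration)
group from the endogenous steady state and scores predictions with relative
least squares, `Σ((pred − obs)/obs)²`. The measured concentrations span
more than four orders of magnitude, so absolute least squares would see
only the largest values; fractional residuals weight each observation
equally. A log-residual variant is available, and both are labelled as
package constructions: the exact weighting of the original "modified least
squares" is not recoverable. DPC species and below-LOD rows never enter the
cost, and the 0.32 ppm exogDPX datum is excluded (different tissue site and
sampling time).

`fit_parameters()` minimizes the cost with Nelder–Mead under box bounds via
the sine-transform construction (each bounded coordinate mapped to an
unbounded one, so the simplex never needs clipping); a single free
parameter uses Brent's method on the interval directly. The optimizer
restarts the simplex around the current best point after natural
convergence and stops when a restart no longer improves the cost. Runs that
exhaust the iteration cap return `converged = FALSE` rather than an error.
Within optimization loops the ODE solver runs at moderately relaxed
tolerances (rtol 1e-6, atol 1e-10) for speed; reported simulations use the
tight defaults below.

`two_stage_fit()` mirrors the published two-stage procedure: stage 1 fits
the tissue thickness separately against the DG-site data (flux 776.6) and
the DPX-site data (flux 800.3); stage 2 refits a single shared thickness
against all data, initialized from the geometric mean of the stage-1
estimates.

### Synthetic data and what recovery tests show

`generate_synthetic_observations()` simulates a protocol design table at
known parameters and multiplies each prediction by lognormal noise with a
chosen coefficient of variation (mean 1, seeded). The default
`recovery_protocols()` design uses single 6-h exposures at 0.7–15.2 ppm at
both sites plus a 7-day daily design, probing both the linear and the
enzyme-saturated range. This emulates the *protocols and noise structure*
of the laboratory data, not its full reality: real measurements carry
inter-animal variability, assay-specific bias and non-lognormal tails, and
the generating model is by construction the fitted model. Passing recovery
tests therefore demonstrate that the optimizer and cost function can
identify the parameters *given the model*, not that the model is correct.
The noisy-recovery experiments in the test suite use 11 replicate datasets
at a 20% coefficient of variation with (`kp`, `thick`) free; the noise-free
experiment frees (`kp`, `k21`, `Vmax`, `Km`, `thick`). `Vmax` and `Km` are
only weakly identified separately (their ratio controls sub-saturation
clearance), which is why the noisy assertions are restricted to the
well-identified pair.

## Dose-response analyses

`dose_response()` evaluates all four adduct species over a concentration
grid after burn-in. Because DPX track concurrent exposure (fast repair)
while DG integrate exposure history (slow repair), the default per-species
protocols differ: DPX under the chronic schedule sampled immediately after
the final 3-h exposure, DG at the plateau of the 28-day daily schedule.
These choices make the two published crossover concentrations mutually
consistent; single-exposure modes are available for both species and the
active mode is recorded on the curve object. `find_crossover()` brackets
the exogenous-over-endogenous crossing on the grid and refines it by
bisection on log-ppm to 1% (each step re-simulating the protocol);
`dpx_dg_ratio()` reports the minimum DPX:DG ratio over the grid per adduct
origin. At the endogenous steady state that ratio has the closed form
`(kDNA_DPX/krep_DPX)/(kDNA_DG/krep_DG) ≈ 30.9`, which the test suite checks
against the simulated fixed point.

A subtlety worth knowing: during exposure the endogenous adduct curves are
*not* flat, because the exogenous formaldehyde load depletes shared free
GSH and thereby raises free endogenous formaldehyde. The crossover analysis
compares each exogenous species against its endogenous counterpart under
the same exposure, as measured experiments do.

## Numerical choices

* Stiff-capable adaptive integration (`deSolve::ode`, lsoda) with
  rtol 1e-8 and atol 1e-12 pmol/mm³ — the rate constants span nine orders
  of magnitude. Exposure on/off edges are always integration restart
  points, and each segment is integrated in segment-local time so step-size
  control stays well scaled on ~2000-h schedules.
* The adaptive path is verified in the test suite against an independently
  coded fixed-step RK4 oracle (step 1e-4 h) on a 24-h single-exposure run,
  to 0.1% on every state.
* States are clamped to zero when the solver returns values within its
  absolute tolerance below zero; larger negativity is an error.
* Degenerate inputs: zero-ppm schedules produce empty episode tables;
  sampling outside the schedule horizon, overlapping episodes and negative
  states are errors naming the offending component.
* Tests and the reproduction script use a 10-point dose grid over
  0.7–15 ppm and 11 noisy replicates; these sizes are the package's own
  choice of a compact but representative experiment.

## Known limitations

* The companion equations (glutathione subsystem, DG pools) are a
  documented reconstruction; absolute adduct predictions inherit that
  structural uncertainty, which is why the package's own checks put
  factor-level tolerances on absolute levels and tight tolerances only on
  ratios, conservation laws and closed forms.
* Single well-mixed slab: no intracellular compartmentalization of 1-carbon
  metabolism, no mucus-layer transport, no regional variation in enzyme
  activity or epithelial thickness (uniform values are required by the
  downstream flux-binning use anyway).
* The DPC (deoxyguanosine-specific crosslink) dataset is shipped but not
  modelled; the low-dose non-detect behaviour cannot be reproduced jointly
  with the DPX data by any single parameter set explored here, consistent
  with the discrepancy discussed in the source literature. The zero-order
  extracellular-clearance variant suppresses low-dose exogDG by about two
  orders of magnitude; in this reconstruction its 0.3-ppm prediction lands
  marginally below the detection limit rather than marginally above it —
  a reminder of how sensitive that regime is to the reconstructed
  clearance structure.
* Breathing-cycle resolution is absent: the flux constants are
  breath-averaged, as in the CFD work they come from.
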