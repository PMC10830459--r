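---
title: "inlandn2o: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{inlandn2o: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inlandn2o)
```

## The problem

Lakes and reservoirs (lentic systems) and the river networks feeding them
are significant sources of nitrous oxide, produced by microbial
nitrification (NH4+ -> NO3-, with a small N2O yield) and denitrification
(NO3- -> ... -> N2O -> N2) acting on nitrogen delivered from land. The
terrestrial load responds to climate, land conversion, atmospheric
deposition and agricultural nitrogen, and is suppressed by elevated CO2
(better plant N retention), so aquatic N2O emission is a moving target
that a constant emission factor cannot track. `inlandn2o` implements a
desk-scale, fully testable simulator of this chain: a gridded
stream-river-lake-reservoir network, daily water and nitrogen routing, a
per-element dissolved-N2O mass balance, a staged simulation protocol with
factorial attribution, and dynamic agricultural emission factors — driven
entirely by a synthetic-data module, so every stage runs and is verified
without external datasets.

## Network and hydrology

Each grid cell carries three subgrid elements: a *hillslope* (runoff
entry, no storage), a *subnetwork* reach (the low-order streams inside the
cell) and a *main-channel* reach. Lentic bodies attach by size class: a
body whose upstream catchment area exceeds the (configurable, default
0.5-degree) cell area is **large** and sits in line on the main channel;
otherwise it is **small** and intercepts a share
`min(upstream_area / cell_area, 1)` of the cell's hillslope flow before
the subnetwork. Ties classify as small (the rule is a strict "greater
than"). Co-located small bodies intercept sequentially in descending
upstream area — each takes its fraction of what remains — so the total
intercepted share never exceeds one and water balance is preserved; the
underlying science leaves this split open and the sequential rule is our
documented choice. Small-body outflow joins the subnetwork's outflow into
the main channel.

Routing is storage-based at a daily step: reaches release
`min(dt / travel_time, 1)` of storage per day with travel time from a
constant celerity (default 1 m s^-1), and lentic bodies follow the
linear-reservoir rule `Q = V / tau` with tau the inventory residence time
(so the steady state satisfies `V* = Q tau`). Reservoirs activate at
their construction year (inclusive); before that, or in natural-flow
runs, they are pass-through: full flush, no lentic biogeochemistry, no
gas exchange. Precipitation falls on active lentic surfaces (evaporation
is a config term, default 0). The engine audits itself: water, nitrogen
and per-element N2O balances are recomputed from the applied deltas every
day, and each run carries its worst residuals.

## Aquatic nitrogen

Four species are tracked per element — NO3-, NH4+, dissolved organic N,
particulate organic N (DIN is reported as NO3- + NH4+ because the
uncertainty protocol perturbs them separately). Advection is donor-cell:
outflow carries each species at the element's own concentration, capped
at a full flush. Transformations are first-order with Q10 temperature
scaling `f_T = q10^((T - t_ref)/10)` on a smoothed water temperature (a
30-day running mean of air temperature, floored at 0 degC), zeroed at or
below 0.5 degC as an ice-cover stand-in:

* DON mineralisation to NH4+ (`k_dec`, default 0.01 d^-1);
* PON settling, `1 - exp(-(v_settle/depth) dt)` (default 0.5 m d^-1,
  purely physical), half to a reactive sediment pool that remineralises
  at `k_sed` = 0.005 d^-1, half permanently buried;
* nitrification (`k_nit`, default 0.05 d^-1), with yield
  `y_nit` = 0.001 diverted to N2O;
* benthic denitrification in uptake-velocity form,
  `v_den f_T A k_half [NO3]/([NO3] + k_half)` with `v_den` = 3e-7 m s^-1
  (literature bounds 3e-8..2e-6) and `k_half` = 0.1 g N m^-3. Note the
  saturating algebra: the Michaelis-Menten factor is applied so the flux
  is linear (velocity x concentration x area) at low nitrate and
  saturates at `v_den f_T A k_half` — the naive product of a linear
  uptake and an MM factor would be super-linear and never saturate.
  Setting `k_half_no3 = 0` disables damping. A fraction `y_den` = 0.005
  of removed nitrate becomes N2O; the rest is N2.

The exact process formulations of the source framework are in
supplementary material we do not reproduce; the forms above are the
standard aquatic-biogeochemistry stand-ins, and every constant is a
config-overridable calibration knob.

## The dissolved-N2O balance

Per element and day, `dM/dt = F_a + Y_water + D - R - E`:

* `F_a` — net advection, including terrestrial runoff which enters
  carrying dissolved N2O at the atmospheric equilibrium concentration
  (soil drainage water is near saturation; without this term fresh
  runoff dilutes short-residence reaches below equilibrium and the whole
  river network becomes a spurious permanent sink);
* `Y_water` — production, `y_nit flux_nit + y_den flux_den`;
* `D` — rain on lentic surfaces at the equilibrium concentration;
* `R` — benthic reduction of N2O to N2,
  `v_red f_T [N2O] A k_half/(k_half + [NO3])` with `v_red` = 1e-7 m s^-1:
  nitrate outcompetes N2O as electron acceptor, so reduction is strongest
  when nitrate is depleted — which is what lets a water body draw its
  concentration below equilibrium and take up atmospheric N2O (the sink
  regime, exercised in the acceptance suite);
* `E` — air-water exchange, instantaneous flux
  `k A (C - c_eq)` (positive to atmosphere). The equilibrium
  concentration uses a Weiss & Price (1980)-type zero-salinity solubility
  polynomial, linear in the atmospheric mixing ratio, which itself ramps
  273 ppb (1850) to 332 ppb (2019). Transfer velocities:
  lentic `k = a + b wind^2` (defaults 0.5 + 0.05 wind^2 m d^-1); lotic
  `k = 100 sqrt(velocity x slope)/sqrt(depth)` floored at 0.3 m d^-1.

Numerics: one canonical operator-split order per day — advection;
decomposition; settling/remineralisation; nitrification; denitrification;
production + deposition; reduction; exchange — with every term limited so
no pool goes negative, and the Eq.-1 identity holding to machine
precision by construction because each term is computed from the mass
change it caused. The exchange term is applied as its exact over-the-step
integral (exponential relaxation toward `c_eq`): in shallow subnetwork
reaches `k A dt / V` exceeds one, and the explicit increment is unstable
(it turns the equilibrium into a period-2 oscillation, which is how the
convergence test caught it). The calendar is 365-day, dt fixed at 1 day.

## Simulation protocol

Equilibrium (first-year forcing repeated until the largest relative
interannual pool change drops below 1e-4, capped at a configurable year
count) -> 30-year spin-up drawing whole years uniformly from the 1850s
under a recorded seed -> a natural-flow transient (dams deactivated) ->
the dam-managed all-combined transient S1, which requires the natural run
first (protocol ordering, enforced in code) -> five factorial runs S2-S6,
each holding one factor (climate, CO2, land use, N deposition,
agricultural N) at its first-year value. All factorial runs branch from
the common post-spin-up state; branching after spin-up (rather than
before) is our documented resolution of an ambiguity in the protocol
description. Reservoir construction is deliberately *not* a separate
factor — its effect rides inside the environmental-change runs — and a
dams-off S1 variant is available as a diagnostic.

Attribution over a decade pair: factor f contributes
`delta S1 - delta S_f` (delta = change of decadal means); relative
contributions are signed percentages of `|delta S1|`, the interaction
residual is reported separately (closure is exact), and a second
normalisation over the sum of absolute contributions is also emitted.
The uncertainty ensemble brackets S1 with all species loads scaled down
and up by their stated perturbations (NO3 22%, NH4 50%, DON 37%,
PON 26%). Decades are [X0, X9]; "the 2010s" is 2010-2019. Emission
factors: `EF_Ag = (S1 - S6)/additions x 100%` per country and decade,
negatives clamped to zero (pre-fertilizer decades genuinely come out
negative — unsaturated N2O under small manure inputs — and the clamp is
part of the contract), zero-addition regions flagged. CO2 equivalents
use `flux x 44/28 x GWP/1000` with GWP 273.

## The synthetic world

The generator is a *stated world*, not a tuning dial. The defaults
encode: a 20 x 20 grid at 45 N draining to one outlet; 8 lakes and 4
reservoirs spanning both size classes (reservoirs built 1900-2000);
seasonal sinusoidal climate (mean 9 degC, amplitude 12) with weather
noise, stationary before 1901, then warming 1.3 degC by 2019; an
accelerating CO2 ramp 285 -> 410 ppm; N deposition 1.5 -> 10
kg N ha^-1 yr^-1; manure growing linearly from 8 kg N ha^-1 yr^-1;
synthetic fertilizer exactly zero before 1910 then logistic (midpoint
1975, plateau 30), so the manure share of agricultural N declines from
100% to ~55% by the 1990s; cropland fraction 0.10 -> 0.40. The load
emulator is reduced-form on purpose — the full land model is out of
scope — but it reproduces the *sign structure* every mechanism claim
relies on: base export 0.05/0.01/0.04/0.03 g N m^-2 yr^-1
(NO3/NH4/DON/PON) scaled by `(1 + 0.08 dT)` and `(1 + 2 crop)`,
minus a CO2 suppression term `0.004 (CO2 - 285)` applied to the base
export only (so the response to agricultural N stays exactly linear, a
tested contract), plus a leached fraction 0.15 of N inputs split
0.7/0.1/0.1/0.1 across species; floored at zero. Daily loads follow
daily runoff. Climate is spatially uniform across the grid (loads vary
per cell through area and a fixed log-normal cropland pattern); that and
the 365-day calendar keep the full six-scenario 1850-2019 protocol
inside its 15-minute single-CPU budget in pure R.

What a green run does *not* establish: magnitudes are not global
magnitudes (no real hydrography, inventories, or calibration data);
spatial covariance of weather is absent; sub-daily hydraulics, ice
hydrology, stratification, ebullition and point-source N are out of
scope by design.

## Verification layout

`tests/testthat/` holds per-module unit tests against closed-form
oracles (spherical cell areas, settling and half-life identities, the
uptake-velocity arithmetic, an independently coded solubility polynomial,
a hand-rolled advection oracle for the conservative-transport limit, and
an element-wise equivalence check between the vectorised engine and the
composed exported operations), property-style suites (no-negative-mass,
temperature monotonicity, ledger closure), and
`test-acceptance.R` with one test per acceptance criterion, including the
full-fixture golden-run regression (frozen decadal means under fixed
seeds) and the trajectory-shape check (steepest decadal rise of lentic
emissions between the 1940s and 1980s). `scripts/acceptance.R` runs the
pipeline end to end and writes the (empty) numeric-target report. Every
run emits a JSON manifest from which the whole world and protocol are
reconstructible bit-identically.
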