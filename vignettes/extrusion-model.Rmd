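---
title: "A 1D global model of twin-screw extrusion for starchy food melts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 1D global model of twin-screw extrusion for starchy food melts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extrusim)
```

## What the model computes

Co-rotating twin-screw extrusion cooks and shears a moist biopolymer feed
(starch, flour, legume or bran blends) between screws and a heated barrel,
then shapes it through a die. The thermomechanical severity of that
treatment — summarized by the die-exit melt temperature `T_com`, the
cumulative specific mechanical energy `SME_com` (kJ/kg), the die-entrance
pressure `P_com` and the die-exit apparent viscosity `eta_com` — largely
decides what the product becomes: how far starch is depolymerized, whether
proteins cross-link, how much the extrudate expands. `extrusim` predicts
those four quantities, and the axial profiles behind them, from machine
geometry and operating conditions, and maps them onto product features
through monotone correlation models, so that the whole chain

> operating conditions → die-exit state → product features

can be run in either direction.

## The flow model

The model is a *global* one-dimensional description, not a CFD solution: each
screw element is treated as a C-chamber (the C-shaped volume between the
intermeshing screws) whose flow obeys the locally-Newtonian lubrication law

$$Q_v = A\,\Omega + \frac{B}{\eta}\,\frac{\Delta P}{\Delta\theta},$$

where $Q_v$ is the volumetric throughput, $\Omega$ the screw speed in rad/s,
and $A$ (drag) and $B$ (pressure conductance) follow from
shallow-rectangular-channel formulas applied to the element geometry
(`shape_factors()`). Right-handed conveying elements have $A > 0$;
left-handed (reverse) elements have $A < 0$ and therefore force full filling
and pressure build-up upstream; kneading blocks are mapped to an equivalent
conveying element whose pitch is implied by the disc stagger (thickness ×
360°/stagger, drag efficiency $1 - \chi/90°$), with a leakage conductance
past the disc tips added to $B$. Reverse elements likewise carry a slot/gap
leakage conductance: practical left-handed elements are slotted precisely so
melt can pass them.

Non-Newtonian behaviour enters through the viscosity at a representative
channel shear rate $\dot\gamma = \pi D N / (60\,h)$ (tip speed over channel
depth). The melt follows an Ostwald–de Waele power law
$\eta = K \dot\gamma^{\,n-1}$ whose consistency depends on absolute
temperature, wet-basis moisture fraction and cumulative SME,

$$K = K_0 \exp\!\Big(\tfrac{E}{R}\big(\tfrac1{T_a} - \tfrac1{T_0}\big)
      - \alpha\,(MC - MC_0) - \beta\,(SME - SME_0)\Big),$$

with reference state $T_0 = 353$ K, $MC_0 = 0.10$, $SME_0 = 350$ kJ/kg, and
whose flow index is an empirical polynomial in $T$ (°C), $MC$ and $SME$ with
pairwise interactions, clamped to $[0.05, 1]$ outside its calibration
window. The package ships published parameter sets for eleven feeds
(`material_db()`, `list_materials()`): four maize starches spanning 1–70%
amylose, potato starch, two breakfast-cereal recipes (`cb`, `hb`), pea flour
and three wheat-flour/bran blends (the latter in the "absolute" dialect
without reference offsets; `convert_dialect()` maps between the two exactly).
Moisture is a wet-basis mass fraction everywhere; Eq-level temperature units
(kelvin in the consistency law, Celsius in the flow-index polynomial) are
preserved, with conversions explicit at call sites.

Two per-element energy terms heat the melt: drag dissipation
$\eta \dot\gamma^2 V$ evaluated separately for the channel and the
flight-tip gap (whose shear rate is tip speed over clearance), and
pressure-flow dissipation $\Delta P\,(Q_v - A\Omega)$, which is the exact
Poiseuille term of combined Couette–Poiseuille channel flow (the cross term
integrates to zero). The second term is what makes reverse elements the
dominant heaters: they force the full backflow through their conductance
against several MPa. Partially filled chambers dissipate in proportion to
their filled fraction, `fill = Qv/(A Ω)` with $P = 0$ — the standard
starved-flow closure. Heat exchange with the barrel follows a Nusselt
closure $h_t = \mathrm{Nu}\,\lambda/h$ on the channel depth (default
$\mathrm{Nu} = 20$), over the barrel-facing surface $\pi D L$ of the filled
fraction scaled by an exchange-area factor (default 0.85: part of the bore
faces the intermeshing region, not the barrel). The energy balance per unit
mass is then $C_p\,\Delta T = E_v - E_{cd}$ with
$E_v = \dot W/(\rho_m Q_v)$.

Melt density, heat capacity and conductivity blend linearly in moisture
between the dry molten material and water. Melting temperature comes from a
per-material moisture curve (piecewise linear, strictly decreasing;
extrapolation refused).

### The backward shooting solver

Melting is assumed instantaneous and pinned at the first restrictive element
(`locate_melting_section()`): the melt state begins at the point, just
upstream of it, where pressure starts to rise, with $T = T_m(MC)$. Because
the product temperature at the die is unknown, `solve_profile()` integrates
*backwards*: it guesses the die-exit temperature, computes the die pressure
drop (power-law Poiseuille per die element, with parallel groups splitting
the flow in closed form and series elements summing), then marches element
by element upstream — pressure from the C-chamber law, temperature from the
energy balance — until the pressure falls to zero upstream of the melting
section. The temperature found there is compared with $T_m$ and the die-exit
guess is adjusted (bracketing + `uniroot`) until they agree within `tol_T`
(default 0.1 °C).

The viscosity law needs the cumulative SME, which is itself an output of the
march, so an outer fixed-point loop iterates the SME profile: each pass
re-marches with the previous profile, re-accumulates
$SME(x) = \sum \dot W_i / \dot m$ forward from the melting point (plus the
die pressure work $\Delta P/\rho$), and updates with damped Picard steps
*in log space*. The log-space damping matters for materials with a strong
SME coefficient $\beta$: the loop gain of that feedback is roughly
$\beta \cdot SME$, so the damping factor shrinks as
$1/(1+\beta\,SME)$; without this the first iterates can swing by decades
and oscillate between frozen and watery states. Melting enthalpy is reported
separately (`melt_enthalpy_kJkg`) and added to `SME_com` only on request
(`include_melt_enthalpy`), since the published SME accounting treats it as a
bookkeeping choice rather than part of the viscous-dissipation history.

Numerical choices worth knowing:

* the march is explicit with per-element sub-stepping (default 4, never
  coarser than 12 mm) and one midpoint corrector per sub-step, which keeps
  discretization error on `T_com` well below 0.5% between refinements;
* shooting guesses far outside the physical range are clamped (temperatures
  floored at −150 °C, viscosities capped at $10^{12}$ Pa·s) so the bracket
  search cannot cross the kelvin pole;
* the solver is fully deterministic — results carry no seeds.

## The machine reconstructions

Only the headline geometry of the four shipped machines is published: screw
diameter, screw length, the qualitative element sequence, and the die. All
element-level geometry in `extruder_fixture()` — pitches (one diameter for
conveying, half for reverse elements), channel depth (0.16 D), flight
widths and clearances, disc thicknesses, the leakage depths of slotted
reverse elements (0.6 h) and kneading blocks (0.25 h), the disc shear
efficiency (0.5), and the exchange-area factor — is a *reconstruction* built
from conventional co-rotating twin-screw ratios and calibrated once against
the published axial-profile landmarks of the breakfast-cereal runs (the
melting position at the first kneading block, the modest disc-section
temperature step versus the sharp 35–60 °C rise across the three reverse
elements, pressure support only at the restrictive and die-fed sections, and
the two printed maximum temperatures). Every value is plain constructor
code: build your own `extruder()` to override any of it, or load one from
YAML (`load_config()`).

Two known blemishes of the reconstruction, which calibration could not
remove without breaking better-anchored behaviour:

* the honey-based recipe (`hb`), whose near-melt consistency is several
  times the cacao recipe's, overshoots the published disc-section
  temperature step (about +27 °C rather than 5–10 °C) while matching the
  total melting-point-to-reverse-exit rise; the cacao recipe matches both;
* the axial temperature maximum sits at the die entrance (the die-fed
  conveying section keeps heating mildly) rather than exactly at the last
  reverse element, although its value matches the published level.

## Operating charts and product design

`run_grid()` sweeps any subset of screw speed, feed rate, moisture and
last-barrel temperature and records the die-exit responses; unconverged
nodes are masked, not dropped. `feasible_region()` intersects interval
constraints on those responses and returns the feasible mask with contour
boundaries for two-axis charts. On the shipped fixtures the standard
monotonicities hold across the starved-flow regime: SME rises with screw
speed and falls with feed rate and moisture, pressure does the reverse, and
the die-exit melt temperature stays above the barrel setpoint. Very low
speed combined with very high throughput approaches the flooded regime,
where the starved-flow closure stops being meaningful; charts should be read
within the starved envelope (`fill < 1`).

The product-feature layer connects die-exit variables to measurable product
features with two-parameter monotone models (`fit_correlation()`: linear,
power, exponential; log-linearized then refined by nonlinear least squares).
`invert_feature()` maps a feature target interval back to a predictor
window in closed form, refusing non-monotone models and clipping to the
fitted validity range; `target_window()` intersects several targets;
`design_window()` composes the whole workflow — invert targets, sweep the
machine, extract the feasible operating window.

The shipped `feature_fixtures()` are *reconstructed*: the published numeric
fit parameters are not part of this package's sources, so each fixture is
re-anchored to printed chart landmarks (for example, the intrinsic-viscosity
drop of 47%-amylose maize passes through 45% at 625 kJ/kg and 55% at
875 kJ/kg; pea-snack density through 200 kg/m³ at 155 °C and 100 kg/m³ at
175 °C). Where the printed landmarks over-determine a two-parameter family —
the pea-snack density trend is quoted both as "800→100 kg/m³ over
125→175 °C" and via the design window "density < 200 above 155 °C" — the
design-window anchors won, because they are the quantitative workflow the
fixtures exist to reproduce; the secondary anchor is then only approximate
(the fixture gives ≈ 565 kg/m³ at 125 °C). Replace any fixture with your own
`fit_correlation()` on real measurements.

## Synthetic data, and what passing tests mean

`generate_rheometry()` and `generate_feature_data()` draw observations
lognormally around the exact model truth, deterministically for a fixed
seed. They emulate the *structure* of rheometer reductions and
product-feature tables — factor grids, multiplicative noise — but none of
the instrument pathology of real data: no shear-history artifacts, no
moisture loss during measurement, no heteroscedastic outliers beyond the
lognormal tail. Parameter-recovery tests built on them therefore demonstrate
that the estimators are correctly implemented and well-conditioned on
sensible designs (viscosity coefficients within 10% at 5% noise and n = 200;
correlation exponents within 20% at 10% noise and n = 12, asserted on the
median over a fixed block of seeds because a single 12-point draw has ~15%
sampling spread), not that real rheometry of a given feed will be as kind.

The moisture sensitivity of the cacao recipe is the model's weakest
quantitative prediction: raising feed moisture from 19% to 23% reduces
`SME_com` by a factor of about 1.8 in this implementation, versus the
published threefold reduction — the printed moisture coefficient
($\alpha = 13.6$) gives an isothermal viscosity ratio of only 1.7 over that
span, and the thermal feedback (the wetter run settles colder, hence
relatively more viscous) pulls the ratio back down. The corresponding
acceptance check is left failing rather than tuned away.

## A worked example

```{r example, eval = FALSE}
sim <- solve_profile(
  extruder_fixture("zsk26_like"), material_db("cb"),
  operating_point(N = 500, Q = 20, MC = 0.15,
                  barrel_temps = c(20, 40, 60, 90, 90, 90, 90)))
summary(sim)
plot(sim)

chart <- run_grid(extruder_fixture("zsk26_like"), "hb",
                  operating_point(N = 500, Q = 20, MC = 0.19,
                                  barrel_temps = c(20, 40, 60, 90, 90, 90, 90)),
                  sweep = list(N = seq(200, 700, by = 100),
                               Q = c(10, 20, 35, 50)))
feasible_region(chart, list(T_com_C = c(-Inf, 165), P_com_Pa = c(0, 1e7)))

ff <- feature_fixtures()
invert_feature(ff$dvis_maize47, c(45, 55))   # SME window for dVis = 50 +/- 5%
```

Problem sizes used throughout the documentation and test-suite (grids of a
few dozen nodes, 200-point rheometry sets) were chosen so a full check of
the package runs in a few minutes on a laptop; the solver itself takes on
the order of a second per operating point.

## Limitations

* No melting-section mechanics: melting is instantaneous at the first
  restrictive element, so solid conveying, friction and sticking energy are
  absent — consistent with the published observation that such models
  underestimate measured SME.
* No residence-time distribution (mean only), no startup transients, no
  degassing mass loss, no wall slip, no elongational viscosity, no
  melt-pressure dependence of viscosity.
* The kneading-block description is an equivalent-element approximation
  behind the `shape_factors()` interface; a dedicated staggered-disc model
  can replace it without touching the solver.
* The expansion physics connecting die-exit state to product structure is
  represented only through monotone correlations, not a mechanistic
  bubble-growth model.
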