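# extrusim

One-dimensional global modelling of co-rotating twin-screw extrusion for
starchy and leguminous food melts — breakfast cereals, expanded starches,
legume snacks, bran-enriched wheat snacks — aimed at food process and
product engineers who want to screen operating conditions numerically before
running trials.

Extrusion cooking transforms a moist biopolymer feed through shear and heat;
what the product becomes (degree of starch depolymerization, protein
cross-linking, density, cell structure) is largely set by the die-exit melt
state: temperature `T_com`, cumulative specific mechanical energy `SME_com`
(kJ/kg), pressure `P_com`, and apparent viscosity `eta_com`. `extrusim`
predicts these from machine geometry and operating conditions, and links
them to product features, so the chain *conditions → melt state → product*
can be run forwards (simulation) and backwards (design).

## The model

* **Elementary screw flow.** Each screw element is a C-chamber obeying the
  locally-Newtonian law *Q<sub>v</sub> = A·Ω + (B/η)·ΔP/Δθ*, with drag (A)
  and pressure (B) coefficients from shallow-channel lubrication formulas;
  reverse elements have A < 0 (restrictive), kneading blocks are equivalent
  conveying elements with tip leakage. Dies are power-law Poiseuille
  channels (circular/slit, series/parallel).
* **Melt rheology.** Ostwald–de Waele power law *η = K·γ̇<sup>n−1</sup>*
  with *K = K₀·exp[E/R·(1/T − 1/T₀) − α(MC − MC₀) − β(SME − SME₀)]* and an
  empirical polynomial flow index n(T, MC, SME) clamped to [0.05, 1]. A
  database of published parameter sets ships with the package
  (`list_materials()`): maize starches (1–70% amylose), potato starch,
  two breakfast-cereal recipes, pea flour, wheat flour with bran.
* **Energy balance.** Per element: drag dissipation (channel + flight gap),
  Poiseuille (pressure-flow) dissipation, and Nusselt-closure barrel
  exchange (Nu = 20 by default); *C<sub>p</sub>ΔT = E<sub>v</sub> −
  E<sub>cd</sub>*.
* **Backward shooting solver.** Melting is instantaneous at the first
  restrictive element with T = T<sub>m</sub>(MC); the computation starts at
  the die with a guessed exit temperature, marches upstream to the melting
  point, and shoots until the melting-temperature boundary condition is met,
  with the SME–viscosity circularity resolved by a damped fixed-point
  iteration.
* **Design layer.** Operating-chart sweeps (`run_grid()`), feasible-region
  extraction (`feasible_region()`), and monotone feature correlations
  (`fit_correlation()`, `invert_feature()`, `design_window()`) that map
  product targets back to operating windows.

See the methods vignette (`vignettes/extrusion-model.Rmd`) for the full
account, including which geometry values are reconstructions and the known
limitations.

## A worked example

Simulate the cacao breakfast-cereal recipe on the 25.5 mm machine fixture at
15% moisture, 500 rpm, 20 kg/h:

```r
library(extrusim)
sim <- solve_profile(
  extruder_fixture("zsk26_like"), material_db("cb"),
  operating_point(N = 500, Q = 20, MC = 0.15,
                  barrel_temps = c(20, 40, 60, 90, 90, 90, 90)))
sim
#> <extrusion_sim> cb on zsk26_like: N = 500 rpm, Q = 20 kg/h, MC = 0.15
#>   T_com = 230.1 degC  SME_com = 469 kJ/kg  P_com = 10.92 MPa  eta_com = 316 Pa.s
#>   T_max = 230.1 degC, melting at 326 mm from die (T_m = 165.0 degC), MRT = 12.4 s
#>   converged: TRUE (15 shooting, 11 history iterations)
```

The melt turns molten 326 mm upstream of the die (at the first kneading
block, where pressure starts to rise), accumulates 469 kJ/kg of mechanical
energy, and reaches a maximum of 230 °C — hot enough that degradation is a
concern, which is exactly the kind of screening such a model is for.
`plot(sim)` draws the axial temperature/pressure/SME/viscosity profiles;
`summary(sim)` returns the one-row die-exit record.

Design direction — which SME window depolymerizes 47%-amylose maize starch
by 50 ± 5% (intrinsic-viscosity drop):

```r
invert_feature(feature_fixtures()$dvis_maize47, c(45, 55))
#> <predictor_interval> SME_com in [625, 875] for 'dVis_pct'
```

A command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("exec/extrusim", package="extrusim"))') \
  --machine zsk26_like --material hb --mc 19% --n-rpm 500 --q-kgh 20 \
  --barrel 20,40,60,90,90,90,90 --out profile.csv
```

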