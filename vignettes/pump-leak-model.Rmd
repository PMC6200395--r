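---
title: "A pump-leak model of neuronal chloride and volume homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A pump-leak model of neuronal chloride and volume homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumpleak)
```

## The model

`pumpleak` implements a biophysical single-compartment model of a neuron as
a cylindrical, semi-permeable membrane enclosing the three permeant ions
Na⁺, K⁺ and Cl⁻ and a pool of membrane-impermeant species X with mean
charge z. The extracellular space is an infinite bath with fixed
composition. Five mechanisms interact:

* **Passive leaks.** Each permeant ion carries an ohmic current
  `g (Vm − E_ion)` with a fixed specific conductance and the Nernst
  potential `E = (RT/zF) ln(C_o/C_i)`.
* **Na⁺/K⁺-ATPase.** The pump extrudes 3 Na⁺ for 2 K⁺ at an effective
  charge-flux rate `J_p = P (Na_i/Na_o)³` — a cubic function of the
  transmembrane sodium gradient, so the pump throttles itself as sodium is
  depleted. The pump can alternatively be frozen at a constant `J_p`
  (`pump_mode = "fixed"`), which isolates pump-mediated feedback in the
  experiments below.
* **KCC2 cotransport.** Electroneutral 1:1 K⁺/Cl⁻ cotransport with flux
  `J_KCC2 = g_KCC2 (E_K − E_Cl)`: chloride is moved using the potassium
  gradient until `E_Cl = E_K`, where the flux vanishes.
* **Membrane potential by charge difference.** `Vm = F (Na + K − Cl +
  zX)/(C_m A_m)` where `A_m = SA/w = 2/r` for a cylinder of fixed length.
  Unlike the GHK voltage equation, this requires no steady-state
  assumption, so arbitrary initial conditions are admissible. A GHK
  expression exists nowhere in the package; charge difference is the only
  voltage model.
* **Water flux.** `dw/dt = v_w p_w SA (Π_i − Π_o)` (osmotic mode), with
  volume changes expressed as radius changes at fixed cylinder length. In
  tension mode a Hookean membrane tension (Laplace pressure
  `H_p = 4π k_m (1 − r_a/r)` beyond the resting radius `r_a`, zero below
  it) enters as `dw/dt = v_w p_w SA (Π_i − Π_o − H_p/RT)`, so a sustained
  transmembrane osmotic difference of order 10 mM can be balanced
  mechanically. `H_p/RT` is evaluated numerically with RT in J/mol, which
  reproduces that ~10 mM scale at a ~9 % radius increase.

The concentration dynamics are

```
dNa/dt = −(A_m/F) [g_Na (Vm − E_Na) + 3 J_p]          − (1/w)(dw/dt) Na
dK/dt  = −(A_m/F) [g_K  (Vm − E_K)  − 2 J_p − J_KCC2] − (1/w)(dw/dt) K
dCl/dt = +(A_m/F) [g_Cl (Vm − E_Cl) + J_KCC2]          − (1/w)(dw/dt) Cl
```

with the last term the dilution by volume change. Impermeant species do
not cross the membrane; their concentration changes only by volume
(rescaled exactly each step, so impermeant moles are conserved to
round-off) or by explicit protocol events. The central derived quantity is
the chloride **driving force** `DF = Vm − E_Cl`, the electrochemical force
on Cl⁻ through an open Cl⁻-permeable (e.g. GABA_A) channel.

No homeostatic "sensor" of any kind is included: the physiological fixed
point, and the regulation of volume and chloride, emerge from the
pump-leak interaction alone.

## Units

Reported membrane parameters mix cm- and dm-based units. Internally one
canon is used throughout — dm, dm³ (= L), mol/L, V, s, S/dm², F/dm²,
C/(dm²·s) — and the constructors convert from the reporting units
(µS/cm², F/cm², µm, mM, pL). A single canon avoids silent 100× errors;
the `uS_cm2_to_S_dm2()` family makes every conversion explicit and
testable.

## Default parameterization

`make_default_cell()` builds a 10 µm diameter × 25 µm cylinder (≈1.96 pL)
in a bath of 145 Na⁺ / 3.5 K⁺ / 119 Cl⁻ / 29.5 X⁻ mM (297 mM, X⁻ valence
−1), with g_Na = 20, g_K = 70, g_Cl = 20, g_KCC2 = 20 µS/cm², pump-rate
constant P = 0.1 C/(dm²·s), C_m = 2 µF/cm², v_w = 0.018 dm³/mol,
p_w = 0.0015 dm/s, and an impermeant pool of mean charge z = −0.85.
Temperature is fixed at 310.15 K. These values give
an effective pump rate J_p = P(14/145)³ ≈ 9×10⁻⁵ C/(dm²·s) at the default
steady state, which is exactly what the Na⁺ flux balance
`g_Na(Vm − E_Na) = −3 J_p` requires.

From any admissible start the model settles to Cl⁻ 5.2, K⁺ 122.9, Na⁺
14.0, X 154.9 mM, Vm −72.6 mV, w 2.0 pL, E_Cl −83.8 mV, E_K −95.1 mV and
DF 11.3 mV.

### Initialization policy

Printed concentrations rounded to 0.1 mM cannot encode the ~6 µM net
charge offset behind Vm = −72.6 mV, so initial states are built exactly
electroneutral (Vm(0) = 0) at the target concentrations and the dynamics
are left to settle. The residual charge is absorbed by one designated
component: the impermeant pool for the default cell (`balance = "x"`), or
[K⁺]ᵢ when the initial chloride or impermeant concentration is itself the
manipulated variable (`balance = "k"`). The potassium choice matters:
balancing through the pool would change the impermeant moles, and since
steady-state volume is proportional to those moles, runs started from
different [Cl⁻]ᵢ would then converge to different volumes instead of the
common 2.0 pL.

## Integration scheme

A forward-Euler update with dt = 1 ms (single compartment): all fluxes and
dw/dt are evaluated on the pre-step state; ions are advanced including the
dilution term; protocol source terms are applied; the volume and radius
are updated; and impermeant concentrations are rescaled by the exact
volume ratio. Intracellular concentrations are thus updated again after
the volume change within each step. A state with any negative
concentration aborts the run naming the ion and time — clamping would
silently violate conservation. Halving dt changes the settled Vm by well
under 10⁻³ mV (tested).

Steady state is detected from windowed finite-difference rates: the run
stops once max |d[ion]/dt| < 10⁻⁶ mM/s and |dw/dt|/w < 10⁻⁹ s⁻¹ hold
across two consecutive windows of 1000 membrane steps (all four
thresholds configurable in `sim_config()`).

## The steady-state solver

`solve_steady_state()` computes fixed points directly by damped Newton
iteration on (log Na, log K, log Cl, log w, Vm) — the log parameterization
keeps concentrations and volume positive — with five constraints: the
three flux balances above with dw/dt = 0, osmotic balance
`Π_i = Π_o` (plus the tension or imposed-offset term where configured),
and consistency of Vm with the charge-difference relation. The impermeant
content enters as an amount of moles and a mean charge; the steady-state
volume follows from them. A watchdog accepts occasional non-monotone
Newton steps (pure damping can stall against a ridge of the residual
norm), with a Levenberg–Marquardt fallback; a failed solve retries after
briefly integrating toward the attractor. Solved roots are classified by
the eigenvalues of the reduced (Na, K, Cl, w) Jacobian, and dynamically
unstable roots are refused with a `pumpleak_no_steady_state` condition.

The verifiable contract — asserted in the test suite over random parameter
draws within ±50 % of the defaults — is agreement of solver and
time-integrated fixed point to < 10⁻² mV and < 10⁻² mM, the dots-on-lines
property of the steady-state figures. `sweep_steady_state()` walks a
parameter grid with warm starts outward from the default, flagging (never
dropping) failed points.

One subtlety found while classifying roots: with the pump fully off the
default composition (internal mean charge −0.85 against external
impermeant charge −1) still admits a *stable* Donnan root at about five
times the resting volume. The familiar "pump off ⇒ the cell swells
without bound" behaviour is, in this parameterization, an hours-long
transient toward that distant equilibrium rather than a true divergence —
the swelling, depolarization and full recovery of the pump off/on
protocol are what the tests assert.

## Protocols

Timed events (`ev_*` constructors, or YAML files via `load_protocol()`)
drive the in-silico experiments:

* `ev_pump_ramp()` — exponential approach of P toward 0 or its restored
  value with τ = duration/5; the default 15 min duration sits inside the
  10–20 min window over which ATPase blockade and its reversal act
  pharmacologically. A zero-duration ramp is a step change.
* `ev_inject()` — impermeant-anion influx at a constant rate, either in
  mM/s relative to the instantaneous volume (the conventional description)
  or in mol/s (`unit = "mol_s"`), which makes the total added moles exact
  despite the volume growing during injection; registry experiments use
  the molar form to land end-state mean charges (−1, −0.93) exactly.
  Negative rates model removal. Injected amounts join the pool by the
  concentration-weighted mean-charge rule.
* `ev_ramp_charge()` — linear interpolation of the pool's mean valence at
  fixed impermeant moles, imitating a charge-carrying transmembrane
  reaction (implemented as a continuous valence change of the designated
  pool, not as discrete species swaps).
* `ev_bath_swap()` — instantaneous, osmo- and electroneutral exchange of
  bath Cl⁻ for bath X⁻ (the bath is infinite; no extracellular dynamics).
* `ev_fix_pump()`, `ev_volume_mode()`, `ev_set_param()`,
  `ev_param_ramp()` — mode switches and parameter changes; g_KCC2 ramps
  are integrated natively, other conductance ramps run piecewise-constant
  over 25 sub-segments.

Injection is applied as a source term after the transmembrane updates
within the same Euler step; the ordering is an O(dt) choice verified by
step halving.

## The virtual dendrite

`chain_model()` links n equal-length cylindrical compartments (default
10 × 10 µm, radius 0.5 µm) without branching; ends are sealed. Na⁺, K⁺
and Cl⁻ — never impermeant anions — move between neighbours by the
one-dimensional Nernst–Planck flux

```
J = −D [ (zF/RT) · (Cᵢ+Cᵢ₊₁)/2 · (Vmᵢ−Vmᵢ₊₁)/dx + (Cᵢ−Cᵢ₊₁)/dx ]
```

with `dx = (hᵢ+hᵢ₊₁)/2` and each compartment's own charge-difference
voltage in the drift term (no cable/axial-resistivity term). All
interface fluxes within a step are evaluated on the pre-step state. Two
discretizations are provided: `"per_length"` divides each side's
concentration update by its own compartment length (exactly
mole-conserving only when geometries are identical — used for figure
reproduction), and
`"conservative"` routes the flux through the shared interface area
`π·min(rᵢ, rᵢ₊₁)²` (the radius choice when neighbours differ is not
dictated by the flux law; the smaller cross-section is the geometric
bottleneck) with per-volume normalization, conserving moles to round-off.
Both are tested; the conservation tests use the conservative mode.

### Time stepping and the two-rate scheme

Electrodiffusive charge exchange between 0.5 µm compartments relaxes with
a ~4 µs time constant, so the chain is integrated at dt = 10⁻³ ms
(forward-Euler substeps become unstable near 5×10⁻³ ms, consistent with
that stiffness estimate). Because the membrane fluxes evolve on ≥ ms
scales, the integrator also offers a two-rate scheme: electrodiffusion
and voltage updates every substep, membrane/volume physics every
`membrane_every` substeps. The figure-scale runs use dt = 2×10⁻³ ms with
`membrane_every = 50` (membrane step 0.1 ms), which keeps a 2× stability
margin and matches the single-rate fine-dt result to < 10⁻² mV over a
validation segment (tested); chain steady states are reached within
60–210 s of simulated time from solver-derived initial states.

## What the registry reproduces

`run_experiment()` exposes deterministic reproductions of the model's
headline experiments; `scripts/acceptance.R` recomputes the quantitative
ones end to end. Highlights: common convergence of [Cl⁻]ᵢ and volume from
four chloride initializations; pump off/on collapse and full recovery;
KCC2 ramps that move E_Cl with only ~2 mV of Vm change; amount-only
impermeant manipulations that leave E_Cl, E_K, Vm and DF untouched while
volume shifts; mean-charge ramps that shift E_Cl, E_K and Vm together
leaving |ΔDF| ≈ 0.16 mV (and exactly 0 with a fixed pump — the DF shift
is entirely pump-mediated, via sodium); and local KCC2/impermeant
manipulations in the dendrite whose spatial spread is governed by the
chloride diffusion constant. Where the underlying schedule is not
numerically specified (injection rates, ramp windows), the registry
defaults are sized so the described end states are reached — e.g. the
amount of valence −1.5 species needed to bring the pool mean charge from
z₀ to z_t at fixed other moles, `Δn = n_X (z_t − z₀)/(v − z_t)` — and all
are configurable.

One reproduction note: at g_KCC2 = 370 µS/cm² the fully settled fixed
point has E_Cl ≈ −94.0 mV. The chloride flux balance pins
`E_Cl − E_K = (g_Cl/g_KCC2)·DF ≈ 1.05 mV` there, so a settled value of
−93.2 mV is not consistent with this model's equations at that
conductance; the registry reports the settled value.

## Problem sizes and runtime

The default single-compartment runs integrate 3.6×10⁶ steps (1 h at
dt = 1 ms) in under a second of wall time; solver calls take
milliseconds. The dendrite experiments integrate (0.6–2)×10⁸ substeps and
complete in a few minutes each. The solver-vs-integrator property uses 20
random parameter draws; conservation properties run 10⁴–10⁵ steps.

## What the synthetic conditions do and do not show

All inputs are parameter configurations; there is no external data and no
randomness in the model itself. The tests therefore demonstrate internal
correctness (conservation, flux-balance closure, solver/integrator
equivalence, discretization robustness) and reproduction of the model's
reference behaviour — not the fidelity of that model to real neurons.
Known idealizations: a single cylindrical compartment with lateral-area
scaling only (no end caps, since length is fixed and A_m = 2/r is then
exact); no bicarbonate and no GABA_A conductance; no voltage-gated
channels or action potentials; KCC2 kinetics linear in E_K − E_Cl with a
fixed conductance; the bath is infinite; water moves only osmotically (a
cotransporter water flux would change kinetics, not the fixed points);
and no Q10/temperature dependence. Within those limits, the package's
claims are the ones its tests compute.
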