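---
title: "A reduced-order model of haemodynamics in aortic dissection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of haemodynamics in aortic dissection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and intent

`aorta0d` is a lumped-parameter (0D) simulator of blood flow in a Stanford
type B aortic dissection: a descending aorta split by an intimal flap into
a narrow true lumen (TL) and a larger false lumen (FL) that communicate
through a primary entry tear, an exit tear, and a variable number of small
secondary tears. The package couples three sub-models —

* a time-varying elastance left heart with diode valves,
* three-element Windkessel (RCR) outlet models for the distal vasculature,
* a configurable resistive network standing in for the aortic geometry —

and provides the surrounding machinery a study of this kind needs: cyclic
convergence control, pressure–volume (PV) loop and stroke-work
quantification, an elastance tuning loop that matches a target cardiac
output, measurement-versus-simulation comparison statistics, and a
synthetic generator for PC-MRI-like inflow and per-lumen flow
"measurements".

The deliberate central simplification is that the 3D vascular geometry is
replaced by a 0D compartment network. Everything that depends on the
spatial flow field — wall shear stress, velocity jets, local pressure
concentrations — is out of scope. What the network surrogate *can*
represent, and what this package quantifies, are bulk quantities: lumen
flow splits, branch perfusion, trans-septal pressure differences, afterload
as felt by the heart, and their sensitivity to the tear topology.

## Units

All internal quantities use a g–mm–s system: pressure in g/(mm·s²)
(numerically pascals), flow in mm³/s, resistance in g/(mm⁴·s), compliance
in mm⁴·s²/g, elastance in g/(mm⁴·s²), and energy in g·mm²/s² (10⁻⁹ J).
The mmHg conversion constant is defined once as `MMHG = 133.32`; this value
(rather than the physical 133.322) keeps the packaged atrial preload of
533.320 g/(mm·s²) at exactly 4 mmHg to the precision the parameter table
uses.

## Waveforms

A `waveform` is one period of a sampled periodic signal: strictly
increasing times starting at 0, linear interpolation between samples, and
periodic wrap-around. Cycle means use the trapezoid rule on the periodic
extension, which is exact for piecewise-linear signals — the natural
convention for 25-phase gated PC-MRI data (52 ms temporal resolution at a
1.3 s cardiac period). Pulse is defined as peak minus minimum over one
period, the convention used for pulse pressure.

## Three-element Windkessel outlets

Each branch outlet is the standard RCR element: proximal resistance
`Rp` in series with a parallel pair of compliance `C` and distal
resistance `Rd`, grounded at a reference pressure `Pd` (default 0; the
parameter tables do not state a value and zero ground is the common
convention). The interface pressure seen by the network is
`P = Rp·Q + Pc`, with the mid-pressure obeying
`C·dPc/dt = Q − (Pc − Pd)/Rd`. The packaged registry carries the 18 tuned
outlet rows (right/left carotid and subclavian, hepatic, splenic, coeliac,
mesenteric, renal, sacral, iliac vessels).

The state is advanced by backward Euler, which is unconditionally stable
and — crucially — makes the stepped element *affine* in the flow:
`Pc' = a + b·Q`. Two analytic oracles guard the implementation: free decay
must follow `exp(−t/(Rd·C))` with first-order convergence in `dt`, and at
cyclic convergence the cycle-mean interface pressure must equal
`mean(Q)·(Rp + Rd) + Pd` (no net capacitor charge over a period).

## The lumped heart

The left heart is a constant atrial pressure source `P_LA` feeding,
through a mitral valve (resistance + inductance + diode), a time-varying
elastance ventricle, which ejects through an aortic valve of the same
structure. Ventricular pressure follows `P_LV = E(t)·(V_LV − V_u)`.

The elastance activation is piecewise cosine: a half-cosine rise from
`E_min` to `E_max` over `t_max`, a half-cosine fall back over `t_relax`,
and `E_min` for the remainder of the cycle. The shape is C⁰-continuous,
periodic, and matches the two timing parameters the parameter table
provides exactly; the published trigonometric form it stands in for is not
printed in full anywhere we could verify against, so this surrogate is
documented rather than claimed identical.

A viscous ejection loss `ΔP = k_LV·P_LV·Q_LV` is applied in series with
the aortic valve. With `k_LV` in s/mm³ this product has pressure units,
i.e. the instantaneous ventricular resistance is `R_LV = k_LV·P_LV` — the
only dimensionally consistent reading of the parameter table.

### Valve switching

Valve handling is the one place where two defensible conventions genuinely
diverge, and the package mixes them deliberately:

* **Aortic valve** — ideal diode: it closes when the solved flow would
  reverse. Because the viscous-loss resistance `k_LV·P_LV` dominates the
  valve inductance (`L/R` of order 1 ms), the flow has already decayed to
  near zero when this happens; closure is instant-like and back flow never
  occurs. Closing instead on the first adverse pressure gradient gives the
  same macroscopic behaviour here but, implemented naively, chatters
  against the reopening test.
* **Mitral valve** — closes instantly on an adverse pressure gradient
  (`P_LV` rising through `P_LA`). This matters: the mitral branch is
  heavily underdamped (`R_mv ≈ 3.9×10⁻⁷`, `L_mv ≈ 1.3×10⁻⁵`), and a pure
  flow-reversal rule lets inertia overfill the ventricle far beyond the
  intended end-diastolic volume. With gradient closure the end-diastolic
  volume is pinned at the diastolic equilibrium `P_LA/E_min ≈ 130 mL`,
  exactly the packaged end-diastolic volume — which is how the parameter
  set was evidently constructed.

Within a step, valve states are frozen during the small Newton solve of
the flow equations and re-evaluated afterwards (at most a handful of
switching passes); flow is clamped to exactly zero on closure, so
`Q ≥ 0` holds identically, never just approximately.

Instant closure has an energetic consequence: the kinetic energy stored in
a valve inductor is discarded at each closure. The cycle energy audit in
the test suite therefore balances stroke work against delivered aortic
work plus valve, viscous and inductive terms; without the inductive term
the books still close within 2 % (the discarded energy is ~1 % per cycle).

## The network surrogate

The aortic domain is a graph of nodes (pressures) and elements (flows):

* **Segments** — Poiseuille resistances `8μL/(πr⁴)` from a radius and
  length, with optional inertance and nodal compliance (both default 0:
  the rigid, incompressible limit, consistent with treating all
  compliance as lumped in the outlets).
* **Tears** — short cylindrical channels through the septum with the
  tear's effective circular diameter `2·sqrt(A/π)` and a 2 mm channel
  length (a typical septum thickness; no measured value is available).
  An optional quadratic orifice loss `ρQ|Q|/(2·C_d²·A²)` can be enabled
  per configuration; it is off by default because the Poiseuille channel
  already reproduces the flow-split behaviour of interest and keeps the
  per-step system linear.
* **Outlets** — Windkessel elements from the registry, attached through
  short branch stubs.
* **Inlet** — either a prescribed flow waveform or the heart model coupled
  monolithically (the network presents itself to the heart as the exact
  affine map `P_inlet = c0 + c1·Q`, read off the factorised system).

The packaged fixtures build four variants of the same anatomy: an
undissected single descending chain; a baseline dissected model with TL
and FL chains of six segments each, entry (135 mm²) and exit (68 mm²)
tears plus 15 secondary tears (17 in total, mostly in the visceral
region); a maximal variant with two additional thoracic tears (19); and a
minimal variant with only entry and exit (2). Branches perfused from the
false lumen (left renal, inferior mesenteric, medial sacral) take off from
the FL chain. Secondary tear areas are not measurable from the imaging
this model descends from; 20 mm² per tear is an assumption, configurable
in the fixture.

Two geometric parameters were calibrated once and then frozen: the TL and
FL chain radii (5.1 mm and 7.0 mm). Their fourth-power resistance ratio
sets the thoracic flow split at roughly 22/78 TL/FL, inside the measured
(21/79) to simulated (25/75) range of the study this emulates. No other
quantity was adjusted toward a target.

### Time stepping and convergence

Each step eliminates all element states by backward Euler, leaving a
nodal flow-balance system that is linear unless orifice losses are on; the
matrix is assembled and factorised once per run and each step reduces to a
right-hand-side build and a back-substitution (with a Newton relinearisation
loop in the orifice case). `dt` defaults to 1 ms and may not exceed it.

Start-up transients are the practical difficulty: outlet time constants
`Rd·C` reach ~28 s for the carotids, hundreds of cardiac cycles if started
cold. Two measures keep runs short:

1. **DC initialisation** — a purely resistive solve under the mean inflow
   fixes every capacitor at its exact periodic cycle-mean before stepping
   begins (for a linear network the periodic means *are* the DC solution).
2. **Aitken acceleration** — the cycle-end capacitor states of three
   consecutive cycles are extrapolated componentwise (Aitken Δ²) onto the
   fixed point of the linear cycle map, repeated every three cycles.

Convergence is declared when every outlet's cycle-mean pressure and flow
change by less than `tol` (default 10⁻³, matching the residual-control
order of magnitude customary for such simulations) between consecutive
cycles. All packaged fixtures converge in 5–6 cycles, inside the 3–7
cycle range reported for the full-scale study.

Mass conservation is structural: with rigid segments the solved outlet
flows sum to the inflow at every instant to solver precision, and the test
suite asserts the cycle-mean identity to 0.1 %.

A note on comparing trans-septal pressure gaps between variants: adding
the two thoracic tears to the 17-tear baseline moves station gaps at the
10⁻³ mmHg level, below what a 10⁻³ relative cyclic tolerance resolves.
Comparisons of such micro-scale gaps therefore carry an absolute floor of
0.005 mmHg; the physiologically meaningful contrasts (2 versus 17 tears:
0.2–0.8 mmHg collapsing to under 0.05 mmHg) are strict.

## Elastance tuning

`tune_elastance()` adjusts `E_max` and `t_max` until the converged heart
simulation reproduces target mean and peak aortic flow within 5 % — the
termination criterion used when such models are calibrated against
measured PC-MRI flow. `E_max` predominantly moves the mean output and
`t_max` the systolic peak, but the coupling is strong, so the loop uses
damped (factor 0.5) two-variable secant steps: a finite-difference
Jacobian at the first iterate, Broyden rank-one updates afterwards, a cap
of 30 iterations, and a hard failure carrying the full evaluation trace if
the cap is hit. Against the packaged systemic afterload and the default
synthetic inflow targets the loop terminates in about seven evaluations.

The packaged single-Windkessel afterload (`Rp 0.008`, `C 11`, `Rd 0.162`)
was chosen once to give a physiologic operating point at a 4.4 L/min
cardiac output: ~92 mmHg mean pressure, ~130/65 mmHg aortic pressure
range, systemic decay time `Rd·C ≈ 1.8 s`.

## Comparison statistics

The comparison module is deliberately plain arithmetic, kept pure and
reproducible: signed relative errors `100·(sim − meas)/meas` per station
and lumen, three-station averages, and per-lumen fractions of total flow.
Fractions use the ratio-of-means convention (mean lumen flow over mean
total flow across stations); the mean-of-ratios variant is computed
alongside. Display rounding (one decimal for errors, integers for
fractions) mirrors how such tables are reported, while unrounded values
stay in the data model. On the packaged measurement set the computed
simulated FL fraction is 75.3 % (38 700/51 400), which rounds to 75; the
value is reported as computed rather than matched to any published
rounding.

## The synthetic generator

`generate_inflow()` produces a half-sine systolic pulse (default systolic
fraction 0.33 of a 1.3 s period) with an optional negative early-diastolic
lobe, sampled at 25 gated phases and renormalised so the sampled net
volume is exactly the stroke volume (default 94 mL). It emulates the three
recoverable features of a measured aortic inflow — stroke volume, period,
and qualitative shape — and nothing else: no beat-to-beat variability, no
measurement noise on the waveform, no velocity-encoding artefacts. The
default has no back flow, consistent with what a diode-valve heart model
can produce; `backflow_fraction = 0.03` approximates the slight
early-diastolic reversal seen in measured traces.

`generate_measurements()` perturbs the packaged per-lumen station means by
seeded multiplicative Gaussian noise and recomputes totals as TL + FL.
Passing tests on these synthetic inputs therefore demonstrates the
*machinery* — conservation, convergence, arithmetic, directional
sensitivity — not agreement with any particular patient.

## Problem sizes used by the tests

The suite runs every network fixture at `dt = 1 ms` (1300 steps per cycle,
5–6 cycles), one baseline run at `dt = 0.5 ms` for the refinement check,
and heart simulations of 7–9 cycles; the tuning tests perform on the order
of ten heart simulations each. These sizes were chosen as the coarsest
grids at which the stated tolerances (0.1 % conservation, 0.5 % `dt`
sensitivity, 0.2 % periodic-mean identity) hold with an order-of-magnitude
margin.

## Known limitations

* Rigid 0D compartments: simulated per-lumen waveform *amplitudes* are
  less meaningful than their means; wall and septum compliance would
  require additional state per segment (supported via `L`/`C` fields but
  not calibrated).
* The tear topology is anatomically schematic — six matched stations with
  tears assigned by region, not by imaged position.
* No baroreflex or autoregulation: boundary conditions are identical
  across variants by design, which is exactly what makes the stroke-work
  and tear-sensitivity contrasts interpretable, but means absolute
  pressures under strongly altered afterload should not be over-read.
* Stroke work is reported in joules from the model's own PV loop
  (order 1.5–2 J per beat); only *relative* changes between variants are
  comparable across models of different fidelity.

## A worked example

```{r}
library(aorta0d)

inflow <- generate_inflow()                       # 94 mL at 1.3 s
topo <- build_network(fixture_configs()$dissected_baseline)
sol <- simulate_network(topo, inflow)

lumen_flow_split(sol, 1)                          # thoracic TL/FL split
build_comparison_report(sol, load_lumen_measurements())

m <- waveform_metrics(inflow)
tuned <- tune_elastance(m$mean, m$peak,
                        load_single_rcr_afterload(),
                        load_table5_heart("dissected"))
stroke_work(pv_loop(tuned$solution))$work_J
```
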