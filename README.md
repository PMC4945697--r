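# aorta0d

Reduced-order (0D) modelling of blood flow in aortic dissection.

In a Stanford type B dissection an intimal tear splits the descending
aorta into a narrow **true lumen** (TL) and a larger **false lumen** (FL),
separated by a septum perforated by a primary entry tear, an exit tear and
a variable number of small secondary tears. Two clinical questions drive
this package: how the flow distributes between the lumina and the branch
vessels, and how much extra work the dissection imposes on the left
ventricle. Both are bulk (0D) quantities, and `aorta0d` computes them with
a fully lumped model — for researchers in computational haemodynamics who
want a fast, testable surrogate for (or boundary-condition generator
around) full 3D CFD.

## The model

Three coupled components, all in a canonical g–mm–s unit system
(1 mmHg = 133.32 g·mm⁻¹·s⁻²):

* **Left heart.** Time-varying elastance ventricle
  `P_LV(t) = E_LV(t)·(V_LV(t) − V_u)` with a piecewise-cosine activation
  between `E_min` and `E_max`, a constant atrial preload `P_LA`, diode
  valves with resistance and inductance, and a viscous ejection loss
  `ΔP = k_LV·P_LV·Q_LV`. The area of the pressure–volume loop is the
  stroke work.
* **Windkessel outlets.** Each of the 18 branch outlets is a three-element
  RCR model, `P = R_p·Q + P_c`, `C·dP_c/dt = Q − (P_c − P_d)/R_d`, with a
  packaged registry of tuned parameters.
* **Dissection network.** Nodes and resistive elements: Poiseuille
  segments `R = 8μL/(πr⁴)` for the trunk and both lumina, septal tears as
  short channels with effective diameter `d = 2·sqrt(A/π)`, outlets from
  the registry, and an inlet driven by a measured-like flow waveform or by
  the heart model coupled monolithically. Backward-Euler stepping with
  Newton iteration, a DC (mean-flow) initialisation and cycle-to-cycle
  Aitken acceleration reach periodic convergence in 5–6 cardiac cycles.

Four packaged anatomical variants: `undissected`, `dissected_baseline`
(17 tears: entry 135 mm², exit 68 mm², 15 secondary), `maximal_tears`
(19) and `minimal_tears` (entry and exit only).

## Worked example

```r
library(aorta0d)

inflow <- generate_inflow()        # 94 mL stroke volume over a 1.3 s cycle
topo   <- build_network(fixture_configs()$dissected_baseline)
sol    <- simulate_network(topo, inflow)
sol
#> <network_solution> 'dissected_baseline': 6 cycles to convergence,
#>   inlet mean 72308 mm^3/s, outlet mean sum 72308 mm^3/s

lumen_flow_split(sol, 1)           # proximal thoracic station
#> $Q_TL 12390   $Q_FL 42714   $total 55104
#> $fraction_TL 22.5   $fraction_FL 77.5
```

The simulated descending-aortic total of 55.1 cm³/s and a 22/78 TL/FL
split land inside the measured range (50.3–55.6 cm³/s; 21 % TL). Feeding
the solution and the packaged PC-MRI station means to the comparison
module:

```r
build_comparison_report(sol, load_lumen_measurements())
#>  location lumen simulated measured rel_error
#>  proximal total   55104.1    55600      -0.9
#>    medial total   55104.1    53800       2.4
#>    distal total   55104.1    50300       9.6
#>  ...
#> Lumen fractions: measured FL 79% / TL 21%, simulated FL 78% / TL 22%
```

Tuning the heart model so its output matches the inflow targets, then
reading off the ventricular workload:

```r
m <- waveform_metrics(inflow)
tuned <- tune_elastance(m$mean, m$peak,
                        load_single_rcr_afterload(),
                        load_table5_heart("dissected"))
#> tuned in 5 evaluations: mean err 0.07%, peak err 4.83%  (both within 5%)
stroke_work(pv_loop(tuned$solution))$work_J
#> [1] 1.50
```

Re-running the tuning against an afterload with all resistances scaled by
1.2 — the lumped analogue of the extra hydraulic load a dissection septum
imposes — raises the stroke work at the same cardiac output (1.50 J →
1.78 J here, +19 %).

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","aorta0d.R",package="aorta0d"))')" \
  simulate --variant dissected_baseline --outdir out
```

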