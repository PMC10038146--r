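# gorgflow

Multiscale flow and plankton capture in gorgonian cylinder arrays.

Gorgonian corals (sea fans) feed by straining ambient currents through
three nested tiers of roughly cylindrical structures: colony branches,
polyp tentacles, and the pinnules on each tentacle. Each tier behaves
either as a *leaky rake* (water passes between the elements) or as a
*solid plate* (water deflects around the array), depending on the element
Reynolds number `Re = rho D U / mu` and the gap-to-diameter ratio `G/D`.
`gorgflow` quantifies that transition and its consequence for feeding:

* **Unit-cell geometry** — an infinite periodic array of finite-height
  cylinders represented by one cylinder in a periodic cell, at the
  branch, tentacle or pinnule scale, optionally decorated with idealized
  eight-tentacled polyps (`branch_cell()`, `pinnule_cell()`,
  `polyp_model()`, `cell_obstacles()`).
* **Flow solver** — steady (or time-marched) incompressible laminar flow
  on a graded staggered grid with periodic sides, uniform inflow,
  zero-pressure outflow and free-slip top/bottom
  (`solve_steady()`, `solve_unsteady()`).
* **Leakiness** — `Le = Q / (U A)` over the gap window, or the
  line-average of streamwise velocity from the cylinder axis to the cell
  edge (`leakiness_gap_flux()`, `leakiness_line()`, `leakiness_sweep()`).
* **Plankton capture** — agents advected by the tiled flow field with
  unbiased Brownian motion (Euler-Maruyama), captured on contact with any
  obstacle surface, summarized over replicates
  (`run_capture_experiment()`, `step_agents()`, `detect_capture()`).
* **Dimensionless reports** — Reynolds and Peclet numbers per level and
  substance, porosity coefficient `Lambda = Le F / U`, morphometric
  G/D and H/D summaries (`reynolds()`, `peclet()`, `dimensionless_report()`,
  `morphometric_summary()`).
* **Fixtures and I/O** — analytic velocity fields for exact testing,
  synthetic morphometric tables, VTK field output, STL obstacle export,
  YAML-configured pipeline runs (`analytic_field()`, `write_field()`,
  `run()`).

## Worked example

Leakiness of a branch-scale array with two-diameter gaps in a slow
feeding current (nominal Re = 2):

```r
library(gorgflow)

cell <- branch_cell(2)      # D = 0.1 cm, cell width 0.3 cm, domain 10 x 4 cm
fld  <- solve_steady(cell, U = 0.2)
fld
#> Flow field: branch cell, G/D = 2, U = 0.2 cm/s (Re = 1.9, nominal 2)
#>   grid 24 x 57 x 66, steady solve: converged (residual 9.4e-05, 19900 iterations)

leakiness_line(fld)
#> Leakiness (line_average metric): Le = 0.3381
leakiness_gap_flux(fld)
#> Leakiness (gap_flux metric): Le = 0.5281  [Q = 0.02112 cm^3/s, A = 0.2 cm^2, U = 0.2 cm/s]
```

Only a third of the free-stream flux that an inviscid flow would carry
actually threads the mid-height gap at this Reynolds number — the array
is mostly a solid plate, and the published line-average value for this
configuration is 0.33. Raising the speed to `U = 1` (nominal Re = 10)
lifts the line-average leakiness to about 0.65: the same morphology
becomes a leaky rake.

Capture experiments follow the same pattern:

```r
params <- agent_params(n_reps = 10, seed = 1)
cap <- run_capture_experiment(g_over_d = c(1, 1.75, 3), Re = 8,
                              params = params)
cap$summary   # mean and SD of the captured fraction per gap ratio
plot(cap)
```

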