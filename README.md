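# adhesim

Single cells are small and round on soft extracellular-matrix substrates,
spread out on stiff ones, and crawl up stiffness gradients (durotaxis).
`adhesim` is an R implementation of a hybrid cellular Potts / finite-element
model in which all of these behaviors emerge from one ingredient: the
mechanosensitive turnover of focal adhesions (FAs), modeled as clusters of
integrin catch-slip bonds loaded by cell traction at a substrate-stiffness-
dependent rate.

For computational cell biologists and biophysicists who want a compact,
scriptable testbed for stiffness-sensing mechanisms: substrate stiffness
field generators, a plane-stress FEM of the substrate, per-site adhesion
kinetics, morphometric analysis, experiment presets and a CLI.

## The model in brief

- **Cell shape (CPM):** occupied lattice sites evolve by boundary copy
  attempts, accepted with probability `min(1, exp(-dH/T))`. Besides
  interface tension, an area constraint and a substrate-adhesion energy,
  retractions pay a detachment barrier `eps * N * w` proportional to the
  local adhesion's bond count `N`.
- **Adhesions:** per-site clusters with per-bond unbinding rate
  `koff(f) = k_s exp(f/F_slip) + k_c exp(-f/F_catch)` (catch-slip; lifetime
  peaks near 30 pN), constant-rate binding from a finite integrin pool, and
  a nascent threshold `N0 = 50` below which clusters disassemble.
- **Traction:** first-moment-of-area model, `Fs = mu * (rbar - r)` towards
  the centroid; forces build up as `dF/dt = E_eff * ell * v0 * (1 - F/Fs)`,
  faster on stiffer substrates — the stiffness sensor.
- **Stress feedback (model variants 2.1/2.2):** a bilinear-quad plane-stress
  FEM gives the hydrostatic substrate stress; its tensile part reinforces
  adhesions via `w = 1 + p*g/(sigma_h + g)` (2.1: detachment energy,
  2.2: stall force; variant 1: no feedback).

One Monte Carlo step represents 10 s; the default lattice is 2.5 um.

## Worked example

```r
library(adhesim)

soft  <- run_simulation(sim_config(substrate_homogeneous(1,  extent = 300),
                                   variant = "1", n_mcs = 2000, seed = 7))
stiff <- run_simulation(sim_config(substrate_homogeneous(50, extent = 300),
                                   variant = "1", n_mcs = 2000, seed = 7))
soft
#> <sim_result> model 1, 2000 MCS, seed 7
#>   final area 2862 um^2, eccentricity 0.68, 36 clusters
stiff
#> <sim_result> model 1, 2000 MCS, seed 7
#>   final area 7488 um^2, eccentricity 0.30, 886 clusters
```

The soft-substrate cell stays near its initial ~2500 um^2 (its adhesions
never mature: force builds too slowly to engage the catch bonds before
nascent clusters decay), while at 50 kPa adhesions stabilize and the cell
ratchets out to ~7500 um^2 — a 2.6-fold increase. The 36 "clusters" on the
soft substrate are the current step's freshly seeded protrusions, all of
which will disassemble. Pooled cluster sizes, spreading
kinetics and trajectories are summarized by `cluster_stats()`,
`fit_spreading_erf()` / `fit_spreading_exp()` and `durotaxis_speed()`:

```r
m <- stiff$morphometrics
fit_spreading_erf(m$time_s / 60, m$area_um2)[c("A50", "t50", "tau")]
#> $A50
#> [1] 3735.547
#> $t50
#> [1] 1.275505   # minutes; A(t50) = A50, half the final area
#> $tau
#> [1] 12.43377
```

On a 20 Pa/um stiffness gradient (1 kPa at the left edge, start at 6 kPa)
the same model durotacts:

```r
sub <- substrate_linear_gradient(E_min = 1, slope = 20, extent = c(500, 250))
run <- run_simulation(sim_config(sub, variant = "1", n_mcs = 3000, seed = 1,
                                 cell_center = c(250, 125)))
durotaxis_speed(trajectory_of(run))$slopes
#> [1] 2.18  # um/h, up-gradient
```

`preset()` bundles the four study designs (spreading, elongation,
motor_velocity, durotaxis) with their sweep axes and replicate counts;
`expand_runs()` derives seeded per-run configurations; `write_run()` emits
`morphometrics.csv`, per-snapshot cluster tables, snapshot grids/PNGs and
`run_meta.json`. A thin command-line front end lives at `inst/cli/adhesim`
(`run`, `sweep`, `preset`, `analyze` subcommands; YAML configurations via
`load_config()` / `save_config()`).

See the methods vignette (`vignettes/model-mechanics.Rmd`) for the model's
assumptions, parameter table, calibration rationale, numerical choices and
known limitations.

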