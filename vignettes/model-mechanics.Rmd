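---
title: "Mechanosensitive focal-adhesion dynamics in a hybrid CPM-FEM cell model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanosensitive focal-adhesion dynamics in a hybrid CPM-FEM cell model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhesim)
```

## The model

`adhesim` simulates a single adherent cell on a flat elastic substrate.
Three layers are coupled:

1. **Cell shape** -- a cellular Potts model (CPM) on a square lattice
   (spacing 2.5 um). The cell is a set of occupied sites evolving by
   boundary copy attempts accepted with the Boltzmann rule
   $\min(1, e^{-\Delta H/T})$. The Hamiltonian combines cell-medium
   interface tension ($J_{cm}$ per von Neumann boundary segment), an
   elastic area constraint $\lambda_A (A - A_t)^2$, a substrate-adhesion
   energy $-\lambda_C$ per occupied site, and a *detachment barrier*
   $\varepsilon\,N\,w$ paid by any retraction that rips a focal adhesion
   of $N$ integrin bonds (reinforced by a factor $w$) off the substrate.
   One Monte Carlo step (MCS) corresponds to $t_{FA} = 10$ s.

2. **Focal adhesions** -- one catch-slip bond cluster per occupied site.
   The per-bond unbinding rate
   $k_{off}(f) = k_s e^{f/F_{slip}} + k_c e^{-f/F_{catch}}$
   falls with per-bond tension $f$ (catch pathway) before rising again
   (slip pathway); the single-bond lifetime peaks near 30 pN, the loading
   optimum reported for alpha5-beta1 integrin. Bonds bind from a finite
   membrane pool at rate $\gamma$ and unbind independently; the cluster
   is integrated as a birth-death (tau-leap) process in substeps of 0.1 s.
   Clusters ending a build-up window below the nascent threshold
   ($N_0 = 50$ bonds) disassemble and refund their bonds.

3. **Traction and substrate mechanics** -- the first-moment-of-area (FMA)
   traction model pulls every occupied site towards the cell centroid
   with stall force $F_s = \mu\,|\bar r - r_i|$ (zero net force and
   torque by construction). Between Monte Carlo steps the force on each
   adhesion relaxes towards its stall force with
   $dF/dt = E_{eff}\,\ell\,v_0 (1 - F/F_s)$: the substrate acts as a
   spring of stiffness $E\,\ell$, in series with an intracellular linkage
   $E_{series}\,\ell$, loaded at the myosin velocity $v_0$. **Forces
   build up faster on stiffer substrates** -- this, not a larger force
   amplitude, is the stiffness sensor. In the feedback variants the
   substrate is additionally solved as a linear plane-stress
   finite-element problem (bilinear quadrilaterals, one per lattice site,
   domain boundary clamped) under the current adhesion forces, and the
   tensile part of the hydrostatic stress $g = \max(\bar\sigma, 0)$
   reinforces adhesions through $w = 1 + p\,g/(\sigma_h + g)$: variant
   2.1 scales the detachment energy, variant 2.2 the stall force, and
   variant 1 has no feedback.

The per-MCS loop is: stall forces from the current shape; joint force
build-up and cluster kinetics for $t_{FA}$ seconds; nascent pruning; (in
variant 2) the plane-stress solve and feedback; one CPM step.

### Why the emergent behaviors follow

*Spreading*: a new protrusion seeds a nascent cluster at $N_0$ bonds and
zero force. At 1 kPa force arrives so slowly that the unloaded cluster
(lifetime $1/k_{off}(0) < 1$ s per bond) decays below threshold within a
window and the protrusion retracts freely. At 50 kPa the per-bond force
crosses into the catch regime within a fraction of a second, the cluster
matures, and its detachment barrier ratchets the boundary outward. The
finite integrin pool slows the growth of new adhesions once the cell is
well spread, which (together with the area constraint) sets the final
area.

*Durotaxis*: on a stiffness gradient the same race is won more often at
the cell's front than its back, biasing adhesion turnover and drifting
the cell up-gradient -- no polarity machinery is modeled.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `spacing` | 2.5 | um | lattice spacing; 200x200 sites for the 500 um domain |
| `T` | 10 | energy | CPM temperature; protrusion/retraction noise |
| `J_cm` | 12 | energy/segment | interface tension; keeps the cell compact |
| `lambda_area` | 3e-4 | energy/um^4 | soft area constraint |
| `A_target` | 1.2 x initial area | um^2 | resolved at initialization |
| `lambda_C` | 0.25 | energy/site | substrate adhesion (spreading) energy |
| `eps_bond` | 0.5 | energy/bond | detachment work per bond; the mechanosensitive ratchet |
| `k_s`, `k_c` | 0.0156, 3 | 1/s | slip and catch prefactors |
| `F_slip`, `F_catch` | 18, 7 | pN | slip and catch force scales |
| `gamma` | 13 | bonds/s | cluster growth rate at a plentiful pool |
| `pool_sat` | 0.4 | -- | free-pool reserve below which binding slows |
| `N0 = N_seed` | 50 | bonds | nascent threshold and protrusion seed |
| `N_total` | 2e5 | bonds | membrane integrin pool |
| `mu` | 0.06 | nN/um | FMA traction coefficient |
| `ell` | 0.3 | um | adhesion coupling length (E to spring constant) |
| `v0` | 0.1 | um/s | myosin motor velocity (100 nm/s) |
| `E_series` | 150 | kPa | intracellular linkage stiffness in series |
| `t_fa`, `dt` | 10, 0.1 | s | build-up window (= 1 MCS) and ODE substep |
| `p`, `sigma_h` | 2, 0.5 | --, kPa | feedback strength and half-saturation |
| `nu`, `thickness` | 0.45, 10 | --, um | substrate Poisson ratio and thickness |

### Calibration rationale

The calibration *procedure* is normative; the numbers fall out of it:

- `k_s, k_c, F_slip, F_catch`: lifetime peak at 31 pN (checked against
  the closed form `koff_argmin()`), with an unloaded-to-peak lifetime
  ratio of ~20 so that a 50-bond nascent cluster dies within seconds
  when unloaded but can grow several-fold when loaded near the optimum.
- `gamma`: small enough that the unloaded steady state
  $\gamma/k_{off}(0) \approx 4 \ll N_0$ (soft substrates shed
  adhesions), large enough that loaded clusters reach 80--120 bonds --
  the range that brackets the 100-bond reporting threshold for "large"
  adhesions.
- `ell` (with `v0` fixed at 100 nm/s): positions the maturation race so
  that 1 kPa clusters die, 5 kPa clusters mature slowly and partially,
  and 50 kPa clusters mature within one window; simultaneously places
  the sensitive zone of the race near the 6 kPa start of the durotaxis
  gradient.
- `E_series`: caps the loading rate on effectively rigid substrates.
  Without it the first substep after seeding throws ~60 pN per bond onto
  a nascent cluster on glass and the cluster slip-collapses, making very
  stiff substrates *less* adhesive -- contrary to the monotone spreading
  the model is supposed to produce. 150 kPa (stress-fiber-scale
  stiffness) makes 50,000 kPa load about 4x faster than 50 kPa.
- CPM energies: `J_cm/T` large enough that interface entropy does not
  inflate the soft-substrate cell (~2.4), `eps_bond` such that a mature
  adhesion's barrier (~40--60) exceeds the retraction energy gain while
  a nascent one's does not, and `lambda_area` sized so the area spring
  only matters near the fully spread state.

## Numerical choices

- **Cluster integrator.** The mean-field ODE
  $dN/dt = b - N\,k_{off}(F/N)$ is integrated as a tau-leap birth-death
  process: Poisson gains with mean $b\,dt$ (clamped by the free pool),
  binomial losses with per-bond probability $1 - e^{-k_{off} dt}$. The
  expectation matches the ODE; the demographic noise matters, because
  marginal clusters must be able to go extinct -- with a deterministic
  integrator any cluster that survives its first window persists
  forever, and intermediate-stiffness cells develop winner-take-all
  adhesion patterns. Integer bookkeeping makes pool conservation exact.
- **Binding and the pool.** Binding is constant-rate ($\gamma$) while
  the free pool fraction exceeds `pool_sat`, then declines linearly.
  A strictly proportional rate made cluster size depend on cell
  spreading state through pool richness, distorting the cluster-size
  distribution at intermediate stiffness.
- **Barrier gating.** The detachment barrier applies to load-bearing,
  matured clusters ($F > 0$ and $N > N_0$). An unloaded nascent cluster
  has no tension-engaged catch bonds; letting it anchor would ratchet
  even soft-substrate cells outward because protrusions are seeded at
  exactly $N_0$ bonds.
- **Force carry-over.** Cluster force is carried across windows and
  clipped down if the stall force fell with the new shape; within a
  window the linear build-up is advanced by its exact exponential
  update, so only the cluster kinetics are discretized.
- **Stress stimulus.** With centripetal traction the substrate under
  the cell body is in in-plane compression; the tensile part of
  $\bar\sigma$ lives in a narrow ring at and beyond the pulling rim.
  Rectifying to tension ($g = \max(\bar\sigma, 0)$) therefore
  concentrates reinforcement under strongly pulling protrusions.
  The magnitude $|\bar\sigma|$ was also examined and rejected: it peaks
  under the cell center and reinforces the wrong sites.
- **FEM.** One bilinear quadrilateral per lattice site, 2x2 Gauss
  quadrature, thickness folded into the load-to-stress scale, boundary
  nodes clamped (the gel is glued to a dish >= 5 cell diameters away).
  The stiffness matrix is factored once per run (sparse Cholesky); each
  MCS is one triangular solve. Stress is evaluated at element centers.
- **Connectivity.** Retractions that would locally fragment the cell
  (cell sites on the 8-ring not forming one contiguous block) are
  vetoed, keeping the cell a single 4-connected component for the
  morphometrics.
- **Attempt schedule.** One MCS performs as many copy attempts as there
  are interface sites, sampling source-target Moore pairs by rejection;
  interface energies use von Neumann neighborhoods.
- **Degenerate inputs.** Zero-amplitude noise and sinusoid fields reduce
  to the homogeneous field; a zero stall force freezes build-up and the
  cluster decays; an empty cell aborts the run; constant area series are
  flagged non-identifiable by the kinetics fits.

## What the tests do and do not show

The test suite runs the study designs at reduced scale: homogeneous
substrates on a 200 um domain (the spread cell's ~50 um radius stays
more than two cell radii from the boundary), gradients on 500 x 150 um
for 2500-6000 MCS, ensembles of 2-5 replicates. The acceptance script
uses the same reduced sizes (stated in its header). The generator of
"data" here is the simulator itself; what passing tests show is that
the implemented mechanism reproduces the emergent behaviors under the
documented parameter set, not that real cells of any particular type
are quantitatively matched.

## Known limitations

- **Spreading kinetics lack a lag phase.** Reconstructed rate constants
  let new protrusions mature within 1-2 windows, so spreading starts
  immediately and the error-function fit places the half-spreading time
  near 1-2.5 min rather than ~5 min. Slowing maturation globally either
  froze the membrane (stringy shapes) or collapsed the spreading
  fold-change; we kept the spreading magnitude and report the faster
  kinetics honestly.
- **No robust biphasic elongation.** In variant 2.1 the intended
  bootstrap (eccentric fluctuation -> pole stress hot spots -> pole
  anchoring -> further elongation) has near-unit gain at this force
  scale: the tensile rim stimulus of a mildly eccentric cell differs by
  only ~25% between poles and flanks, and interface tension plus shape
  noise erase the bias before it amplifies. Cells instead become
  slightly *rounder* with increasing stiffness. The corresponding
  acceptance check is expected to fail and is retained unmodified.
- Single cell only; no cell-cell interactions, no intracellular
  signaling, no fibrous/strain-stiffening matrices (the substrate is
  linearly elastic and isotropic), no adhesion merging or diffusion.
- The FMA traction model is a deliberate simplification; it is not
  derived from the CPM Hamiltonian and ignores stress-fiber anisotropy.

## Reproducing a run

```{r example, eval = FALSE}
cfg <- sim_config(substrate_homogeneous(50, extent = 300),
                  variant = "1", n_mcs = 2000, seed = 1)
res <- run_simulation(cfg)
res
fit_spreading_erf(res$morphometrics$time_s / 60, res$morphometrics$area_um2)
write_run(res, "run50kPa")
```

Presets bundle the four study designs
(`preset("spreading")`, `"elongation"`, `"motor_velocity"`,
`"durotaxis"`); `expand_runs()` turns them into seeded replicate
configurations, and the `inst/cli/adhesim` script exposes the same
functionality from a shell.
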