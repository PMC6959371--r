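# lbadhesion

Lattice Boltzmann–immersed boundary simulation of micro-particle adhesion
at blood-vessel walls in shear flow.

## The problem

Systemically injected drug-delivery particles reach their targets by
leaving the flowing blood and binding to the vessel wall.  Whether a
particle of a given shape, ligand coverage and bond chemistry *firmly
adheres*, *rolls*, *slides* or *does not adhere* under a given wall shear
is the central design question of vascular nanomedicine.  `lbadhesion`
answers it for rigid circular and elliptical particles in a
two-dimensional linear shear cell: a fixed receptor-coated wall at
`y = 0`, a moving wall at `y = H` setting the Reynolds number
`Re = H u_max / nu`, and a particle released a gap `y_0 = 3e-3 H` from
the wall.

The model couples four layers, each exposed as package functions:

* **D2Q9 lattice Boltzmann fluid** — BGK collision, Guo forcing with the
  half-force momentum correction, Zou–He known-velocity walls
  (`equilibrium_populations()`, `collide_and_stream()`,
  `apply_wall_velocity_bc()`, ...).
* **Moving-least-squares immersed boundary** — linear-basis MLS transfer
  between grid and surface elements, direct forcing, probe-based load
  integration `F_p = Σ (-p_l n_l) S_l`, `F_v = Σ (τ_l·n_l) S_l`
  (`build_boundary()`, `mls_interpolate()`, `evaluate_loads()`, ...).
* **Stochastic adhesive dynamics** — ligands as linear springs
  `f = σ (y_l - y_cr,eq) n_l` forming with `P_f = 1 - exp(-k_f Nl Δt)`
  and rupturing with the slip-bond probability
  `P_r = 1 - exp(-k_r0 exp[(σ-σ*)(y_l-y_cr,eq)²/2k_BT] Δt)`, plus a van
  der Waals-like wall repulsion `F_w = H_k/(8√2) √(r/ε⁵)`
  (`update_bonds()`, `vdw_wall_force()`, ...).
* **Rigid-body dynamics** — explicit second-order multistep
  Newton–Euler update under the combined pressure, viscous, adhesive and
  wall loads, weakly coupled to the fluid (`newton_euler_step()`).

On top sit the experiment drivers: `run_near_wall_simulation()`,
`classify_regimen()`, `sweep_phase_map()` (rolling-velocity and
adhesion-probability maps over `Re`, ligand density `ρ_l`, shape and bond
strength `σ`), and the closed-form microfluidic-chip relations
`U = Q/(WH)`, `S = 6Q/(WH²)` and
`u_th = (3/2)(Q/WH)[1 - (1 - d/H)²]` used to validate simulated rolling
velocities against cell-rolling measurements
(`theoretical_rolling_velocity()`, `rolling_velocity_validation()`).

## Worked example

```r
library(lbadhesion)

chip <- chip_geometry()            # W = 210 um, H = 42 um, d = 15 um
chip_flow_quantities(chip)
#> # A tibble: 4 × 3
#>       Q     U     S
#>   <dbl> <dbl> <dbl>
#> 1    50  94.5  13.5
#> 2   100 189.   27.0
#> 3   150 283.   40.5
#> 4   200 378.   54.0
theoretical_rolling_velocity(chip)
#> [1]  83.15401 166.30802 249.46203 332.61604
```

`U` (µm/s) is the mean chip velocity and `S` (1/s) the wall shear rate at
each flow rate `Q` (nL/min); `u_th` is the closed-form rolling velocity
of a 15 µm cell at the wall — the values a cell-rolling experiment in
this chip should bracket.

A reduced-scale near-wall run (a minute or two on one core):

```r
cfg <- simulation_config(H_nodes = 101, domain_H = 4, tau = 1, Re = 0.1,
                         rho_l = 0.5, sigma = 2, nsteps = 120000, seed = 1)
sim <- run_near_wall_simulation(cfg)
sim
```

The printed summary reports the window-averaged minimum separation
`y_min/H` (below the critical bond distance `6.8e-3 H` when the particle
is tethered, above it once it escapes), the rolling velocity
`u_roll/u_max`, the normalized
rotation rate `Ω H/u_max`, the active-bond fraction, and the classified
regimen.  `write_trajectory_csv()`, `write_vtk_fields()` and
`write_phase_map_csv()` export the records.

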