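# mdtsim

Magnetic drug targeting promises to concentrate drug-carrying paramagnetic
nanoparticles at a target site — a tumor, a vessel lesion — by steering them
with an external magnetic field, sparing healthy tissue. Whether a given
particle design (core radius, coating, susceptibility) and magnet
configuration actually delivers particles to the target depends on the
competition between hydrodynamic drag, magnetic forcing, Brownian motion
and wall interactions in pulsatile vessel flow.

`mdtsim` is a desk-scale simulator for exactly this question, aimed at
researchers studying particle-design trade-offs. It couples:

* a **D3Q19 lattice-Boltzmann (LBGK) solver** with Guo second-order body
  forcing, Bouzidi–Firdaouss–Lallemand interpolated bounce-back for curved
  walls, parabolic velocity inlets driven by tabulated pulse waveforms, and
  fixed-density outlets;
* an **overdamped Lagrangian point-particle model**,
  `u_p = v(x_p) + beta (F + F_R)` with mobility
  `beta = 1/(6 pi mu (a + a_c))`, where `F` collects the magnet-dipole
  force on the induced moment `m_i = (4/3) pi a^3 chi_v H`, inter-particle
  point-dipole forces, wall and pair lubrication closures
  `F_L = 6 pi mu a^2 (u . r_hat)(1/h - 1/h_e)`, and gravity/buoyancy;
  `F_R` is fluctuation–dissipation Brownian noise;
* **synthetic voxelized vessels** (straight cylinder, torus bend, plane
  channel) with analytic wall-cut fractions and wall-distance queries, a
  documented voxel-mask file format, sphere seeding of particle batches,
  and region-of-interest (RoI) occupancy readouts — the targeting
  efficiency is the percentage of injected particles inside the RoI over
  time.

Validation drivers reproduce the classical checks: driven wall approach
against the analytic lubrication resistance `F0 (9a/(8h) + 1)`, the
two-particle dipolar force against its symbolic solution, Hagen–Poiseuille
flow in a cylinder of non-integer lattice radius, shear-wave viscosity
recovery, Stokes–Einstein diffusion and Stokes settling.

## Worked example

Verify the flow solver against Hagen–Poiseuille in a cylinder of radius
10.3 lattice spacings, then run the five-particle demonstration: five
particles evenly spaced from the centerline toward the wall of a
pressure-driven tube (103.9 Pa/m) pass a permanent magnet of moment
{0, 3000, 0} A m² held outside the vessel.

```r
library(mdtsim)

pois <- run_poiseuille_benchmark(R_lat = 10.3, tau = 0.9, wall_scheme = "bfl")
round(100 * pois$centerline_error, 3)   # 0.067  (% error vs analytic)
round(pois$R_fitted, 3)                 # 10.303 (radius recovered from the
                                        #         parabolic fit, in voxels)

demo <- run_five_particle_demo(seed = 1)
round(demo$residence, 2)
# 0.63 0.77 0.92 1.07 1.24
```

`residence` is the time (seconds) each particle spends within 20% of the
wall, ordered innermost to outermost. The particle nearest the magnet is
deflected to the wall first and lingers longest (1.24 s vs 0.63 s for the
centerline particle) — magnetic capture slows particles where the flow is
slowest. `demo$min_pair_distance` confirms the trajectories never merge:
the magnet–particle force dominates the inter-particle dipolar attraction.

Targeting efficiency studies are one call each:

```r
vs <- run_targeting_sweep("velocity", seed = 1)   # resting vs elevated inflow
sapply(vs, function(x) x$peak_fraction)           # 50.0 22.5  (% in RoI)
```

Raising the inflow velocity halves the peak RoI occupancy at fixed magnet —
drag wins over magnetic drift at higher flow rates.

A thin command-line front end ships in `inst/cli/mdtsim.R`
(`simulate <config.yaml>`, `validate maude|dipole|poiseuille`,
`demo five-particle`, `roi-report`); field snapshots export as VTK
ImageData (`.vti`), trajectories and RoI series as CSV.

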