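# verletdiag

Diagnostics for Verlet neighbor-list artifacts in molecular dynamics
simulations.

MD engines evaluate short-range forces over a neighbor list built with an
outer cutoff *r*<sub>l</sub> ≥ *r*<sub>c</sub> and rebuilt every `nstlist`
steps. When the buffer *r*<sub>l</sub> − *r*<sub>c</sub> is too thin for the
rebuild interval, particle pairs occasionally cross from beyond
*r*<sub>l</sub> to within the interaction cutoff *r*<sub>c</sub> between
rebuilds and their interaction is silently dropped. The missed interactions
bias the virial pressure; barostats acting on the biased pressure — at
intervals not commensurate with the rebuilds — slowly deform the box, which
in large membrane systems shows up as unphysical buckling. This package is
for simulators who want to detect, quantify and avoid that failure mode.

It provides:

* **Missed-interaction model** (`n_missed_point()`, `n_missed_rigid()`,
  `crossing_probability_endpoint()`): the expected number of unique missed
  pair interactions per particle per update interval, for point particles
  (closed-form endpoint estimate and a path Monte-Carlo reference that
  follows free-flight pairs across every force-evaluation step) and for
  rigid molecules with thermal tumbling. `recommend_rl()` inverts the model
  to the smallest outer cutoff meeting a miss tolerance; `drift_rate()`
  converts miss rates into an energy-drift analog (kJ mol⁻¹ ps⁻¹).
* **Pressure diagnostics** (`running_average()`, `phase_average()`,
  `delta_p()`, `welch_psd()`, `detect_nstlist_harmonics()`): stride-dependent
  running averages, phase averages over blocks of `nstlist` steps aligned to
  rebuilds with block-bootstrap errors, the before/after-rebuild pressure
  difference ΔP, and Welch spectra with scale-free detection of harmonics of
  1/(nstlist·Δt). GROMACS xvg input/output via `read_xvg()`/`write_xvg()`.
* **Box-shape isotropy** (`classify_semiiso()`, `classify_aniso()`,
  `chisq_gof()`, `isotropy_events()`): classify replicate deformation events
  and run Pearson chi-squared tests under explicitly named conventions.
* **Membrane bending energy** (`heights_from_points()`, `mean_curvature()`,
  `bending_energy()`): Monge-gauge mean curvature by periodic finite
  differences and the Helfrich energy E = 2κ∫H²dA, reported in kJ/mol and
  k<sub>B</sub>T.
* **Instrumented LJ simulator** (`run_ljmd()` and friends): a minimal
  Lennard-Jones engine (velocity Verlet, cell lists, optional dual pair
  list, v-rescale thermostat, Berendsen-type barostat) that counts every
  missed interaction as it happens, reproducing the artifacts at desk scale.
* **Synthetic generators** (`gen_pressure_series()`, `gen_freeflight_gas()`,
  `gen_lj_fluid()`, `gen_height_field()`) with closed-form ground truth for
  calibrating the detectors.

Units are GROMACS-style MD units (nm, ps, amu, kJ/mol, bar, K) with
k<sub>B</sub> = 0.0083144621 kJ/(mol·K) and 16.6054 bar per (kJ/mol)/nm³;
`reduced_units()` switches the simulator to dimensionless LJ units.

## Worked example

How thick a buffer does coarse-grained water need? A Martini-like bead
fluid (ρ = 7.08 nm⁻³, m = 72 amu, T = 310 K) with r_c = 1.1 nm, a 20 fs
step and rebuilds every 25 steps:

```r
library(verletdiag)

gas   <- gas_model(rho = 7.08, mass = 72, temperature = 310)
sched <- schedule_config(dt = 0.02, nstlist = 25)

n_missed_point(cutoff_scheme(r_c = 1.1, r_l = 1.28), sched, gas,
               mode = "path-mc", seed = 7)
#> <miss_estimate> 0.5843 unique missed pair interactions per particle per update interval
#>   per-step (pair,step) evaluations missed: 2.757
#>   method: path-MC ; MC stderr: 0.0307

recommend_rl(schedule_config(dt = 0.02, nstlist = 20), gas,
             r_c = 1.1, tolerance = 1e-4)
#> [1] 1.531675
```

With the stock 0.18 nm buffer, every particle misses about 0.6 pair
interactions in *each* 0.5 ps rebuild interval — the pressure bias behind
box deformations. Pushing the residual miss rate down to 10⁻⁴ per particle
per interval at `nstlist = 20` requires an outer cutoff near 1.5 nm.

The same number can be measured instead of modelled: run the instrumented
simulator in free flight at identical parameters,

```r
g   <- gen_freeflight_gas(rho = 7.08, temperature = 310, mass = 72,
                          box = rep(6.56, 3), seed = 13)
sim <- run_ljmd(g, lj_potential(r_c = 1.1), cutoff_scheme(1.1, 1.28),
                sched, n_steps = 25 * 200, forces_on = FALSE)
attr(misses_per_particle(sim), "mean")
#> [1] 0.5986143
```

and the simulated 0.599 ± 0.002 agrees with the model's 0.584 ± 0.031.

Schedule hazards are flagged directly from the run parameters:

```r
check_schedule(schedule_config(dt = 0.02, nstlist = 25,
                               nstpcouple = 20, nsttcouple = 20))
#> # A tibble: 2 × 3
#>   code                    severity message
#>   <chr>                   <chr>    <chr>
#> 1 pcouple_incommensurate  warning  nstpcouple = 20 is not a multiple of nstlist = 25: …
#> 2 tcouple_incommensurate  warning  nsttcouple = 20 is not a multiple of nstlist = 25: …
```

A command-line interface wrapping these functions is installed at
`inst/cli/verletdiag.R` (subcommands `recommend`, `simulate`, `diagnose`,
`psd`, `anisotropy`, `curvature`, `gen`).

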