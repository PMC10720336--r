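---
title: "Diagnosing neighbor-list artifacts in molecular dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing neighbor-list artifacts in molecular dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(verletdiag)
```

## The problem

Molecular dynamics engines avoid an O(N²) force loop by keeping, for every
particle, a Verlet neighbor list of partners within an outer cutoff
$r_\ell \ge r_c$, where $r_c$ is the interaction cutoff. The shell
$r_\ell - r_c$ is a buffer that lets the list stay valid for `nstlist`
integration steps between rebuilds. If the buffer is too thin or the rebuild
interval too long, pairs occasionally travel from $r > r_\ell$ to $r < r_c$
between rebuilds and their interaction is silently dropped from the force
evaluation.

A handful of missed pairs per thousand particles sounds harmless, but the
missed interactions bias the *virial*, hence the instantaneous pressure
tensor. In NPT simulations a barostat acts on that biased pressure at fixed
intervals, and when its coupling interval is not commensurate with the list
rebuild interval it periodically reads pressures computed from a stale list.
For a cohesive (attraction-dominated) fluid the apparent pressure is inflated
late in each rebuild interval, the barostat over-expands the box, and in
large anisotropically coupled systems — membranes above all — the box slowly
deforms and the membrane buckles. This package provides (i) a quantitative
model of how many interactions are missed, (ii) time-series diagnostics that
reveal the artifact in pressure data, (iii) statistics for box-shape
isotropy, (iv) bending-energy estimation to quantify membrane deformation,
and (v) a small instrumented Lennard-Jones simulator that reproduces the
whole mechanism at desk scale.

## The missed-interaction model

Between rebuilds, a buffer-crossing pair is essentially in free flight:
collisions that would deflect it act on the same time scale as the crossing
itself, and ignoring them is conservative. We therefore model the fluid as
point particles of mass $m$ at number density $\rho$ with Maxwell–Boltzmann
velocities at temperature $T$. The relative coordinate of a pair then
diffuses ballistically: after time $t$ its displacement is an isotropic
Gaussian with per-component standard deviation
$\sigma_t = t\sqrt{k_B T (1/m_1 + 1/m_2)}$ (equal masses:
$\sqrt{2 k_B T/m}$).

Two estimators are implemented.

**Path Monte Carlo (reference definition).** `n_missed_point(mode =
"path-mc")` samples initial separations uniformly in the shell
$[r_\ell, R_{\max}]$ with $R_{\max} = r_\ell + 8\sigma_{t_{int}}$ (the
Gaussian weight beyond $8\sigma$ is below $10^{-15}$), draws a
Maxwell–Boltzmann relative velocity, and follows the straight-line path
across the force-evaluation times $k\,\Delta t$, $k = 1,\dots,
\mathrm{nstlist}-1$ — exactly the evaluations that use the stale list. A
sampled pair is a *unique miss* if its separation is below $r_c$ at any of
those times; `per_step` additionally counts every offending $(pair, k)$.
The expected number of unique missed pairs per particle per interval is
$\rho V_{shell}$ times the missed fraction, with a binomial Monte-Carlo
standard error. Every estimate records its seed and is bit-reproducible.

**Endpoint closed form.** For speed (`recommend_rl()` evaluates the model
inside a bisection), `crossing_probability_endpoint()` integrates the
closed-form probability that the *endpoint* of the interval lies inside the
cutoff sphere,

$$n_{missed} \approx \rho \int_{r_\ell}^{R_{\max}}
  P\bigl(|\vec r + \vec d| < r_c\bigr)\, 4\pi r^2\, dr,$$

with $\vec d$ Gaussian at the full interval time. Ignoring mid-interval
excursions that return outside $r_c$ makes this an approximation; against
the path estimator it agrees within roughly 10–25% over the regimes we
exercise, which is ample for choosing buffers (the miss count varies by
orders of magnitude over a few tenths of a nm in $r_\ell$). The closed form
itself is verified in the test suite against a direct Gaussian sampling
oracle to four Monte-Carlo standard errors.

**Rigid molecules.** `n_missed_rigid()` extends the picture to rigid
molecules (e.g. three-site water): molecules translate ballistically with
their total mass and tumble with body-frame angular velocities drawn per
principal axis with variance $k_B T / I_a$. The body-frame angular velocity
is held constant during an interval — exact for spherical tops and a
short-time approximation otherwise; buffer crossings happen within a few
tenths of a ps, where free-precession corrections are negligible. Site-pair
(X, Y) misses are counted per molecule. Because peripheral light sites swing
at $\omega d \sim \sqrt{k_B T/I}\,d$, which for water-like geometry exceeds
the center-of-mass thermal speed several-fold, hydrogen–hydrogen pairs are
missed far more often than oxygen–oxygen pairs at identical cutoffs — the
test suite pins this ordering.

**Recommendation engine.** `recommend_rl()` bisects (to $10^{-3}$ nm) for
the smallest $r_\ell$ whose endpoint miss estimate is below a user
tolerance, expressed in unique missed pair interactions per particle per
interval. `drift_rate()` converts the per-step miss rate into an
order-of-magnitude energy-drift analog (missed evaluations × mean missed
pair energy ÷ interval), comparable in spirit to engine buffer tolerances
quoted in kJ mol⁻¹ ps⁻¹; it is a diagnostic scale, not a reimplementation of
any engine's internal machinery.

## The instrumented simulator

`run_ljmd()` integrates a truncated-and-shifted Lennard-Jones fluid
(velocity Verlet, orthorhombic periodic box, minimum image) with the exact
neighbor-list discipline under scrutiny: a cell-list rebuild every `nstlist`
steps, optionally a dual scheme where an inner list (pairs of the outer pool
within `r_inner`) is rebuilt every `nstlist_inner` steps and used for the
forces. A velocity-rescaling thermostat and a Berendsen-type weak-coupling
barostat (isotropic, semi-isotropic or anisotropic) are available; the
artifact mechanism does not depend on the barostat flavour, so the simplest
rescaler suffices. Tail corrections are deliberately absent — they would
partially mask the missed-interaction signal the simulator exists to expose.
The pair search is cluster-free (1×1 pairs), so the simulator is spatially
isotropic by construction.

The engine is instrumented: together with each outer list it builds a
*shadow list* with cutoff $r_\ell + 1.5 \times 2 v_{\max}\,
\mathrm{nstlist}\,\Delta t$. Any pair that could cross from beyond the
shadow cutoff to within $r_c$ in one list lifetime would need to move faster
than 1.5× the fastest particle pair at build time, so scanning shadow pairs
absent from the force list at every force evaluation yields the exact
per-lifetime counts of unique missed pairs and missed (pair, step)
evaluations (exact for free flight; for interacting runs the safety factor
covers thermostat-scale velocity changes). Free-flight runs (`forces_on =
FALSE`) turn the simulator into a direct numerical realisation of the
analytic model; the test suite requires agreement within three combined
standard errors across several $(r_\ell, \mathrm{nstlist})$ settings.

Numerical conventions worth knowing:

* The truncated-and-shifted potential has $u(r_c) = 0$ but an unshifted
  force, so the force jumps by $|u'(r_c)|$ at the cutoff. At $r_c =
  2.5\sigma$ this discontinuity dominates the residual total-energy noise;
  the NVE fidelity check therefore runs at $r_c = 3.5\sigma$, where the
  discontinuity is several times smaller and the symplectic drift bound of
  $10^{-4}\,\epsilon$/particle over $10^4$ steps at $\Delta t = 0.002\,\tau$
  is met with margin.
* Samples are recorded at every step; the sample at a step whose force
  evaluation used a freshly rebuilt list has phase 0. A rebuild at step $s$
  means evaluations $k = 1,\dots,\mathrm{nstlist}-1$ after it use the stale
  list, matching the path estimator's convention.
* With `r_inner = r_l` the dual scheme keeps the entire outer pool, making
  dual and single-list trajectories bit-identical (a degeneracy the tests
  assert).
* Divergence (non-finite energy) aborts with the offending step; boxes must
  exceed $2 r_\ell$ per dimension for minimum-image validity and the engine
  refuses barostat moves that would violate this.

## Pressure diagnostics

`running_average()` reproduces what an engine reports when averaging
quantities saved every `stride` steps: when the per-step pressure carries a
pattern with the rebuild period, stride-1 and stride-`nstlist` averages
converge to different limits (the full-phase mean vs the single sampled
phase), and that gap is itself a warning sign. `phase_average()` averages
over blocks of `nstlist` steps aligned to rebuilds (phase 0 = first
evaluation after a build); `delta_p()` reports
$\Delta P = \langle P \rangle_{\mathrm{nstlist}-1} - \langle P \rangle_0$,
the pressure excess just before a rebuild relative to just after. Positive
$\Delta P$ indicates missed attraction; negative indicates missed repulsion
(e.g. close-range like-charge pairs in atomistic water). Standard errors
come from a block bootstrap that resamples whole intervals (1000 resamples,
seeded), because pressure is strongly autocorrelated within an interval and
pointwise errors would be optimistic. The per-phase overall mean equals the
plain mean of the whole-interval truncation exactly.

`welch_psd()` implements the standard Welch estimate (mean-detrended,
Hann-windowed, 50%-overlapping segments; default segment the largest power
of two not exceeding min(8192, length/8)), scaled so the one-sided spectrum
integrates to the variance — white-noise Parseval holds within 5% in the
tests. `detect_nstlist_harmonics()` inspects the bins nearest each harmonic
$k/(\mathrm{nstlist}\,\Delta t)$ below Nyquist and compares them with the
median spectrum in a surrounding band (other harmonics excluded). The
median-ratio is scale-free, so one threshold (default 10×) works across
systems; on 100 seeded white-noise series the false-positive rate is below
5%, and a run with `nstlist = 1` has no harmonic below Nyquist by
construction and can never be flagged.

## Box-shape isotropy

For replicate NPT runs of an isotropic fluid, no box axis should be
preferred. `classify_semiiso()`/`classify_aniso()` classify each replicate
by comparing 10%-endpoint-window means of the box edges — windowed means
rather than raw endpoints so single-step noise cannot flip a call, with
exact ties erroring (semi-isotropic) or breaking to the smallest axis index
with a warning (anisotropic). `chisq_gof()` then tests the event counts
against the isotropic null (1/2:1/2, or 1/3:1/3:1/3). Published tables are
not always explicit about their test convention, so three are exposed: the
textbook `standard` Pearson test on $k-1$ degrees of freedom (the default),
the continuity-corrected `yates` test for two categories, and `df_equals_k`,
which refers the plain statistic to $k$ degrees of freedom and is required
to reproduce some published three-category p-values. The conventions are
reported in every result; reproducing a printed value under a stated
convention is a statement about arithmetic, not an endorsement of that
convention for new analyses.

## Membrane bending energy

A deformed membrane betrays itself energetically. With the surface as a
periodic Monge-gauge height field $h(x, y)$ (`heights_from_points()` bins
head-group coordinates; empty bins are filled by iterative periodic
neighbour averaging to $10^{-6}$ nm and recorded in a mask),
`mean_curvature()` evaluates

$$H = \frac{(1 + h_y^2) h_{xx} - 2 h_x h_y h_{xy} + (1 + h_x^2) h_{yy}}
           {2\,(1 + h_x^2 + h_y^2)^{3/2}}$$

by second-order periodic central differences (finite differences rather
than spectral derivatives: they stay robust when filled bins leave small
discontinuities), and `bending_energy()` integrates the Helfrich form
$E = 2\kappa \int H^2\, dA$ over the flat xy plane, ignoring curvature
corrections to the area element and the topology-invariant Gaussian term.
With $H$ the *mean* of the principal curvatures this prefactor equals the
$(\kappa/2)\int(2H)^2$ convention; conventions differ across the
literature, so the prefactor is switchable and always reported. The default
rigidity is 25 $k_B T$, typical of phospholipid bilayers. Tests pin the
small-slope closed form $(\kappa/2) a^2 (2\pi/L)^4 L_x L_y / 2$ for a
sinusoid to 1% at $n = 128$, $a/L = 0.005$, second-order convergence
against the exact 1-D Monge expression, and linearity for superposed
orthogonal modes.

## What the generators emulate — and what they do not

`gen_pressure_series()` produces Gaussian noise plus a deterministic
per-phase pattern (optionally an inner-period sawtooth mimicking dual-list
beating); its closed-form per-phase means make it an exact oracle for the
phase diagnostics. Real pressure series differ in two ways the generator
deliberately ignores: broadband autocorrelation from collective dynamics,
and barostat feedback coupling the pattern to the box trajectory. Passing
the synthetic checks therefore demonstrates correct arithmetic and
calibrated detection thresholds, not that every real artifact will be this
clean; the simulator-based checks close part of that gap with genuinely
dynamical data. `gen_freeflight_gas()` realises the model's ideal gas
exactly (its velocity variance and pair-distance statistics are themselves
tested), and `gen_lj_fluid()` provides the canonical dense reduced-unit
state $\rho\sigma^3 = 0.8$, $k_B T/\epsilon = 1.0$.

## Problem sizes and study conditions

The desk-scale study conditions used throughout the tests and the
acceptance script: a Martini-water-like gas ($\rho = 7.08$ nm⁻³, $m = 72$
amu, $T = 310$ K, $\Delta t = 0.02$ ps — the bead density of 1530 particles
in a (6 nm)³ box) for the model-vs-simulation comparison with $N = 2000$
particles over 200 rebuild intervals per setting; a dense LJ fluid with
$N = 1000$, zero buffer and `nstlist = 40` over 400 intervals for the
pressure-artifact sign; $N = 500$ over $10^4$ steps for integrator
fidelity; and $128 \times 128$ grids for curvature. These sizes give
standard errors comfortably inside the claimed bounds while keeping the
full suite in the minutes range.

## Limitations

* The model's free-flight assumption weakens for near-zero buffers combined
  with long intervals, where a crossing pair may interact before the next
  evaluation; no correction is attempted, and simulated misses can slightly
  exceed the model there.
* Engines that cluster particles for SIMD pair search carry an extra
  implicit buffer (and an anisotropic one); the simulator is cluster-free,
  so its miss counts bound such engines from above at identical parameters.
* The rigid-molecule propagator ignores free precession of asymmetric tops
  over one interval.
* Only orthorhombic boxes and height-field (no overhang) membrane surfaces
  are supported.
* Large-membrane deformation runs (multi-million particles, microseconds)
  are far beyond desk scale; the package covers that regime only through
  the property surrogates above, not by reproducing the deformations
  themselves.
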