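# Synthetic-data generators.  These ship in the package (not only in the
# test suite) so that users can calibrate detector thresholds on data with
# known ground truth before pointing the diagnostics at real runs.

#' Generate a synthetic pressure series with a known phase pattern
#'
#' Gaussian white noise plus an additive periodic phase pattern of period
#' `nstlist = length(phase_pattern)`, optionally superposed with a zero-mean
#' sawtooth of shorter period `inner_period` (emulating the beating between
#' outer and inner pair-list updates in dual-list engines).  The closed-form
#' per-phase means are `baseline + phase_pattern + sawtooth aliased onto the
#' outer period`, which makes the generator an exact oracle for
#' [phase_average()] and [delta_p()].
#'
#' @param n_steps Series length in steps.
#' @param dt Time step (ps).
#' @param noise_sd White-noise standard deviation (bar).
#' @param phase_pattern Additive offsets (bar), one per phase; its length
#'   sets `nstlist`.
#' @param inner_period,inner_amplitude Optional inner-list sawtooth.
#' @param baseline Constant offset (bar).
#' @param seed RNG seed (recorded in the provenance attribute).
#' @return A [pressure_series()]; attribute `phase_means` carries the exact
#'   per-phase means.
#' @export
gen_pressure_series <- function(n_steps, dt, noise_sd = 0,
                                phase_pattern = numeric(1),
                                inner_period = NULL, inner_amplitude = 0,
                                baseline = 0, seed = 1L) {
  nstlist <- length(phase_pattern)
  stopifnot(n_steps >= 2, dt > 0, noise_sd >= 0, nstlist >= 1)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  step <- seq_len(n_steps) - 1L
  x <- baseline + phase_pattern[(step %% nstlist) + 1L]
  saw_of_phase <- NULL
  if (!is.null(inner_period)) {
    stopifnot(inner_period >= 2)
    saw <- function(k) {
      inner_amplitude * ((k %% inner_period) / inner_period -
                           (inner_period - 1) / (2 * inner_period))
    }
    x <- x + saw(step)
    saw_of_phase <- saw(0:(nstlist - 1L))
  }
  if (noise_sd > 0) x <- x + rnorm(n_steps, sd = noise_sd)
  out <- pressure_series(x, dt = dt, nstlist = nstlist,
                         provenance = sprintf("gen_pressure_series(seed=%d)", seed))
  pm <- baseline + phase_pattern
  if (!is.null(saw_of_phase)) {
    # exact aliasing of the sawtooth onto the outer period requires the
    # phase means over all interval alignments; with inner_period dividing
    # nstlist the alignment is fixed and the per-phase sawtooth is exact
    if (nstlist %% inner_period == 0) pm <- pm + saw_of_phase
  }
  attr(out, "phase_means") <- pm
  attr(out, "seed") <- seed
  out
}

#' Generate a free-flight (ideal) gas state
#'
#' Uniform random positions in the box and Maxwell-Boltzmann velocities at
#' the requested temperature (per-component variance \eqn{k_B T / m}), with
#' the centre-of-mass momentum removed.  Run it with `forces_on = FALSE` in
#' [run_ljmd()] to validate the missed-interaction model against a
#' simulation whose particles genuinely fly ballistically.
#'
#' @param rho Number density (nm^-3); the particle count is `round(rho * V)`.
#' @param temperature Temperature (K or reduced).
#' @param mass Particle mass (amu or reduced).
#' @param box Length-3 box (nm).
#' @param seed RNG seed.
#' @param units Unit system ([md_units()] or [reduced_units()]).
#' @return A [sim_state()].
#' @export
gen_freeflight_gas <- function(rho, temperature, mass, box, seed = 1L,
                               units = md_units()) {
  check_units(units)
  stopifnot(rho > 0, temperature > 0, mass > 0, length(box) == 3)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  n <- round(rho * prod(box))
  if (n < 2) abort("box too small: fewer than 2 particles at this density")
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  vel <- matrix(rnorm(3 * n, sd = sqrt(units$kB * temperature / mass)), ncol = 3)
  vel <- sweep(vel, 2, colMeans(vel))
  sim_state(pos, vel, box, masses = mass)
}

#' Generate a dense Lennard-Jones fluid state
#'
#' `n` particles on a perturbed simple-cubic lattice at number density
#' `rho`, with Maxwell-Boltzmann velocities (centre-of-mass momentum
#' removed).  Intended as the starting point for desk-scale reduced-unit
#' runs (equilibrate briefly with a thermostat before measuring).
#'
#' @param n Particle count.
#' @param rho Number density (sigma^-3 in reduced units).
#' @param temperature Temperature (epsilon/kB in reduced units).
#' @param mass Particle mass.
#' @param seed RNG seed.
#' @param units Unit system; defaults to [reduced_units()].
#' @param jitter Lattice perturbation as a fraction of the lattice spacing.
#' @return A [sim_state()].
#' @export
gen_lj_fluid <- function(n, rho, temperature, mass = 1, seed = 1L,
                         units = reduced_units(), jitter = 0.05) {
  check_units(units)
  stopifnot(n >= 2, rho > 0, temperature > 0)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  L <- (n / rho)^(1 / 3)
  m <- ceiling(n^(1 / 3))
  a <- L / m
  g <- expand.grid(i = 0:(m - 1), j = 0:(m - 1), k = 0:(m - 1))
  g <- g[seq_len(n), ]
  pos <- (as.matrix(g) + 0.5) * a +
    matrix(runif(3 * n, -jitter * a, jitter * a), ncol = 3)
  vel <- matrix(rnorm(3 * n, sd = sqrt(units$kB * temperature / mass)), ncol = 3)
  vel <- sweep(vel, 2, colMeans(vel))
  sim_state(pos, vel, c(L, L, L), masses = mass)
}

#' Generate a height field with known analytic curvature energy
#'
#' Builds a flat, single-sinusoid or two-orthogonal-sinusoid height field on
#' an `n` x `n` periodic grid and returns, alongside the field, its exact
#' small-slope bending energy: for \eqn{h = a \sin(2\pi q x / L)} the
#' Helfrich energy \eqn{2\kappa\int H^2 dA} tends to
#' \eqn{(\kappa/2)\, a^2 (2\pi q/L)^4 \, L_x L_y / 2}, and superposed
#' orthogonal modes add (the energy is quadratic).
#'
#' @param mode `"flat"`, `"sinusoid"` or `"superposition"`.
#' @param n Grid points per side.
#' @param L Box edge (nm); square box.
#' @param amplitude Mode amplitude(s): one value, or two for superposition.
#' @param q Integer mode number(s) along x (and y for superposition).
#' @return List with `field` (a [height_field()]) and `E_analytic`, a
#'   function of `kappa` (kJ/mol) returning the small-slope energy in
#'   kJ/mol.
#' @export
gen_height_field <- function(mode = c("flat", "sinusoid", "superposition"),
                             n = 128, L = 50, amplitude = 0.25, q = 1L) {
  mode <- match.arg(mode)
  xs <- (seq_len(n) - 1) / n * L
  mk <- function(a, qq, axis) {
    phase <- outer(xs, xs, function(x, y) if (axis == "x") x else y)
    a * sin(2 * pi * qq * phase / L)
  }
  if (mode == "flat") {
    h <- matrix(0, n, n)
    modes <- list()
  } else if (mode == "sinusoid") {
    h <- mk(amplitude[1], q[1], "x")
    modes <- list(c(a = amplitude[1], q = q[1]))
  } else {
    if (length(amplitude) == 1) amplitude <- rep(amplitude, 2)
    if (length(q) == 1) q <- rep(q, 2)
    h <- mk(amplitude[1], q[1], "x") + mk(amplitude[2], q[2], "y")
    modes <- list(c(a = amplitude[1], q = q[1]), c(a = amplitude[2], q = q[2]))
  }
  e_one <- function(a, qq, kappa) kappa / 2 * a^2 * (2 * pi * qq / L)^4 * L^2 / 2
  list(field = height_field(h, dx = L / n),
       E_analytic = function(kappa) {
         if (!length(modes)) return(0)
         sum(vapply(modes, function(m) e_one(m["a"], m["q"], kappa), 1.0))
       })
}
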