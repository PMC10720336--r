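#' Truncated-and-shifted Lennard-Jones potential
#'
#' \eqn{u(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] - u_{raw}(r_c)} for
#' \eqn{r < r_c}, zero beyond.  The energy shift makes \eqn{u(r_c) = 0}; the
#' force is the unshifted LJ force, continuous for \eqn{r < r_c}.  No tail
#' corrections are applied: they would partially offset the very
#' missed-interaction signal the simulator is instrumented to expose.
#'
#' @param epsilon Well depth (kJ/mol, or 1 in reduced units).
#' @param sigma Particle diameter (nm, or 1).
#' @param r_c Interaction cutoff (defaults to `2.5 * sigma`).
#' @return An object of class `"lj_potential"`.
#' @export
lj_potential <- function(epsilon = 1, sigma = 1, r_c = 2.5 * sigma) {
  stopifnot(epsilon > 0, sigma > 0, r_c > 0)
  structure(list(epsilon = epsilon, sigma = sigma, r_c = r_c,
                 shift = -4 * epsilon * ((sigma / r_c)^12 - (sigma / r_c)^6)),
            class = "lj_potential")
}

#' Simulation state
#'
#' Particle positions and velocities in an orthorhombic periodic box.
#' Positions are wrapped into `[0, L)` on construction.
#'
#' @param positions N x 3 matrix (nm).
#' @param velocities N x 3 matrix (nm/ps).
#' @param box Length-3 vector of box edges (nm).
#' @param masses Length-N vector (amu) or a scalar recycled to N.
#' @param step Integration step counter.
#' @return An object of class `"sim_state"`.
#' @export
sim_state <- function(positions, velocities, box, masses, step = 0L) {
  positions <- as.matrix(positions); velocities <- as.matrix(velocities)
  n <- nrow(positions)
  if (n < 2 || ncol(positions) != 3) abort("positions must be an N x 3 matrix, N >= 2")
  if (!all(dim(velocities) == c(n, 3))) abort("velocities must match positions")
  if (length(box) != 3 || any(box <= 0)) abort("box must be 3 positive lengths")
  if (length(masses) == 1) masses <- rep(masses, n)
  if (length(masses) != n || any(masses <= 0)) abort("need N positive masses")
  positions <- sweep(positions, 2, box, function(x, L) x - L * floor(x / L))
  structure(list(positions = positions, velocities = velocities,
                 box = as.numeric(box), masses = as.numeric(masses),
                 step = as.integer(step)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state>", nrow(x$positions), "particles; box =",
      paste(signif(x$box, 5), collapse = " x "), "nm; step =", x$step, "\n")
  invisible(x)
}

check_box_for_rl <- function(box, r_l) {
  if (min(box) <= 2 * r_l) {
    abort(sprintf(
      "box lengths (min %.4g) must exceed 2*r_l = %.4g for minimum-image validity",
      min(box), 2 * r_l))
  }
}

#' Build a Verlet neighbor list
#'
#' Cell-list search for all particle pairs within the outer cutoff `r_l`
#' under the minimum-image convention.  The pair set is identical to a
#' brute-force O(N^2) search (`method = "brute"`, kept as the oracle).
#'
#' @param state A [sim_state()].
#' @param cutoffs A [cutoff_scheme()] (its `r_l` is used).
#' @param method `"cell"` (default) or `"brute"`.
#' @return An object of class `"neighbor_list"` with a `pairs` matrix
#'   (i < j, 1-based), `built_at_step` and `r_l`.
#' @export
build_neighbor_list <- function(state, cutoffs, method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(state, "sim_state"), inherits(cutoffs, "cutoff_scheme"))
  check_box_for_rl(state$box, cutoffs$r_l)
  pairs <- cpp_build_pairs(state$positions, state$box, cutoffs$r_l,
                           method == "brute")
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  structure(list(pairs = pairs, built_at_step = state$step, r_l = cutoffs$r_l),
            class = "neighbor_list")
}

#' @export
print.neighbor_list <- function(x, ...) {
  cat("<neighbor_list>", nrow(x$pairs), "pairs within r_l =", x$r_l,
      "nm (built at step", paste0(x$built_at_step, ")"), "\n")
  invisible(x)
}

#' Forces, potential energy and virial over a pair list
#'
#' Evaluates the truncated-and-shifted LJ interaction for every listed pair
#' whose *current* minimum-image distance is below `r_c` (the list may be
#' stale).  The virial tensor is \eqn{W_{\alpha\beta} = \sum_{pairs}
#' r_{ij,\alpha} f_{ij,\beta}}.
#'
#' @param state A [sim_state()].
#' @param potential An [lj_potential()].
#' @param nlist A [build_neighbor_list()] result.
#' @return List with `forces` (N x 3), `energy` (scalar) and `virial` (3 x 3).
#' @export
forces_energy_virial <- function(state, potential, nlist) {
  stopifnot(inherits(potential, "lj_potential"), inherits(nlist, "neighbor_list"))
  cpp_forces(state$positions, state$box, nlist$pairs, potential$epsilon,
             potential$sigma, potential$r_c)
}

#' Instantaneous virial pressure
#'
#' \eqn{P_{\alpha\beta} = (\sum_i m_i v_{i\alpha} v_{i\beta} +
#' W_{\alpha\beta}) / V} times the pressure conversion factor.  Also reports
#' the scalar pressure (trace/3), the lateral component
#' \eqn{P_\parallel = (P_{xx}+P_{yy})/2} and the normal component
#' \eqn{P_\perp = P_{zz}} used in membrane diagnostics.
#'
#' @param state A [sim_state()].
#' @param virial 3 x 3 virial tensor (e.g. from [forces_energy_virial()]);
#'   defaults to zero (ideal gas).
#' @param units Unit system, see [md_units()].
#' @return One-row tibble with class `"pressure_sample"`: columns `step`,
#'   `P`, `Pxx`, `Pyy`, `Pzz`, `P_par`, `P_perp`, plus kinetic (`K*`) and
#'   virial (`W*`) diagonal parts in bar.
#' @export
instantaneous_pressure <- function(state, virial = matrix(0, 3, 3),
                                   units = md_units()) {
  check_units(units)
  v <- state$velocities
  K <- crossprod(v * sqrt(state$masses))  # sum m v_a v_b
  V <- prod(state$box)
  Pt <- (K + virial) / V * units$pressure_factor
  tibble(step = state$step,
         P = sum(diag(Pt)) / 3,
         Pxx = Pt[1, 1], Pyy = Pt[2, 2], Pzz = Pt[3, 3],
         P_par = (Pt[1, 1] + Pt[2, 2]) / 2, P_perp = Pt[3, 3],
         Kxx = K[1, 1] / V * units$pressure_factor,
         Kyy = K[2, 2] / V * units$pressure_factor,
         Kzz = K[3, 3] / V * units$pressure_factor,
         Wxx = virial[1, 1] / V * units$pressure_factor,
         Wyy = virial[2, 2] / V * units$pressure_factor,
         Wzz = virial[3, 3] / V * units$pressure_factor)
}

#' Count interactions missing from a pair list
#'
#' Brute-force scan for pairs whose current minimum-image distance is below
#' the interaction cutoff `r_c` yet which are absent from the (possibly
#' stale) list — exactly the interactions a force evaluation using that list
#' would miss.
#'
#' @param state A [sim_state()].
#' @param potential An [lj_potential()] (its `r_c` is used).
#' @param nlist A [build_neighbor_list()] result.
#' @return List with `n_missing` and the `pairs` matrix of offenders.
#' @export
count_missed <- function(state, potential, nlist) {
  mp <- cpp_missing_pairs(state$positions, state$box, nlist$pairs,
                          potential$r_c)
  list(n_missing = nrow(mp), pairs = mp)
}

#' Berendsen-type barostat configuration
#'
#' Weak-coupling box rescaler: every `interval` steps each coupled dimension
#' group is scaled by \eqn{\mu_\alpha = [1 - \Delta t_{couple} \kappa
#' (P_0 - P_\alpha) / \tau_p]^{1/3}}.  `"isotropic"` couples all axes to the
#' scalar pressure, `"semi-isotropic"` couples (x, y) jointly to
#' \eqn{P_\parallel} and z to \eqn{P_\perp}, `"anisotropic"` couples each
#' axis to its own diagonal component.
#'
#' @param mode One of `"none"`, `"isotropic"`, `"semi-isotropic"`,
#'   `"anisotropic"`.
#' @param tau_p Coupling time constant (ps).
#' @param target Target pressure (bar).
#' @param compressibility Isothermal compressibility (bar^-1).
#' @param interval Steps between barostat actions (`nstpcouple`).
#' @return An object of class `"barostat_config"`.
#' @export
barostat_config <- function(mode = c("none", "isotropic", "semi-isotropic",
                                     "anisotropic"),
                            tau_p = 12, target = 1,
                            compressibility = 4.5e-5, interval = 1L) {
  mode <- match.arg(mode)
  stopifnot(tau_p > 0, compressibility > 0, interval >= 1)
  structure(list(mode = mode, tau_p = tau_p, target = target,
                 compressibility = compressibility,
                 interval = as.integer(interval)),
            class = "barostat_config")
}

#' Run an instrumented Lennard-Jones MD simulation
#'
#' Velocity-Verlet dynamics with a Verlet neighbor list rebuilt every
#' `nstlist` steps (dual mode: an inner list, drawn from the outer pool
#' within `r_inner`, rebuilt every `nstlist_inner` steps and used for the
#' forces).  Optional velocity-rescaling thermostat and Berendsen-type
#' barostat.  The run is instrumented: at every force evaluation the engine
#' scans for pairs within `r_c` that are absent from the active force list
#' and logs, per list lifetime, the number of unique missed pairs and of
#' missed (pair, step) evaluations.
#'
#' Stability is the caller's responsibility: choose `dt` small against the
#' shortest oscillation period (reduced units: `dt = 0.002` is conservative
#' at liquid densities).  Divergence (non-finite energies) aborts with the
#' step number.
#'
#' @param state Initial [sim_state()].
#' @param potential An [lj_potential()]; set `forces_on = FALSE` for
#'   free-flight (ideal-gas) runs that keep the instrumentation.
#' @param cutoffs A [cutoff_scheme()] (single or dual).
#' @param schedule A [schedule_config()] (`dt`, `nstlist`, `nsttcouple`).
#' @param n_steps Number of integration steps.
#' @param thermostat `"none"` or `"v-rescale"`; rescales velocities to
#'   `temperature` every `schedule$nsttcouple` steps.
#' @param temperature Thermostat target (K or reduced).
#' @param barostat A [barostat_config()].
#' @param units Unit system ([md_units()] or [reduced_units()]).
#' @param forces_on Evaluate forces? `FALSE` gives free flight.
#' @param count_misses Instrument missed interactions?
#' @param miss_safety Safety factor on the shadow-list margin.
#' @return An object of class `"ljmd_run"`: a list with tibbles `pressure`
#'   (per-step diagonal pressure tensor, scalar, lateral/normal split,
#'   kinetic/virial parts), `energy`, `box`, `misses` (per list lifetime),
#'   the `final_state`, and the run parameters.
#' @export
run_ljmd <- function(state, potential, cutoffs, schedule, n_steps,
                     thermostat = c("none", "v-rescale"), temperature = NULL,
                     barostat = barostat_config("none"),
                     units = md_units(), forces_on = TRUE,
                     count_misses = TRUE, miss_safety = 1.5) {
  thermostat <- match.arg(thermostat)
  stopifnot(inherits(state, "sim_state"), inherits(potential, "lj_potential"),
            inherits(cutoffs, "cutoff_scheme"),
            inherits(schedule, "schedule_config"),
            inherits(barostat, "barostat_config"))
  check_units(units)
  check_box_for_rl(state$box, cutoffs$r_l)
  if (abs(potential$r_c - cutoffs$r_c) > 1e-12) {
    abort("potential$r_c and cutoffs$r_c disagree; use the same interaction cutoff")
  }
  if (thermostat == "v-rescale" && is.null(temperature)) {
    abort("v-rescale thermostat needs a target temperature")
  }
  if (cutoffs$dual && schedule$nstlist %% cutoffs$nstlist_inner != 0L) {
    abort("nstlist_inner must divide nstlist")
  }
  baro_mode <- match(barostat$mode,
                     c("none", "isotropic", "semi-isotropic", "anisotropic")) - 1L
  raw <- cpp_run_md(state$positions, state$velocities, state$box, state$masses,
                    potential$epsilon, potential$sigma, potential$r_c,
                    cutoffs$r_l, schedule$nstlist, cutoffs$dual,
                    ifelse(cutoffs$dual, cutoffs$r_inner, cutoffs$r_l),
                    ifelse(cutoffs$dual, cutoffs$nstlist_inner, 1L),
                    schedule$dt, as.integer(n_steps),
                    ifelse(thermostat == "v-rescale", 1L, 0L),
                    ifelse(is.null(temperature), 0, temperature),
                    schedule$nsttcouple,
                    baro_mode, barostat$tau_p, barostat$target,
                    barostat$compressibility, barostat$interval,
                    units$kB, units$pressure_factor,
                    forces_on, count_misses, miss_safety)
  pressure <- tibble(
    step = raw$step,
    time = raw$step * schedule$dt,
    P = raw$p_scalar,
    Pxx = raw$pdiag[, 1], Pyy = raw$pdiag[, 2], Pzz = raw$pdiag[, 3],
    P_par = (raw$pdiag[, 1] + raw$pdiag[, 2]) / 2, P_perp = raw$pdiag[, 3],
    Kxx = raw$kdiag[, 1], Kyy = raw$kdiag[, 2], Kzz = raw$kdiag[, 3],
    Wxx = raw$wdiag[, 1], Wyy = raw$wdiag[, 2], Wzz = raw$wdiag[, 3])
  energy <- tibble(step = raw$step, epot = raw$epot, ekin = raw$ekin,
                   etot = raw$epot + raw$ekin)
  box <- tibble(step = raw$step, Lx = raw$box[, 1], Ly = raw$box[, 2],
                Lz = raw$box[, 3])
  misses <- tibble(build_step = raw$miss_build_step,
                   n_unique = raw$miss_unique, n_events = raw$miss_events)
  final_state <- sim_state(raw$pos, raw$vel, raw$box_final, state$masses,
                           step = state$step + as.integer(n_steps))
  structure(list(pressure = pressure, energy = energy, box = box,
                 misses = misses, final_state = final_state,
                 schedule = schedule, cutoffs = cutoffs,
                 potential = potential, units = units,
                 n_particles = nrow(state$positions)),
            class = "ljmd_run")
}

#' @export
print.ljmd_run <- function(x, ...) {
  n <- nrow(x$pressure) - 1L
  cat("<ljmd_run>", x$n_particles, "particles,", n, "steps (dt =",
      x$schedule$dt, "); nstlist =", x$schedule$nstlist, "\n")
  cat("  mean P =", signif(mean(x$pressure$P), 5),
      "; unique missed pairs per interval (mean) =",
      signif(mean(x$misses$n_unique), 4), "\n")
  invisible(x)
}

#' @export
tidy.ljmd_run <- function(x, ...) x$pressure

#' @export
glance.ljmd_run <- function(x, ...) {
  e <- x$energy
  tibble(n_particles = x$n_particles, n_steps = nrow(e) - 1L,
         mean_P = mean(x$pressure$P),
         mean_epot = mean(e$epot), mean_ekin = mean(e$ekin),
         energy_drift_per_particle = (e$etot[nrow(e)] - e$etot[1]) / x$n_particles,
         mean_missed_unique = mean(x$misses$n_unique),
         mean_missed_events = mean(x$misses$n_events))
}

#' Per-particle unique missed pairs per update interval
#'
#' Converts the per-lifetime miss log of an [run_ljmd()] result into the
#' per-particle, per-interval unit used by the analytic model: each missed
#' pair involves two particles, so the per-particle count is
#' `2 * n_unique / N`.  Only complete intervals are used.
#'
#' @param run An `"ljmd_run"`.
#' @return Tibble with per-interval values and a `mean`/`se` summary as
#'   attributes `mean` and `se`.
#' @export
misses_per_particle <- function(run) {
  stopifnot(inherits(run, "ljmd_run"))
  m <- run$misses
  complete <- m$build_step + run$schedule$nstlist <= max(run$pressure$step)
  m <- m[complete, , drop = FALSE]
  per <- 2 * m$n_unique / run$n_particles
  out <- tibble(build_step = m$build_step, n_missed_per_particle = per)
  attr(out, "mean") <- mean(per)
  attr(out, "se") <- sd(per) / sqrt(length(per))
  out
}
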