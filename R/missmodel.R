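#' Ideal-gas model of a fluid for missed-interaction estimates
#'
#' The missed-interaction model treats the fluid as point particles (or rigid
#' molecules) uniformly distributed in space with number density `rho`,
#' moving ballistically with Maxwell-Boltzmann velocities at temperature
#' `temperature`.  This free-flight picture is what makes closed-form and
#' Monte-Carlo estimates of neighbor-list misses tractable; it is accurate
#' when the buffer is crossed in a time short compared to the collision time.
#'
#' For rigid molecules supply `sites`, a data frame with columns `type`,
#' `x`, `y`, `z` (site offsets in nm) and `mass` (amu).  Offsets are
#' re-centred on the centre of mass and rotated into the principal frame;
#' the principal moments of inertia are computed from the site geometry.
#' `rho` is then the molecule number density.
#'
#' @param rho Number density (nm^-3) of particles (or molecules).
#' @param mass Particle mass in amu; for rigid molecules the total mass is
#'   taken from the sites and `mass` may be omitted.
#' @param temperature Temperature in K (or reduced units).
#' @param sites Optional data frame of rigid-molecule sites (see Details).
#' @param units Unit system, see [md_units()].
#' @return An object of class `"gas_model"`.
#' @examples
#' # Martini-water-like bead fluid: 1530 beads in a (6 nm)^3 box
#' gas_model(rho = 1530 / 6^3, mass = 72, temperature = 310)
#' @export
gas_model <- function(rho, mass = NULL, temperature, sites = NULL,
                      units = md_units()) {
  stopifnot(rho > 0, temperature > 0)
  check_units(units)
  if (is.null(sites)) {
    if (is.null(mass) || mass <= 0) abort("point model requires mass > 0")
    return(structure(list(rho = rho, mass = mass, temperature = temperature,
                          sites = NULL, units = units), class = "gas_model"))
  }
  req <- c("type", "x", "y", "z", "mass")
  if (!all(req %in% names(sites))) {
    abort("`sites` needs columns type, x, y, z, mass")
  }
  if (any(sites$mass <= 0)) abort("site masses must be positive")
  M <- sum(sites$mass)
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  com <- colSums(xyz * sites$mass) / M
  xyz <- sweep(xyz, 2, com)
  # inertia tensor and principal frame
  I <- matrix(0, 3, 3)
  for (k in seq_len(nrow(xyz))) {
    d <- xyz[k, ]
    I <- I + sites$mass[k] * (sum(d^2) * diag(3) - tcrossprod(d))
  }
  eig <- eigen(I, symmetric = TRUE)
  axes <- eig$vectors
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  principal <- xyz %*% axes
  moments <- pmax(eig$values, 0)
  # a vanishing moment about an axis requires all sites to sit on that axis
  for (a in 1:3) {
    perp <- sqrt(rowSums(principal[, -a, drop = FALSE]^2))
    if (moments[a] <= 1e-12 * max(moments, 1e-12) && any(perp > 1e-9)) {
      abort("zero moment of inertia with nonzero site offset off that axis")
    }
  }
  structure(list(rho = rho, mass = M, temperature = temperature,
                 sites = tibble(type = as.character(sites$type),
                                x = principal[, 1], y = principal[, 2],
                                z = principal[, 3], mass = sites$mass),
                 moments = moments, units = units),
            class = "gas_model")
}

#' @export
print.gas_model <- function(x, ...) {
  cat("<gas_model> rho =", x$rho, "nm^-3; mass =", x$mass, "amu; T =",
      x$temperature, "\n")
  if (!is.null(x$sites)) {
    cat("  rigid molecule with", nrow(x$sites), "sites; principal moments =",
        signif(x$moments, 4), "amu nm^2\n")
  }
  invisible(x)
}

# per-component sd of the relative free-flight displacement over time t
sigma_rel <- function(gas, t, m1 = gas$mass, m2 = gas$mass) {
  t * sqrt(gas$units$kB * gas$temperature * (1 / m1 + 1 / m2))
}

#' Probability that a pair beyond the list cutoff ends inside the cutoff
#'
#' For a pair at initial separation `r > r_l`, free flight over time `t`
#' displaces the relative coordinate by an isotropic Gaussian with
#' per-component standard deviation
#' \eqn{\sigma_t = t \sqrt{k_B T (1/m_1 + 1/m_2)}}
#' (reduced-mass form; for equal masses \eqn{\sqrt{2 k_B T/m}}).  This
#' function returns the closed-form probability that the displaced pair ends
#' at a distance below the interaction cutoff `r_c`:
#' \deqn{P = \Phi\!\left(\frac{r_c - r}{\sigma_t}\right)
#'        - \Phi\!\left(\frac{-(r_c + r)}{\sigma_t}\right)
#'        + \frac{\sigma_t}{r\sqrt{2\pi}}\left[
#'            e^{-(r_c + r)^2 / 2\sigma_t^2} - e^{-(r_c - r)^2 / 2\sigma_t^2}
#'          \right]}
#' This endpoint probability underlies the fast analytic estimate in
#' [n_missed_point()]; the sampling-based path estimate is the reference.
#'
#' @param r Initial separation(s), nm (> 0).  Misses only involve pairs with
#'   `r > r_l`, but the probability itself is a pure geometric quantity and
#'   is defined for any positive separation.
#' @param cutoffs A [cutoff_scheme()].
#' @param t Flight time (ps).
#' @param gas A [gas_model()].
#' @return Probability (vectorised over `r`).
#' @export
crossing_probability_endpoint <- function(r, cutoffs, t, gas) {
  stopifnot(inherits(cutoffs, "cutoff_scheme"), inherits(gas, "gas_model"))
  if (any(r <= 0)) abort("r must be positive")
  if (t < 0) abort("t must be >= 0")
  s <- sigma_rel(gas, t)
  if (s == 0) return(rep(0, length(r)))
  rc <- cutoffs$r_c
  pnorm((rc - r) / s) - pnorm(-(rc + r) / s) +
    (s / (r * sqrt(2 * pi))) *
      (exp(-(rc + r)^2 / (2 * s^2)) - exp(-(rc - r)^2 / (2 * s^2)))
}

miss_estimate <- function(n_missed, per_step, stderr, method, seed = NA_integer_,
                          extra = list()) {
  structure(c(list(n_missed = n_missed, per_step = per_step, stderr = stderr,
                   method = method, seed = seed), extra),
            class = "miss_estimate")
}

#' @export
print.miss_estimate <- function(x, ...) {
  cat("<miss_estimate>", format(x$n_missed, digits = 4),
      "unique missed pair interactions per particle per update interval\n")
  cat("  per-step (pair,step) evaluations missed:",
      format(x$per_step, digits = 4), "\n")
  cat("  method:", x$method, "; MC stderr:", format(x$stderr, digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.miss_estimate <- function(x, ...) {
  tibble(n_missed = x$n_missed, per_step = x$per_step, stderr = x$stderr,
         method = x$method, seed = x$seed)
}

# shared path-MC core: free-flight pair sampling between list rebuilds.
# Returns per-sample unique-miss indicators and event counts, plus the shell
# volume; optionally the distances at offending evaluations (for drift_rate).
path_mc_point <- function(cutoffs, schedule, gas, n_samples, seed,
                          keep_distances = FALSE) {
  rl <- cutoffs$r_l; rc <- cutoffs$r_c
  nst <- schedule$nstlist; dt <- schedule$dt
  t_int <- nst * dt
  s_int <- sigma_rel(gas, t_int)
  rmax <- rl + 8 * s_int
  if (nst <= 1L || s_int == 0) {
    return(list(miss = numeric(0), events = numeric(0),
                vshell = 0, distances = numeric(0)))
  }
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  # uniform positions in the shell [rl, rmax] (volume weighted)
  u <- runif(n_samples)
  r0 <- (u * (rmax^3 - rl^3) + rl^3)^(1 / 3)
  dir <- matrix(rnorm(3 * n_samples), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  pos0 <- dir * r0
  sv <- sigma_rel(gas, 1)  # per-component relative velocity sd
  vel <- matrix(rnorm(3 * n_samples, sd = sv), ncol = 3)
  miss <- logical(n_samples)
  events <- integer(n_samples)
  distances <- if (keep_distances) vector("list", nst - 1L) else NULL
  for (k in seq_len(nst - 1L)) {
    p <- pos0 + vel * (k * dt)
    d2 <- rowSums(p^2)
    hit <- d2 < rc^2
    miss <- miss | hit
    events <- events + hit
    if (keep_distances && any(hit)) distances[[k]] <- sqrt(d2[hit])
  }
  list(miss = as.numeric(miss), events = as.numeric(events),
       vshell = 4 / 3 * pi * (rmax^3 - rl^3),
       distances = if (keep_distances) unlist(distances) else numeric(0))
}

# set.seed with restoration of the caller's RNG state
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Expected missed pair interactions per particle per update interval
#'
#' Estimates the expected number of *unique* pair interactions a particle
#' misses between two neighbor-list rebuilds: pairs that are beyond the outer
#' cutoff `r_l` when the list is built, yet come within the interaction
#' cutoff `r_c` at one of the force-evaluation steps before the next rebuild.
#'
#' Two estimators are provided.
#' * `"path-mc"` (reference definition): sample initial separations uniformly
#'   in the shell above `r_l` and Maxwell-Boltzmann relative velocities, then
#'   follow the free-flight path over the evaluation times
#'   \eqn{k\,\Delta t}, \eqn{k = 1 \dots \mathrm{nstlist}-1}; a sampled pair
#'   is a miss if its separation drops below `r_c` at any of them.  The
#'   estimate is \eqn{\rho V_{shell}} times the missed fraction, with a
#'   binomial-style Monte-Carlo standard error; `per_step` counts every
#'   offending \eqn{(pair, step)} evaluation.
#' * `"endpoint"`: fast closed form,
#'   \eqn{\rho \int_{r_l}^{R_{max}} P_{cross}(r)\, 4\pi r^2\, dr} with
#'   \eqn{P_{cross}} from [crossing_probability_endpoint()] evaluated at the
#'   full interval time \eqn{t = \mathrm{nstlist}\,\Delta t}, by adaptive
#'   quadrature with \eqn{R_{max} = r_l + 8\sigma_t}.  It considers only the
#'   end of the interval, so it approximates the path estimate (typically
#'   within tens of percent) at negligible cost.
#'
#' @param cutoffs A [cutoff_scheme()].
#' @param schedule A [schedule_config()].
#' @param gas A point-particle [gas_model()].
#' @param mode `"endpoint"` or `"path-mc"`.
#' @param n_samples Monte-Carlo sample count (path mode).
#' @param seed RNG seed (path mode); recorded in the result.
#' @return A `miss_estimate` with fields `n_missed`, `per_step`, `stderr`,
#'   `method`, `seed`.
#' @examples
#' gas <- gas_model(rho = 7.08, mass = 72, temperature = 310)
#' sched <- schedule_config(dt = 0.02, nstlist = 25)
#' n_missed_point(cutoff_scheme(1.1, 1.28), sched, gas)
#' @export
n_missed_point <- function(cutoffs, schedule, gas,
                           mode = c("endpoint", "path-mc"),
                           n_samples = 200000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cutoffs, "cutoff_scheme"), inherits(schedule, "schedule_config"),
            inherits(gas, "gas_model"))
  if (!is.null(gas$sites)) abort("n_missed_point needs a point-particle gas_model")
  if (mode == "endpoint") {
    t_int <- schedule$nstlist * schedule$dt
    s <- sigma_rel(gas, t_int)
    if (s == 0) return(miss_estimate(0, NA_real_, 0, "endpoint-closed-form"))
    rmax <- cutoffs$r_l + 8 * s
    f <- function(r) crossing_probability_endpoint(r, cutoffs, t_int, gas) * 4 * pi * r^2
    # open lower endpoint: P is defined only for r > r_l
    q <- integrate(f, cutoffs$r_l + 1e-12, rmax, rel.tol = 1e-8,
                   subdivisions = 500L)
    miss_estimate(gas$rho * q$value, NA_real_, 0, "endpoint-closed-form")
  } else {
    mc <- path_mc_point(cutoffs, schedule, gas, n_samples, seed)
    if (mc$vshell == 0) {
      return(miss_estimate(0, 0, 0, "path-MC", seed))
    }
    scale <- gas$rho * mc$vshell
    n <- length(mc$miss)
    miss_estimate(scale * mean(mc$miss), scale * mean(mc$events),
                  scale * sd(mc$miss) / sqrt(n), "path-MC", seed,
                  extra = list(per_step_stderr = scale * sd(mc$events) / sqrt(n),
                               n_samples = n))
  }
}

#' Recommend an outer list cutoff for a tolerated miss rate
#'
#' Finds the smallest outer cutoff `r_l >= r_c` (bisection to 1e-3 nm) such
#' that the expected number of unique missed pair interactions per particle
#' per update interval, from the endpoint estimate of [n_missed_point()],
#' does not exceed `tolerance`.  The recommendation grows with
#' `nstlist * dt`, temperature and density, and shrinks as the tolerance is
#' relaxed; if even a zero buffer satisfies the tolerance, `r_c` is returned.
#'
#' @param schedule A [schedule_config()].
#' @param gas A point-particle [gas_model()].
#' @param r_c Interaction cutoff (nm).
#' @param tolerance Maximum tolerated `n_missed` per particle per interval.
#' @return Recommended `r_l` in nm.
#' @examples
#' gas <- gas_model(rho = 7.08, mass = 72, temperature = 310)
#' recommend_rl(schedule_config(dt = 0.02, nstlist = 20), gas, r_c = 1.1,
#'              tolerance = 1e-4)
#' @export
recommend_rl <- function(schedule, gas, r_c, tolerance) {
  stopifnot(tolerance > 0)
  nm <- function(rl) {
    n_missed_point(cutoff_scheme(r_c, rl), schedule, gas, mode = "endpoint")$n_missed
  }
  if (nm(r_c) <= tolerance) return(r_c)
  s <- sigma_rel(gas, schedule$nstlist * schedule$dt)
  hi <- r_c + s
  while (nm(hi) > tolerance) hi <- hi + s
  lo <- r_c
  while (hi - lo > 1e-3) {
    mid <- (hi + lo) / 2
    if (nm(mid) > tolerance) lo <- mid else hi <- mid
  }
  hi
}

#' Energy-drift analog of missed interactions
#'
#' Order-of-magnitude analog of a maximum-energy-drift tolerance: the
#' per-step missed (pair, step) evaluation rate from the path Monte-Carlo
#' estimator, times the mean absolute truncated-shifted Lennard-Jones pair
#' energy over the distribution of missed-pair distances, divided by the
#' update interval length.  Units: kJ/mol per particle per ps.  This is a
#' diagnostic scale for how much interaction energy goes unaccounted between
#' rebuilds, not a reimplementation of any engine's internal buffer-tolerance
#' machinery.
#'
#' @param cutoffs A [cutoff_scheme()].
#' @param schedule A [schedule_config()].
#' @param gas A point-particle [gas_model()].
#' @param epsilon,sigma Lennard-Jones parameters (kJ/mol, nm).
#' @param n_samples,seed Monte-Carlo controls.
#' @return Drift estimate in kJ/mol/ps per particle (0 when nothing is missed).
#' @export
drift_rate <- function(cutoffs, schedule, gas, epsilon, sigma,
                       n_samples = 200000L, seed = 1L) {
  stopifnot(epsilon > 0, sigma > 0)
  mc <- path_mc_point(cutoffs, schedule, gas, n_samples, seed,
                      keep_distances = TRUE)
  if (mc$vshell == 0 || !any(mc$events > 0)) return(0)
  per_step <- gas$rho * mc$vshell * mean(mc$events)
  u <- function(r) {
    sr6 <- (sigma / r)^6
    4 * epsilon * (sr6^2 - sr6) - (4 * epsilon * ((sigma / cutoffs$r_c)^12 -
                                                    (sigma / cutoffs$r_c)^6))
  }
  mean_u <- mean(abs(u(mc$distances)))
  per_step * mean_u / (schedule$nstlist * schedule$dt)
}
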