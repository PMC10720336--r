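# Rigid-molecule Monte-Carlo estimate of missed site-pair interactions.
#
# Molecules fly and tumble freely between list rebuilds: centre-of-mass
# motion is ballistic with Maxwell-Boltzmann velocities for the total mass,
# and rotation is propagated with the body-frame angular velocity held
# constant (drawn per principal axis with variance kB*T/I).  Holding the
# body-frame angular velocity fixed is exact for spherical tops and a
# short-time approximation otherwise; buffer-crossing times are a few tenths
# of a ps, where free precession corrections are negligible.

# n random rotation matrices via uniform quaternions; returns n x 9 matrix
# with columns R11,R12,R13,R21,...,R33 (row-major).
random_rotations <- function(n) {
  q <- matrix(rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

# Rotate the fixed body vector `o` by angle theta (n-vector) about unit axes
# `u` (n x 3), then by the sample rotations R (n x 9).  Returns n x 3.
rotate_offset <- function(o, u, theta, R) {
  ct <- cos(theta); st <- sin(theta)
  uo <- u[, 1] * o[1] + u[, 2] * o[2] + u[, 3] * o[3]
  cx <- u[, 2] * o[3] - u[, 3] * o[2]
  cy <- u[, 3] * o[1] - u[, 1] * o[3]
  cz <- u[, 1] * o[2] - u[, 2] * o[1]
  bx <- o[1] * ct + cx * st + u[, 1] * uo * (1 - ct)
  by <- o[2] * ct + cy * st + u[, 2] * uo * (1 - ct)
  bz <- o[3] * ct + cz * st + u[, 3] * uo * (1 - ct)
  cbind(R[, 1] * bx + R[, 2] * by + R[, 3] * bz,
        R[, 4] * bx + R[, 5] * by + R[, 6] * bz,
        R[, 7] * bx + R[, 8] * by + R[, 9] * bz)
}

#' Expected missed site-pair interactions for rigid molecules
#'
#' Monte-Carlo estimate of the expected number of unique missed interactions
#' between sites of type `pair_type[1]` on one molecule and `pair_type[2]`
#' on another, per molecule per neighbor-list update interval.  A site pair
#' is missed when its distance exceeds the outer cutoff `r_l` at list build
#' time but drops below the interaction cutoff `r_c` at one of the
#' force-evaluation steps before the next rebuild, under rigid-body free
#' flight (ballistic centre-of-mass motion plus thermal tumbling).
#'
#' Light peripheral sites (e.g. hydrogens ~0.1 nm off the centre of a
#' water-like molecule) swing fast under thermal rotation, so their pairs are
#' missed far more often than heavy central sites at identical cutoffs.
#'
#' @param cutoffs A [cutoff_scheme()]; the same cutoffs are applied to the
#'   selected site pair.
#' @param schedule A [schedule_config()].
#' @param gas A [gas_model()] with rigid-molecule `sites`.
#' @param pair_type Character vector of two site types, e.g. `c("H", "H")`.
#' @param n_samples Monte-Carlo sample count.
#' @param seed RNG seed, recorded in the result.
#' @return A `miss_estimate` (method `"rigid-MC"`) with per-molecule counts.
#' @examples
#' tip3p <- data.frame(
#'   type = c("O", "H", "H"),
#'   x = c(0, 0.0757, -0.0757), y = c(0, 0.0587, 0.0587), z = 0,
#'   mass = c(15.999, 1.008, 1.008))
#' gas <- gas_model(rho = 33, temperature = 310, sites = tip3p)
#' n_missed_rigid(cutoff_scheme(1.2, 1.24), schedule_config(0.002, 20),
#'                gas, c("H", "H"), n_samples = 5000, seed = 1)
#' @export
n_missed_rigid <- function(cutoffs, schedule, gas, pair_type,
                           n_samples = 30000L, seed = 1L) {
  stopifnot(inherits(gas, "gas_model"))
  if (is.null(gas$sites)) abort("n_missed_rigid needs a gas_model with sites")
  if (length(pair_type) != 2) abort("pair_type must name two site types")
  if (!all(pair_type %in% gas$sites$type)) abort("unknown site type in pair_type")
  rl <- cutoffs$r_l; rc <- cutoffs$r_c
  nst <- schedule$nstlist; dt <- schedule$dt
  if (nst <= 1L) return(miss_estimate(0, 0, 0, "rigid-MC", seed))
  kB <- gas$units$kB; Tk <- gas$temperature; M <- gas$mass
  offsets <- as.matrix(gas$sites[, c("x", "y", "z")])
  d_max <- max(sqrt(rowSums(offsets^2)))
  s_trans <- nst * dt * sqrt(kB * Tk * 2 / M)
  r_lo <- max(0, rl - 2 * d_max)
  r_hi <- rl + 2 * d_max + 8 * s_trans
  vshell <- 4 / 3 * pi * (r_hi^3 - r_lo^3)

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  n <- as.integer(n_samples)

  # molecule B centre of mass uniform in the shell; A at the origin
  u <- runif(n)
  r0 <- (u * (r_hi^3 - r_lo^3) + r_lo^3)^(1 / 3)
  dirm <- matrix(rnorm(3 * n), ncol = 3)
  dirm <- dirm / sqrt(rowSums(dirm^2))
  com_b0 <- dirm * r0

  sv <- sqrt(kB * Tk / M)
  vel_a <- matrix(rnorm(3 * n, sd = sv), ncol = 3)
  vel_b <- matrix(rnorm(3 * n, sd = sv), ncol = 3)

  Ra <- random_rotations(n)
  Rb <- random_rotations(n)
  omega_sd <- ifelse(gas$moments > 0, sqrt(kB * Tk / gas$moments), 0)
  draw_omega <- function() {
    cbind(rnorm(n, sd = omega_sd[1]), rnorm(n, sd = omega_sd[2]),
          rnorm(n, sd = omega_sd[3]))
  }
  om_a <- draw_omega(); om_b <- draw_omega()
  norm_axis <- function(om) {
    mag <- sqrt(rowSums(om^2))
    ax <- om / ifelse(mag > 0, mag, 1)
    ax[mag == 0, ] <- rep(c(1, 0, 0), each = sum(mag == 0))
    list(axis = ax, mag = mag)
  }
  oa <- norm_axis(om_a); ob <- norm_axis(om_b)

  # site indices participating in the requested type pair
  ia <- which(gas$sites$type == pair_type[1])
  ib <- which(gas$sites$type == pair_type[2])
  pair_idx <- unique(rbind(expand.grid(a = ia, b = ib),
                           expand.grid(a = which(gas$sites$type == pair_type[2]),
                                       b = which(gas$sites$type == pair_type[1]))))

  site_pos <- function(which_mol, s, t) {
    o <- offsets[s, ]
    if (which_mol == "a") {
      rotate_offset(o, oa$axis, oa$mag * t, Ra) + vel_a * t
    } else {
      rotate_offset(o, ob$axis, ob$mag * t, Rb) + com_b0 + vel_b * t
    }
  }

  np <- nrow(pair_idx)
  qualifies <- matrix(FALSE, n, np)
  for (p in seq_len(np)) {
    pa <- site_pos("a", pair_idx$a[p], 0)
    pb <- site_pos("b", pair_idx$b[p], 0)
    qualifies[, p] <- rowSums((pa - pb)^2) > rl^2
  }
  missed <- matrix(FALSE, n, np)
  events <- numeric(n)
  for (k in seq_len(nst - 1L)) {
    t <- k * dt
    pos_a <- lapply(seq_len(nrow(offsets)), function(s) site_pos("a", s, t))
    pos_b <- lapply(seq_len(nrow(offsets)), function(s) site_pos("b", s, t))
    for (p in seq_len(np)) {
      d2 <- rowSums((pos_a[[pair_idx$a[p]]] - pos_b[[pair_idx$b[p]]])^2)
      hit <- qualifies[, p] & (d2 < rc^2)
      missed[, p] <- missed[, p] | hit
      events <- events + hit
    }
  }
  count <- rowSums(missed)
  scale <- gas$rho * vshell
  miss_estimate(scale * mean(count), scale * mean(events),
                scale * sd(count) / sqrt(n), "rigid-MC", seed,
                extra = list(n_samples = n))
}
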