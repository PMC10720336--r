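# Shared fixtures and independent oracles for the test suite.

# O(N^2) minimum-image pair search written in plain R, independent of the
# compiled search paths.
r_brute_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  out <- list()
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    j <- which(rowSums(d^2) < cutoff^2) + i
    if (length(j)) out[[length(out) + 1L]] <- cbind(i, j)
  }
  m <- if (length(out)) do.call(rbind, out) else matrix(integer(), 0, 2)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# closed-form chi-squared upper-tail probabilities for df 1..3, built from
# the error function rather than pchisq
chisq_sf_closed <- function(x, df) {
  switch(as.character(df),
         "1" = 2 * pnorm(-sqrt(x)),
         "2" = exp(-x / 2),
         "3" = 2 * pnorm(-sqrt(x)) + sqrt(2 * x / pi) * exp(-x / 2),
         stop("df must be 1, 2 or 3"))
}

# truncated-and-shifted LJ energy, for hand checks
u_lj_shifted <- function(r, eps = 1, sigma = 1, rc = 2.5) {
  u <- function(rr) 4 * eps * ((sigma / rr)^12 - (sigma / rr)^6)
  ifelse(r < rc, u(r) - u(rc), 0)
}

# quick equilibrated dense LJ fluid used by several simulator tests
equilibrated_fluid <- function(n = 256, rho = 0.8, temp = 1.0, seed = 11,
                               n_equil = 2000, r_c = 2.5, r_l = 2.8) {
  st <- gen_lj_fluid(n, rho, temp, seed = seed)
  run_ljmd(st, lj_potential(r_c = r_c), cutoff_scheme(r_c, r_l),
           schedule_config(0.002, 10), n_equil,
           thermostat = "v-rescale", temperature = temp,
           units = reduced_units(), count_misses = FALSE)$final_state
}
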