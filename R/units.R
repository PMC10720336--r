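#' Unit systems
#'
#' The package works in GROMACS-style molecular-dynamics units throughout:
#' lengths in nm, times in ps, masses in amu (g/mol), energies in kJ/mol,
#' temperatures in K and pressures in bar.  Two constants tie these together:
#' the Boltzmann constant \eqn{k_B = 0.0083144621} kJ/(mol K), and the
#' conversion factor 16.6054 from (kJ/mol)/nm\eqn{^3} to bar, applied exactly
#' once in any pressure computation.
#'
#' `reduced_units()` gives the dimensionless Lennard-Jones convention
#' (\eqn{k_B = 1}, pressure factor 1) used for desk-scale simulator runs with
#' \eqn{\epsilon = \sigma = m = 1}.
#'
#' @return A list with elements `kB` and `pressure_factor` (and a `name` tag).
#' @examples
#' u <- md_units()
#' u$kB * 300  # ~2.494 kJ/mol: thermal energy at 300 K
#' @export
md_units <- function() {
  list(name = "md", kB = 0.0083144621, pressure_factor = 16.6054)
}

#' @rdname md_units
#' @export
reduced_units <- function() {
  list(name = "reduced", kB = 1.0, pressure_factor = 1.0)
}

check_units <- function(units) {
  if (!is.list(units) || !is.numeric(units$kB) || !is.numeric(units$pressure_factor) ||
      units$kB <= 0 || units$pressure_factor <= 0) {
    abort("`units` must be a list with positive `kB` and `pressure_factor` (see md_units())")
  }
  units
}
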