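#' MD schedule configuration
#'
#' Bundles the step intervals that govern when an MD engine rebuilds its
#' neighbor list (`nstlist`), samples and evaluates energies (`nstenergy`,
#' `nstcalcenergy`), and applies barostat/thermostat action (`nstpcouple`,
#' `nsttcouple`), together with the integration time step `dt` (ps).
#'
#' The derived predicate `commensurate` is `TRUE` iff both coupling intervals
#' are integer multiples of `nstlist`; incommensurate coupling means the
#' barostat and thermostat periodically act on pressures computed from a stale
#' pair list.
#'
#' @param dt Integration time step in ps (> 0).
#' @param nstlist Steps between neighbor-list rebuilds (integer >= 1).
#' @param nstenergy,nstcalcenergy,nstpcouple,nsttcouple Step intervals for
#'   energy output, energy/pressure evaluation, pressure coupling and
#'   temperature coupling (integers >= 1).
#' @param vbt_analog Tolerance on the energy-drift analog of missed
#'   interactions in kJ/mol/ps (see [drift_rate()]), or `NA` to disable.
#' @return An object of class `"schedule_config"` (a named list).
#' @seealso [check_schedule()], [cutoff_scheme()]
#' @export
schedule_config <- function(dt, nstlist, nstenergy = 1L, nstcalcenergy = 1L,
                            nstpcouple = nstlist, nsttcouple = nstlist,
                            vbt_analog = NA_real_) {
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0)
  iv <- c(nstlist = nstlist, nstenergy = nstenergy, nstcalcenergy = nstcalcenergy,
          nstpcouple = nstpcouple, nsttcouple = nsttcouple)
  if (any(iv < 1) || any(iv != as.integer(iv))) {
    abort("all schedule intervals must be integers >= 1")
  }
  out <- list(dt = as.numeric(dt), nstlist = as.integer(nstlist),
              nstenergy = as.integer(nstenergy),
              nstcalcenergy = as.integer(nstcalcenergy),
              nstpcouple = as.integer(nstpcouple),
              nsttcouple = as.integer(nsttcouple),
              vbt_analog = as.numeric(vbt_analog))
  out$commensurate <- (out$nstpcouple %% out$nstlist == 0L) &&
    (out$nsttcouple %% out$nstlist == 0L)
  structure(out, class = "schedule_config")
}

#' @export
print.schedule_config <- function(x, ...) {
  cat("<schedule_config> dt =", x$dt, "ps; nstlist =", x$nstlist,
      "; nstenergy =", x$nstenergy, "; nstcalcenergy =", x$nstcalcenergy,
      "\n  nstpcouple =", x$nstpcouple, "; nsttcouple =", x$nsttcouple,
      "; commensurate =", x$commensurate, "\n")
  invisible(x)
}

#' Cutoff scheme for Verlet pair lists
#'
#' Describes an interaction cutoff `r_c` and an outer list cutoff `r_l >= r_c`
#' (the shell between them is the Verlet buffer).  In dual-list mode an inner
#' list with cutoff `r_inner` (`r_c <= r_inner <= r_l`) is rebuilt from the
#' outer pool every `nstlist_inner` steps, with `nstlist_inner` dividing
#' `nstlist`.
#'
#' @param r_c Interaction cutoff (nm, > 0).
#' @param r_l Outer list cutoff (nm, >= `r_c`). Defaults to `r_c` (no buffer).
#' @param dual Use a dual (outer/inner) pair list?
#' @param r_inner Inner-list cutoff (nm), dual mode only.
#' @param nstlist_inner Inner rebuild interval (steps), dual mode only; must
#'   divide `nstlist` of the schedule it is used with.
#' @return An object of class `"cutoff_scheme"`.
#' @export
cutoff_scheme <- function(r_c, r_l = r_c, dual = FALSE, r_inner = NULL,
                          nstlist_inner = NULL) {
  stopifnot(is.numeric(r_c), r_c > 0, is.numeric(r_l))
  if (r_l < r_c) abort("r_l must be >= r_c")
  if (dual) {
    if (is.null(r_inner) || is.null(nstlist_inner)) {
      abort("dual mode requires r_inner and nstlist_inner")
    }
    if (r_inner < r_c || r_inner > r_l) abort("dual mode requires r_c <= r_inner <= r_l")
    if (nstlist_inner < 1 || nstlist_inner != as.integer(nstlist_inner)) {
      abort("nstlist_inner must be an integer >= 1")
    }
  }
  structure(list(r_c = as.numeric(r_c), r_l = as.numeric(r_l), dual = isTRUE(dual),
                 r_inner = if (dual) as.numeric(r_inner) else NA_real_,
                 nstlist_inner = if (dual) as.integer(nstlist_inner) else NA_integer_),
            class = "cutoff_scheme")
}

#' @export
print.cutoff_scheme <- function(x, ...) {
  cat("<cutoff_scheme> r_c =", x$r_c, "nm; r_l =", x$r_l, "nm; buffer =",
      x$r_l - x$r_c, "nm\n")
  if (x$dual) cat("  dual list: r_inner =", x$r_inner, "nm every",
                  x$nstlist_inner, "steps\n")
  invisible(x)
}

#' Check an MD schedule for neighbor-list hazards
#'
#' Flags schedule combinations known to produce or mask neighbor-list
#' artifacts: pressure or temperature coupling at intervals that are not
#' multiples of `nstlist` (the barostat/thermostat then periodically acts on
#' pressures computed from a stale pair list), and energy/pressure evaluation
#' at a multiple of `nstlist` (every evaluation then happens right after a
#' list rebuild, which can mask the deviations the other evaluations would
#' reveal).
#'
#' The check is pure: the warning set depends only on the divisibility
#' relations among the intervals.
#'
#' @param cfg A [schedule_config()].
#' @return A tibble with columns `code`, `severity` and `message`; zero rows
#'   when no hazards are found.
#' @examples
#' check_schedule(schedule_config(dt = 0.02, nstlist = 25, nstpcouple = 20,
#'                                nsttcouple = 20))
#' @export
check_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "schedule_config"))
  out <- list()
  if (cfg$nstpcouple %% cfg$nstlist != 0L) {
    out <- c(out, list(tibble(
      code = "pcouple_incommensurate", severity = "warning",
      message = sprintf(
        "nstpcouple = %d is not a multiple of nstlist = %d: the barostat periodically acts on pressures computed from a stale pair list",
        cfg$nstpcouple, cfg$nstlist))))
  }
  if (cfg$nsttcouple %% cfg$nstlist != 0L) {
    out <- c(out, list(tibble(
      code = "tcouple_incommensurate", severity = "warning",
      message = sprintf(
        "nsttcouple = %d is not a multiple of nstlist = %d: the thermostat periodically acts on kinetic energies out of sync with list rebuilds",
        cfg$nsttcouple, cfg$nstlist))))
  }
  if (cfg$nstlist > 1L && cfg$nstcalcenergy %% cfg$nstlist == 0L) {
    out <- c(out, list(tibble(
      code = "calcenergy_masks_misses", severity = "warning",
      message = sprintf(
        "nstcalcenergy = %d is a multiple of nstlist = %d: pressure/energy are only evaluated right after list rebuilds, which can mask missed-interaction deviations",
        cfg$nstcalcenergy, cfg$nstlist))))
  }
  if (length(out) == 0) {
    tibble(code = character(), severity = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Read a key-value run configuration file
#'
#' Parses a plain `key = value` text format mirroring GROMACS mdp parameter
#' names (`dt`, `nstlist`, `rlist`, `rvdw`, `rcoulomb`, `nstenergy`,
#' `nstcalcenergy`, `nstpcouple`, `nsttcouple`, `verlet-buffer-tolerance`,
#' ...), so values can be pasted from an mdp or log file.  Lines starting
#' with `;` or `#` are comments.  Full mdp/log parsing is out of scope.
#'
#' @param path Path to the configuration file.
#' @return A named list of parsed values (numbers where possible); the keys
#'   `rvdw`/`rcoulomb` are additionally folded into `r_c` (their maximum) and
#'   `rlist` into `r_l`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[;#].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) abort(sprintf("cannot parse line: '%s'", lines[which(bad)[1]]))
  keys <- tolower(trimws(vapply(kv, `[[`, "", 1L)))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  num <- suppressWarnings(as.numeric(vals))
  out <- stats::setNames(as.list(ifelse(is.na(num), vals, num)), keys)
  for (i in seq_along(out)) if (!is.na(num[i])) out[[i]] <- num[i]
  rc <- suppressWarnings(max(c(out$rvdw, out$rcoulomb), na.rm = TRUE))
  if (is.finite(rc)) out$r_c <- rc
  if (!is.null(out$rlist)) out$r_l <- out$rlist
  if (!is.null(out$`verlet-buffer-tolerance`)) out$vbt <- out$`verlet-buffer-tolerance`
  out
}
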