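#' Pressure time series
#'
#' A uniformly sampled per-step pressure series with its time step and
#' neighbor-list schedule metadata attached.  `values` may be a numeric
#' vector (scalar pressure) or a data frame of components (e.g. `P`,
#' `P_par`, `P_perp`, `Pxx`...).
#'
#' @param values Numeric vector or data frame of per-step pressures (bar).
#' @param dt Time step between samples (ps).
#' @param start_step Step index of the first sample.
#' @param nstlist Steps between neighbor-list rebuilds, if known.
#' @param provenance Free-text tag describing the origin of the data.
#' @return A tibble of class `"pressure_series"` with columns `step`, `time`
#'   and one column per component, plus attributes `dt`, `nstlist`,
#'   `provenance`.
#' @export
pressure_series <- function(values, dt, start_step = 0L, nstlist = NULL,
                            provenance = "unspecified") {
  if (is.numeric(values)) values <- tibble(P = as.numeric(values))
  values <- as_tibble(values)
  values <- values[, !(names(values) %in% c("step", "time")), drop = FALSE]
  if (nrow(values) < 2) abort("a pressure series needs at least 2 samples")
  stopifnot(dt > 0)
  step <- start_step + seq_len(nrow(values)) - 1L
  out <- dplyr::bind_cols(tibble(step = step, time = step * dt), values)
  structure(out, dt = dt, nstlist = if (is.null(nstlist)) NA_integer_ else
    as.integer(nstlist), provenance = provenance,
    class = c("pressure_series", class(out)))
}

series_values <- function(series) {
  if (is.numeric(series)) return(matrix(series, dimnames = list(NULL, "P")))
  df <- as.data.frame(series)
  df <- df[, setdiff(names(df), c("step", "time")), drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  as.matrix(df[, num, drop = FALSE])
}

series_dt <- function(series, dt) {
  if (!is.null(dt)) return(dt)
  a <- attr(series, "dt")
  if (is.null(a)) abort("supply `dt` (series carries no time step)")
  a
}

series_nstlist <- function(series, nstlist) {
  if (!is.null(nstlist)) return(as.integer(nstlist))
  a <- attr(series, "nstlist")
  if (is.null(a) || is.na(a)) abort("supply `nstlist` (series carries none)")
  as.integer(a)
}

#' Running averages under a sampling stride
#'
#' Subsamples a pressure series every `stride` steps (from its first sample)
#' and returns the cumulative mean — the curve an engine would print when
#' averaging quantities saved every `stride` steps.  When the series carries
#' a periodic per-phase pattern (period `nstlist`), stride-1 and
#' stride-`nstlist` running averages converge to different limits: the former
#' to the full-phase mean, the latter to the mean of the single sampled
#' phase.  That gap is itself a diagnostic of missed-interaction artifacts.
#'
#' @param series A [pressure_series()], numeric vector or data frame.
#' @param stride Sampling stride in steps (>= 1).
#' @param dt Time step (ps), if the series does not carry one.
#' @return Tibble with `step`, `time` and the cumulative mean of each
#'   component at the sampled steps.
#' @export
running_average <- function(series, stride = 1L, dt = NULL) {
  X <- series_values(series)
  if (stride < 1 || stride != as.integer(stride)) abort("stride must be an integer >= 1")
  if (stride > nrow(X)) abort("stride exceeds the series length")
  dt <- series_dt(series, dt)
  idx <- seq(1L, nrow(X), by = as.integer(stride))
  sub <- X[idx, , drop = FALSE]
  cm <- apply(sub, 2, function(v) cumsum(v) / seq_along(v))
  step0 <- if (is.data.frame(series) && "step" %in% names(series)) {
    series$step[idx]
  } else idx - 1L
  dplyr::bind_cols(tibble(step = step0, time = step0 * dt), as_tibble(cm))
}

# split the series into complete nstlist-long intervals aligned to the build
# schedule; returns a list of per-component interval matrices (n_int x nstlist)
interval_matrices <- function(series, nstlist, phase_offset) {
  X <- series_values(series)
  step <- if (is.data.frame(series) && "step" %in% names(series)) {
    series$step
  } else seq_len(nrow(X)) - 1L
  phase <- (step + phase_offset) %% nstlist
  iid <- (step + phase_offset) %/% nstlist
  keep_ids <- as.integer(names(which(table(iid) == nstlist)))
  keep <- iid %in% keep_ids
  if (!any(keep)) abort("series too short: need at least one complete nstlist interval")
  ord <- order(iid[keep], phase[keep])
  rows <- which(keep)[ord]
  n_int <- length(keep_ids)
  lapply(stats::setNames(seq_len(ncol(X)), colnames(X)), function(j) {
    matrix(X[rows, j], nrow = n_int, ncol = nstlist, byrow = TRUE)
  })
}

#' Phase averages aligned to neighbor-list updates
#'
#' Averages a per-step pressure series over blocks of `nstlist` time steps
#' starting immediately after a neighbor-list update: phase 0 is the first
#' force-evaluation step after a rebuild, phase `nstlist - 1` the last one
#' before the next rebuild.  With missed interactions, late phases deviate
#' systematically from phase 0.  Standard errors come from a block bootstrap
#' that resamples whole intervals (pressure is autocorrelated within an
#' interval, so pointwise errors would be too small).
#'
#' @param series A [pressure_series()], numeric vector or data frame.
#' @param nstlist Steps between rebuilds; taken from the series if attached.
#' @param phase_offset Added to step indices so that phase 0 coincides with
#'   the first step after a build (0 if the series starts at a build).
#' @param n_boot Bootstrap resamples for the standard errors.
#' @param seed Bootstrap RNG seed.
#' @return An object of class `"phase_average"`: list with tibbles
#'   `per_phase` (`component`, `phase`, `mean`, `se`), `overall`
#'   (per-component mean of the truncated series) and `delta_p`
#'   (`component`, `delta`, `se`), plus `nstlist` and `n_intervals`.
#' @export
phase_average <- function(series, nstlist = NULL, phase_offset = 0L,
                          n_boot = 1000L, seed = 1L) {
  nstlist <- series_nstlist(series, nstlist)
  if (nstlist < 1) abort("nstlist must be >= 1")
  mats <- interval_matrices(series, nstlist, as.integer(phase_offset))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  res <- purrr::imap(mats, function(M, comp) {
    n_int <- nrow(M)
    mu <- colMeans(M)
    if (n_int > 1) {
      boots <- matrix(0, n_boot, nstlist)
      for (b in seq_len(n_boot)) {
        boots[b, ] <- colMeans(M[sample.int(n_int, n_int, replace = TRUE), ,
                                 drop = FALSE])
      }
      se <- apply(boots, 2, sd)
      dse <- sd(boots[, nstlist] - boots[, 1])
    } else {
      se <- rep(NA_real_, nstlist)
      dse <- NA_real_
    }
    list(per_phase = tibble(component = comp, phase = 0:(nstlist - 1L),
                            mean = mu, se = se),
         overall = tibble(component = comp, mean = mean(M)),
         delta = tibble(component = comp, delta = mu[nstlist] - mu[1],
                        se = dse),
         n_intervals = nrow(M))
  })
  structure(list(per_phase = dplyr::bind_rows(purrr::map(res, "per_phase")),
                 overall = dplyr::bind_rows(purrr::map(res, "overall")),
                 delta_p = dplyr::bind_rows(purrr::map(res, "delta")),
                 nstlist = nstlist, n_intervals = res[[1]]$n_intervals,
                 n_boot = n_boot, seed = seed),
            class = "phase_average")
}

#' @export
print.phase_average <- function(x, ...) {
  cat("<phase_average> nstlist =", x$nstlist, "over", x$n_intervals,
      "complete intervals\n")
  dp <- x$delta_p
  for (i in seq_len(nrow(dp))) {
    cat(sprintf("  dP[%s] = %.5g +/- %.3g\n", dp$component[i], dp$delta[i],
                dp$se[i]))
  }
  invisible(x)
}

#' @export
tidy.phase_average <- function(x, ...) x$per_phase

#' @export
glance.phase_average <- function(x, ...) {
  tidyr::pivot_wider(x$delta_p, names_from = "component",
                     values_from = c("delta", "se")) %>%
    mutate(nstlist = x$nstlist, n_intervals = x$n_intervals)
}

#' Pressure difference across a neighbor-list rebuild
#'
#' \eqn{\Delta P} = (mean pressure at the last phase before a rebuild) minus
#' (mean pressure at the first phase after a rebuild), with a block-bootstrap
#' standard error, reported per component.  Positive \eqn{\Delta P} indicates
#' missed attractive interactions inflating the apparent pressure late in the
#' interval; negative values indicate missed repulsion.
#'
#' @inheritParams phase_average
#' @return Tibble with `component`, `delta`, `se`.
#' @export
delta_p <- function(series, nstlist = NULL, phase_offset = 0L,
                    n_boot = 1000L, seed = 1L) {
  phase_average(series, nstlist, phase_offset, n_boot, seed)$delta_p
}
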