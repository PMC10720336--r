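#' Welch power spectral density of a pressure series
#'
#' Standard Welch estimate: the series is cut into `segment_length`-sample
#' segments with fractional `overlap`, each segment is mean-detrended,
#' Hann-windowed and Fourier transformed, and the one-sided periodograms are
#' averaged.  The scaling is such that the integral of the PSD over frequency
#' recovers the series variance (Parseval, up to windowing tolerance).
#'
#' When `nstlist` is known the frequency axis is also expressed in units of
#' \eqn{1/(\mathrm{nstlist}\,\Delta t)}, the fundamental frequency of
#' neighbor-list updates, where missed-interaction artifacts appear as
#' harmonic spikes.
#'
#' @param series A [pressure_series()], numeric vector or data frame; for
#'   data frames the scalar pressure column `P` (or the first numeric
#'   column) is used.
#' @param dt Sample spacing in ps (taken from the series if attached).
#' @param segment_length Samples per Welch segment; default the largest
#'   power of two not exceeding `min(8192, length/8)` (at least 16).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param window Taper; only `"hann"` is implemented.
#' @param nstlist Steps between list rebuilds, for the scaled axis.
#' @return A tibble of class `"psd_result"` with columns `frequency` (1/ps),
#'   `power` (bar^2 ps) and, when `nstlist` is known, `frequency_nstlist`;
#'   attributes `segment_length`, `n_segments`, `window`, `dt`, `nstlist`.
#' @export
welch_psd <- function(series, dt = NULL, segment_length = NULL, overlap = 0.5,
                      window = "hann", nstlist = NULL) {
  window <- match.arg(window, "hann")
  X <- series_values(series)
  x <- if ("P" %in% colnames(X)) X[, "P"] else X[, 1]
  dt <- series_dt(series, dt)
  n <- length(x)
  if (is.null(nstlist)) {
    a <- attr(series, "nstlist")
    if (!is.null(a) && !is.na(a)) nstlist <- as.integer(a)
  }
  if (is.null(segment_length)) {
    segment_length <- 2^floor(log2(max(min(8192, n / 8), 16)))
  }
  segment_length <- as.integer(segment_length)
  if (segment_length > n) abort("segment_length exceeds the series length")
  if (overlap < 0 || overlap >= 1) abort("overlap must be in [0, 1)")
  hop <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  starts <- seq(1L, n - segment_length + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(segment_length) / segment_length))
  wnorm <- sum(w^2)
  nf <- segment_length %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment_length - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2
    p <- sp[seq_len(nf)] * dt / wnorm
    # one-sided: double everything except DC and (even-length) Nyquist
    dbl <- rep(2, nf); dbl[1] <- 1
    if (segment_length %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  psd <- acc / length(starts)
  freq <- (seq_len(nf) - 1L) / (segment_length * dt)
  out <- tibble(frequency = freq, power = psd)
  if (!is.null(nstlist)) out$frequency_nstlist <- freq * nstlist * dt
  structure(out, segment_length = segment_length, n_segments = length(starts),
            window = window, dt = dt,
            nstlist = if (is.null(nstlist)) NA_integer_ else as.integer(nstlist),
            class = c("psd_result", class(out)))
}

#' Flag harmonics of the neighbor-list update frequency in a PSD
#'
#' For each harmonic \eqn{k/(\mathrm{nstlist}\,\Delta t)} below the Nyquist
#' frequency, the PSD at the nearest frequency bin is compared against the
#' median PSD in a surrounding band from which a small exclusion window
#' around the harmonic (and the bins of every other harmonic falling in the
#' band) is removed.  A harmonic is flagged when this excess ratio exceeds
#' `threshold_ratio`.  The median-background ratio is scale-free, so the
#' same threshold works across systems with very different absolute pressure
#' fluctuations.
#'
#' @param psd A [welch_psd()] result.
#' @param nstlist Steps between list rebuilds (taken from the PSD if
#'   attached).
#' @param dt Time step in ps (taken from the PSD if attached).
#' @param threshold_ratio Flagging threshold on PSD / local median background.
#' @param band_bins Half-width (in bins) of the background band.
#' @param exclude_bins Half-width (in bins) of the exclusion window.
#' @return A tibble of class `"harmonic_flags"` with one row per harmonic:
#'   `k`, `frequency`, `power`, `background`, `excess`, `flagged`; attribute
#'   `verdict` is `TRUE` when any harmonic is flagged.  Zero rows (verdict
#'   `FALSE`) when no harmonic lies below Nyquist, e.g. for `nstlist = 1`.
#' @export
detect_nstlist_harmonics <- function(psd, nstlist = NULL, dt = NULL,
                                     threshold_ratio = 10, band_bins = 25L,
                                     exclude_bins = 2L) {
  stopifnot(inherits(psd, "psd_result") || is.data.frame(psd))
  if (is.null(dt)) dt <- attr(psd, "dt")
  if (is.null(nstlist) || is.na(nstlist)) nstlist <- attr(psd, "nstlist")
  if (is.null(dt) || is.null(nstlist) || is.na(nstlist)) {
    abort("supply nstlist and dt (not attached to the PSD)")
  }
  freq <- psd$frequency
  pow <- psd$power
  nyquist <- 1 / (2 * dt)
  f0 <- 1 / (nstlist * dt)
  ks <- seq_len(floor(nyquist / f0 - 1e-9))
  harm_bins <- vapply(ks, function(k) which.min(abs(freq - k * f0)), 1L)
  rows <- purrr::map(seq_along(ks), function(i) {
    b <- harm_bins[i]
    band <- max(2L, b - band_bins):min(length(freq), b + band_bins)
    excl <- unlist(lapply(harm_bins, function(hb) (hb - exclude_bins):(hb + exclude_bins)))
    band <- setdiff(band, excl)
    bg <- if (length(band) >= 3) median(pow[band]) else NA_real_
    tibble(k = ks[i], frequency = freq[b], power = pow[b], background = bg,
           excess = pow[b] / bg, flagged = !is.na(bg) && pow[b] / bg > threshold_ratio)
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(k = integer(), frequency = numeric(), power = numeric(),
           background = numeric(), excess = numeric(), flagged = logical())
  structure(out, verdict = any(out$flagged), threshold_ratio = threshold_ratio,
            class = c("harmonic_flags", class(out)))
}
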