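#' Box-dimension time series
#'
#' Per-step box edge lengths from one replicate of an NPT run.
#'
#' @param Lx,Ly,Lz Numeric vectors of box edges (nm), equal length.
#' @param dt Time between samples (ps).
#' @param replicate Replicate identifier.
#' @return A tibble of class `"box_series"` with columns `step`, `Lx`, `Ly`,
#'   `Lz`.
#' @export
box_series <- function(Lx, Ly, Lz, dt = NA_real_, replicate = NA_character_) {
  n <- length(Lx)
  if (length(Ly) != n || length(Lz) != n || n < 2) {
    abort("Lx, Ly, Lz must be equal-length vectors (length >= 2)")
  }
  if (any(c(Lx, Ly, Lz) <= 0)) abort("box lengths must be positive")
  structure(tibble(step = seq_len(n) - 1L, Lx = Lx, Ly = Ly, Lz = Lz),
            dt = dt, replicate = replicate,
            class = c("box_series", class(tibble())))
}

window_means <- function(x, frac) {
  n <- length(x)
  k <- max(1L, floor(frac * n))
  c(first = mean(x[seq_len(k)]), last = mean(x[(n - k + 1L):n]))
}

#' Classify a semi-isotropic box deformation event
#'
#' Compares the mean normal box edge \eqn{L_z} over the final `window`
#' fraction of the series against the mean over the initial fraction:
#' `"elongation"` if the box grew along z, `"contraction"` if it shrank.
#' Endpoint-window means are used rather than raw endpoints so single-step
#' noise cannot flip the call; an exact tie is an error prompting a longer
#' series.
#'
#' @param series A [box_series()] (or data frame with `Lx`, `Ly`, `Lz`).
#' @param window Fraction of the series in each endpoint window.
#' @return `"contraction"` or `"elongation"`.
#' @export
classify_semiiso <- function(series, window = 0.1) {
  w <- window_means(series$Lz, window)
  if (w["last"] == w["first"]) {
    abort("exact tie in Lz window means: run a longer series")
  }
  if (w["last"] > w["first"]) "elongation" else "contraction"
}

#' Classify the dominant expansion axis of an anisotropic run
#'
#' Returns the axis (`"x"`, `"y"` or `"z"`) with the largest relative change
#' (final-window mean over initial-window mean).  Classification is
#' invariant to a uniform rescaling of all box lengths.  Exact ties break
#' deterministically toward the smallest axis index, with a warning.
#'
#' @inheritParams classify_semiiso
#' @return `"x"`, `"y"` or `"z"`.
#' @export
classify_aniso <- function(series, window = 0.1) {
  ratios <- vapply(c(x = "Lx", y = "Ly", z = "Lz"), function(col) {
    w <- window_means(series[[col]], window)
    unname(w["last"] / w["first"])
  }, 1.0)
  top <- which(ratios == max(ratios))
  if (length(top) > 1) {
    warn(sprintf("tie between axes %s; choosing %s",
                 paste(names(ratios)[top], collapse = ", "),
                 names(ratios)[top[1]]))
  }
  c("x", "y", "z")[top[1]]
}

#' Pearson chi-squared goodness-of-fit test for event counts
#'
#' Tests observed category counts (e.g. how often replicate boxes elongated
#' along each axis) against expected probabilities.  Three conventions are
#' exposed because published tables are not always explicit about theirs:
#'
#' * `"standard"`: plain Pearson statistic \eqn{\sum (O-E)^2/E} on
#'   `k - 1` degrees of freedom (the library default);
#' * `"yates"`: continuity-corrected two-category test
#'   (\eqn{|O-E|} reduced by 0.5 before squaring), 1 degree of freedom;
#' * `"df_equals_k"`: plain statistic referred to `k` degrees of freedom,
#'   needed to reproduce some published multi-category p-values.
#'
#' @param counts Non-negative integer counts per category.
#' @param probs Expected probabilities (summing to 1); default uniform.
#' @param convention `"standard"`, `"yates"` or `"df_equals_k"`.
#' @return One-row tibble of class `"isotropy_test"`: `statistic`, `df`,
#'   `p_value`, `convention`, `n`; the counts and expectations are attached
#'   as attributes.
#' @examples
#' chisq_gof(c(2274, 2226), convention = "yates")        # p ~ 0.484
#' chisq_gof(c(1486, 1489, 1525), convention = "df_equals_k")  # p ~ 0.890
#' @export
chisq_gof <- function(counts, probs = rep(1 / length(counts), length(counts)),
                      convention = c("standard", "yates", "df_equals_k")) {
  convention <- match.arg(convention)
  k <- length(counts)
  if (k < 2) abort("need at least two categories")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (length(probs) != k || any(probs <= 0) || abs(sum(probs) - 1) > 1e-8) {
    abort("probs must be positive, match counts in length, and sum to 1")
  }
  n <- sum(counts)
  E <- n * probs
  if (convention == "yates") {
    if (k != 2) abort("the Yates continuity correction applies to k = 2 only")
    stat <- sum((abs(counts - E) - 0.5)^2 / E)
    df <- 1L
  } else {
    stat <- sum((counts - E)^2 / E)
    df <- if (convention == "standard") k - 1L else k
  }
  out <- tibble(statistic = stat, df = as.integer(df),
                p_value = pchisq(stat, df, lower.tail = FALSE),
                convention = convention, n = n)
  structure(out, counts = counts, expected = E,
            class = c("isotropy_test", class(out)))
}

#' @export
tidy.isotropy_test <- function(x, ...) as_tibble(unclass(x))

#' Tabulate deformation events across replicates and test isotropy
#'
#' Classifies each replicate box series ([classify_semiiso()] or
#' [classify_aniso()]), tabulates the events and runs [chisq_gof()] against
#' the isotropic null (1/2 : 1/2 for contraction/elongation in the
#' semi-isotropic case, 1/3 each for expansion along x, y, z in the
#' anisotropic case).
#'
#' @param series_list List of [box_series()] objects.
#' @param coupling `"semi-isotropic"` or `"anisotropic"`.
#' @param convention Passed to [chisq_gof()].
#' @param window Passed to the classifier.
#' @return List with `counts` (named integer vector) and `test`
#'   (an `"isotropy_test"`).
#' @export
isotropy_events <- function(series_list,
                            coupling = c("semi-isotropic", "anisotropic"),
                            convention = "standard", window = 0.1) {
  coupling <- match.arg(coupling)
  if (coupling == "semi-isotropic") {
    cls <- vapply(series_list, classify_semiiso, "", window = window)
    lev <- c("contraction", "elongation")
  } else {
    cls <- vapply(series_list, classify_aniso, "", window = window)
    lev <- c("x", "y", "z")
  }
  counts <- table(factor(cls, levels = lev))
  list(counts = stats::setNames(as.integer(counts), lev),
       test = chisq_gof(as.integer(counts), convention = convention))
}
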