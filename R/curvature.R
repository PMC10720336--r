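#' Periodic membrane height field
#'
#' A membrane surface in the Monge gauge: heights \eqn{h(x, y)} on a regular
#' grid spanning a periodic orthorhombic box, membrane normal along z.
#'
#' @param h Numeric `n_x` x `n_y` matrix of heights (nm), periodic in both
#'   directions.
#' @param dx,dy Grid spacing (nm).
#' @param mask Optional logical matrix marking bins that were empty in the
#'   source data and filled by interpolation.
#' @return An object of class `"height_field"`.
#' @export
height_field <- function(h, dx, dy = dx, mask = NULL) {
  h <- as.matrix(h)
  if (nrow(h) < 4 || ncol(h) < 4) abort("height grid must be at least 4 x 4")
  if (!all(is.finite(h))) abort("heights must be finite")
  if (dx <= 0 || dy <= 0) abort("grid spacing must be positive")
  if (!is.null(mask) && !all(dim(mask) == dim(h))) abort("mask must match h")
  structure(list(h = h, dx = dx, dy = dy, mask = mask),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat("<height_field>", nrow(x$h), "x", ncol(x$h), "grid; spacing",
      signif(x$dx, 4), "x", signif(x$dy, 4), "nm; height range [",
      signif(min(x$h), 4), ",", signif(max(x$h), 4), "] nm\n")
  invisible(x)
}

shift_mat <- function(m, di, dj) {
  n <- nrow(m); k <- ncol(m)
  m[((seq_len(n) - 1 + di) %% n) + 1, ((seq_len(k) - 1 + dj) %% k) + 1,
    drop = FALSE]
}

#' Local mean curvature of a height field
#'
#' Monge-gauge mean curvature
#' \deqn{H = \frac{(1 + h_y^2) h_{xx} - 2 h_x h_y h_{xy} + (1 + h_x^2) h_{yy}}
#'            {2 (1 + h_x^2 + h_y^2)^{3/2}}}
#' with all derivatives taken by second-order periodic central finite
#' differences.  \eqn{H} is the mean of the two principal curvatures; in the
#' small-slope limit \eqn{H \to \nabla^2 h / 2}.
#'
#' @param field A [height_field()].
#' @return Matrix of \eqn{H} values (nm^-1), same shape as the grid.
#' @export
mean_curvature <- function(field) {
  stopifnot(inherits(field, "height_field"))
  h <- field$h; dx <- field$dx; dy <- field$dy
  hxp <- shift_mat(h, 1, 0); hxm <- shift_mat(h, -1, 0)
  hyp <- shift_mat(h, 0, 1); hym <- shift_mat(h, 0, -1)
  hx <- (hxp - hxm) / (2 * dx)
  hy <- (hyp - hym) / (2 * dy)
  hxx <- (hxp - 2 * h + hxm) / dx^2
  hyy <- (hyp - 2 * h + hym) / dy^2
  hxy <- (shift_mat(h, 1, 1) - shift_mat(h, 1, -1) -
            shift_mat(h, -1, 1) + shift_mat(h, -1, -1)) / (4 * dx * dy)
  ((1 + hy^2) * hxx - 2 * hx * hy * hxy + (1 + hx^2) * hyy) /
    (2 * (1 + hx^2 + hy^2)^1.5)
}

#' Helfrich bending energy of a height field
#'
#' \deqn{E = 2 \kappa \int_A H^2 \, dA}
#' with \eqn{H} the local mean curvature (mean of the principal curvatures)
#' and \eqn{\kappa} the bending rigidity; spontaneous curvature is zero and
#' the Gaussian term, invariant for fixed topology, is omitted.  The
#' integral runs over the flat xy plane of the box (curvature corrections to
#' the area element are ignored).  This \eqn{2\kappa \int H^2} prefactor
#' equals the \eqn{(\kappa/2)\int (2H)^2} convention; set
#' `prefactor = 0.5` for the \eqn{(\kappa/2)\int H^2} convention instead.
#'
#' @param field A [height_field()].
#' @param kappa Bending rigidity, in kJ/mol or units of \eqn{k_B T}
#'   (see `kappa_units`); a typical lipid-bilayer value is 25 \eqn{k_B T}.
#' @param kappa_units `"kJ/mol"` or `"kBT"`.
#' @param temperature Temperature (K) for the \eqn{k_B T} conversion.
#' @param prefactor Multiple of \eqn{\kappa \int H^2 dA} (default 2).
#' @param units Unit system, see [md_units()].
#' @return An object of class `"bending_result"`: list with the `H` grid
#'   (nm^-1), `integral_H2` (\eqn{\int H^2 dA}, dimensionless), `E_kJ_mol`,
#'   `E_kBT`, and the `kappa` used (kJ/mol).
#' @export
bending_energy <- function(field, kappa = 25, kappa_units = c("kBT", "kJ/mol"),
                           temperature = 310, prefactor = 2,
                           units = md_units()) {
  kappa_units <- match.arg(kappa_units)
  check_units(units)
  stopifnot(kappa > 0, temperature > 0)
  kT <- units$kB * temperature
  kappa_kj <- if (kappa_units == "kBT") kappa * kT else kappa
  H <- mean_curvature(field)
  int_h2 <- sum(H^2) * field$dx * field$dy
  E <- prefactor * kappa_kj * int_h2
  structure(list(H = H, integral_H2 = int_h2, E_kJ_mol = E, E_kBT = E / kT,
                 kappa_kJ_mol = kappa_kj, temperature = temperature,
                 prefactor = prefactor),
            class = "bending_result")
}

#' @export
print.bending_result <- function(x, ...) {
  cat("<bending_result> E_bend =", signif(x$E_kJ_mol, 5), "kJ/mol =",
      signif(x$E_kBT, 5), "kBT (kappa =", signif(x$kappa_kJ_mol, 4),
      "kJ/mol)\n")
  invisible(x)
}

#' @export
tidy.bending_result <- function(x, ...) {
  tibble(E_kJ_mol = x$E_kJ_mol, E_kBT = x$E_kBT,
         integral_H2 = x$integral_H2, kappa_kJ_mol = x$kappa_kJ_mol,
         temperature = x$temperature)
}

#' Build a height field from head-group coordinates
#'
#' Bins point coordinates (e.g. lipid phosphate positions) on a regular
#' `grid` over the periodic xy plane and takes the per-bin mean z as the
#' local membrane height.  With `leaflet = "midplane-split"` points are
#' first assigned to leaflets by the sign of \eqn{z - \mathrm{median}(z)}
#' and the midsurface (mean of the two leaflet fields) is returned;
#' `"upper"`/`"lower"` keep a single leaflet.  Empty bins are filled by
#' iterative averaging of their four periodic neighbours (to 1e-6 nm); the
#' returned mask records which bins were filled.  More than 50% empty bins
#' is an error — the grid is too fine for the point density.
#'
#' @param points M x 3 matrix or data frame of coordinates (nm).
#' @param box Length-2 (or 3) box edges (nm); x and y extents are used.
#' @param grid Integer vector `c(n_x, n_y)`.
#' @param leaflet `"midplane-split"`, `"upper"`, `"lower"`, or `"all"` for a
#'   single sheet whose points all belong to one surface.
#' @return A [height_field()] with the fill mask set.
#' @export
heights_from_points <- function(points, box, grid,
                                leaflet = c("midplane-split", "upper", "lower",
                                            "all")) {
  leaflet <- match.arg(leaflet)
  points <- as.matrix(as.data.frame(points)[, 1:3])
  if (length(grid) == 1) grid <- c(grid, grid)
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  Lx <- box[1]; Ly <- box[2]
  bin_field <- function(p) {
    ix <- pmin(pmax(floor(p[, 1] %% Lx / Lx * nx), 0), nx - 1) + 1L
    iy <- pmin(pmax(floor(p[, 2] %% Ly / Ly * ny), 0), ny - 1) + 1L
    sums <- matrix(0, nx, ny); cnt <- matrix(0L, nx, ny)
    for (m in seq_len(nrow(p))) {
      sums[ix[m], iy[m]] <- sums[ix[m], iy[m]] + p[m, 3]
      cnt[ix[m], iy[m]] <- cnt[ix[m], iy[m]] + 1L
    }
    empty <- cnt == 0L
    if (mean(empty) > 0.5) {
      abort("more than 50% of bins are empty: use a coarser grid")
    }
    h <- sums / ifelse(empty, 1, cnt)
    h[empty] <- mean(h[!empty])
    # iterative periodic neighbour averaging on the filled bins
    repeat {
      avg <- (shift_mat(h, 1, 0) + shift_mat(h, -1, 0) +
                shift_mat(h, 0, 1) + shift_mat(h, 0, -1)) / 4
      delta <- max(abs(avg[empty] - h[empty]), 0)
      h[empty] <- avg[empty]
      if (delta < 1e-6) break
    }
    list(h = h, mask = empty)
  }
  if (leaflet == "midplane-split") {
    mid <- median(points[, 3])
    up <- bin_field(points[points[, 3] >= mid, , drop = FALSE])
    lo <- bin_field(points[points[, 3] < mid, , drop = FALSE])
    height_field((up$h + lo$h) / 2, dx = Lx / nx, dy = Ly / ny,
                 mask = up$mask | lo$mask)
  } else if (leaflet == "all") {
    f <- bin_field(points)
    height_field(f$h, dx = Lx / nx, dy = Ly / ny, mask = f$mask)
  } else {
    mid <- median(points[, 3])
    sel <- if (leaflet == "upper") points[, 3] >= mid else points[, 3] < mid
    f <- bin_field(points[sel, , drop = FALSE])
    height_field(f$h, dx = Lx / nx, dy = Ly / ny, mask = f$mask)
  }
}

#' Read particle coordinates from a GRO file
#'
#' Minimal reader for the fixed-column GROMACS coordinate format: a title
#' line, an atom count, fixed-width atom records with positions in nm, and
#' a final box line.
#'
#' @param path Path to the .gro file.
#' @return Tibble with columns `resname`, `atomname`, `x`, `y`, `z`;
#'   attribute `box` holds the box vector.
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) abort("not a valid gro file (too short)")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || length(lines) < n + 3) abort("corrupt gro file: bad atom count")
  at <- lines[3:(n + 2)]
  num <- function(s) suppressWarnings(as.numeric(s))
  out <- tibble(
    resname = trimws(substr(at, 6, 10)),
    atomname = trimws(substr(at, 11, 15)),
    x = num(substr(at, 21, 28)), y = num(substr(at, 29, 36)),
    z = num(substr(at, 37, 44)))
  if (anyNA(out$x) || anyNA(out$y) || anyNA(out$z)) {
    abort("corrupt gro file: non-numeric coordinates")
  }
  box <- num(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])
  attr(out, "box") <- box[1:3]
  out
}
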