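test_that("flat membranes have zero curvature and zero bending energy", {
  f <- height_field(matrix(4.2, 32, 32), dx = 0.5)
  expect_true(all(mean_curvature(f) == 0))
  expect_equal(bending_energy(f)$E_kJ_mol, 0)
})

test_that("small-slope sinusoid curvature matches the closed form to <1%", {
  L <- 50; a <- 0.25; n <- 64  # a/L = 0.005
  g <- gen_height_field("sinusoid", n = n, L = L, amplitude = a, q = 1)
  H <- mean_curvature(g$field)
  xs <- (seq_len(n) - 1) / n * L
  # small-slope limit: H = h_xx / 2 = -(a/2) k^2 sin(kx)
  H_small <- matrix(rep(-(a / 2) * (2 * pi / L)^2 * sin(2 * pi * xs / L), n), n, n)
  expect_lt(max(abs(H - H_small)) / max(abs(H_small)), 0.01)
})

test_that("finite-difference curvature converges at second order", {
  L <- 50; a <- 1.5; k <- 2 * pi / L  # large enough amplitude to see FD error
  exact_H <- function(n) {
    xs <- (seq_len(n) - 1) / n * L
    matrix(rep(-a * k^2 * sin(k * xs) / (2 * (1 + a^2 * k^2 * cos(k * xs)^2)^1.5),
               n), n, n)
  }
  err <- vapply(c(16, 32, 64), function(n) {
    g <- gen_height_field("sinusoid", n = n, L = L, amplitude = a, q = 1)
    max(abs(mean_curvature(g$field) - exact_H(n)))
  }, 1.0)
  expect_gt(err[1] / err[2], 3.3)
  expect_gt(err[2] / err[3], 3.3)
})

test_that("sinusoid bending energy matches (kappa/2) a^2 k^4 A/2 within 1% at n = 128", {
  u <- md_units(); kT <- u$kB * 310
  g <- gen_height_field("sinusoid", n = 128, L = 50, amplitude = 0.25, q = 1)
  be <- bending_energy(g$field, kappa = 25, kappa_units = "kBT",
                       temperature = 310)
  expect_lt(abs(be$E_kJ_mol - g$E_analytic(25 * kT)) / g$E_analytic(25 * kT),
            0.01)
  expect_equal(be$E_kBT, be$E_kJ_mol / kT, tolerance = 1e-12)
})

test_that("orthogonal small-amplitude modes superpose linearly within 1%", {
  u <- md_units(); kT <- u$kB * 310
  gs <- gen_height_field("superposition", n = 128, L = 50,
                         amplitude = c(0.25, 0.2), q = c(1, 2))
  bs <- bending_energy(gs$field, 25, "kBT", 310)
  expect_lt(abs(bs$E_kJ_mol - gs$E_analytic(25 * kT)) / gs$E_analytic(25 * kT),
            0.01)
})

test_that("bending energy invariances: offset, transpose, positivity", {
  g <- gen_height_field("superposition", n = 64, L = 40,
                        amplitude = c(0.3, 0.15), q = c(2, 3))
  E0 <- bending_energy(g$field)$E_kJ_mol
  expect_gte(E0, 0)
  shifted <- height_field(g$field$h + 7.7, dx = g$field$dx)
  expect_equal(bending_energy(shifted)$E_kJ_mol, E0, tolerance = 1e-10)
  transposed <- height_field(t(g$field$h), dx = g$field$dy, dy = g$field$dx)
  expect_equal(bending_energy(transposed)$E_kJ_mol, E0, tolerance = 1e-10)
})

test_that("height fields are recovered from binned point clouds", {
  # exact plane
  set.seed(9)
  pts <- cbind(runif(4000, 0, 20), runif(4000, 0, 20), 3.3)
  f <- heights_from_points(pts, box = c(20, 20), grid = 16, leaflet = "all")
  expect_equal(f$h, matrix(3.3, 16, 16), tolerance = 1e-12)

  # sinusoidal sheet sampled densely: RMS error below a/100
  a <- 1.0; L <- 40
  m <- 40000
  xy <- cbind(runif(m, 0, L), runif(m, 0, L))
  pts2 <- cbind(xy, a * sin(2 * pi * xy[, 1] / L))
  f2 <- heights_from_points(pts2, box = c(L, L), grid = 24, leaflet = "all")
  xs <- (seq_len(24) - 0.5) / 24 * L  # bin centres
  ref <- matrix(rep(a * sin(2 * pi * xs / L), 24), 24, 24)
  expect_lt(sqrt(mean((f2$h - ref)^2)), a / 100 * 2.5)
})

test_that("empty bins fill from periodic neighbours; overly fine grids error", {
  # a 6x6 grid with one empty bin surrounded by height c
  set.seed(2)
  L <- 12
  centres <- expand.grid(x = (0:5 + 0.5) * 2, y = (0:5 + 0.5) * 2)
  centres <- centres[!(centres$x == 1 & centres$y == 1), ]
  pts <- cbind(centres$x, centres$y, 5.5)
  f <- heights_from_points(pts, box = c(L, L), grid = 6, leaflet = "all")
  expect_equal(f$h[1, 1], 5.5, tolerance = 1e-6)
  expect_true(f$mask[1, 1])
  expect_equal(sum(f$mask), 1L)

  sparse <- cbind(runif(20, 0, L), runif(20, 0, L), 1)
  expect_error(heights_from_points(sparse, box = c(L, L), grid = 32,
                                   leaflet = "all"), "coarser grid")
})

test_that("midplane-split builds the midsurface of two leaflets", {
  set.seed(5)
  m <- 20000
  xy <- cbind(runif(m, 0, 30), runif(m, 0, 30))
  upper <- cbind(xy, 6 + 0.5 * sin(2 * pi * xy[, 1] / 30))
  lower <- cbind(xy, 2 + 0.5 * sin(2 * pi * xy[, 1] / 30))
  f <- heights_from_points(rbind(upper, lower), box = c(30, 30), grid = 16)
  xs <- (seq_len(16) - 0.5) / 16 * 30
  ref <- matrix(rep(4 + 0.5 * sin(2 * pi * xs / 30), 16), 16, 16)
  expect_lt(max(abs(f$h - ref)), 0.05)
})

test_that("gro files are parsed with fixed-column positions and a box line", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "membrane head groups",
    "    3",
    "    1POPC   PO4    1   1.234   2.345   3.456",
    "    2POPC   PO4    2   4.000   5.125   6.250",
    "    3W      W      3   0.100   0.200   0.300",
    "  10.00000  10.00000   8.00000"), path)
  g <- read_gro(path)
  expect_equal(nrow(g), 3L)
  expect_equal(g$x, c(1.234, 4.0, 0.1))
  expect_equal(g$atomname, c("PO4", "PO4", "W"))
  expect_equal(attr(g, "box"), c(10, 10, 8))
})
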