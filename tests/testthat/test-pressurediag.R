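test_that("running averages: constant series and phase-pattern aliasing", {
  const <- pressure_series(rep(3.5, 200), dt = 0.02)
  ra <- running_average(const, stride = 1)
  expect_true(all(ra$P == 3.5))
  ra7 <- running_average(const, stride = 7)
  expect_true(all(ra7$P == 3.5))

  # sawtooth with period 10: stride 10 samples a single phase
  pat <- seq(-4.5, 4.5, by = 1)
  ser <- gen_pressure_series(1000, dt = 0.02, noise_sd = 0, phase_pattern = pat)
  s1 <- running_average(ser, stride = 1)
  s10 <- running_average(ser, stride = 10)
  expect_equal(tail(s1$P, 1), mean(pat), tolerance = 1e-12)
  expect_equal(tail(s10$P, 1), pat[1], tolerance = 1e-12)
  # limits differ by the phase-pattern mean difference
  expect_equal(tail(s1$P, 1) - tail(s10$P, 1), mean(pat) - pat[1],
               tolerance = 1e-12)
  expect_error(running_average(ser, stride = 5000), "length")
  expect_error(running_average(ser, stride = 0), "integer")
})

test_that("white-noise phase averages are flat (no spurious per-phase structure)", {
  nst <- 10L
  ser <- gen_pressure_series(nst * 10000, dt = 0.02, noise_sd = 1,
                             phase_pattern = numeric(nst), seed = 77)
  pa <- phase_average(ser, n_boot = 500, seed = 2)
  pp <- pa$per_phase
  z <- (pp$mean - mean(pp$mean)) / pp$se
  expect_lt(max(abs(z)), 4)
  expect_equal(nrow(pp), nst)
})

test_that("an injected phase pattern is recovered within bootstrap error", {
  nst <- 25L
  pat <- 0.4 * sin(2 * pi * (0:24) / 25) + seq(0, 0.5, length.out = 25)
  ser <- gen_pressure_series(nst * 2000, dt = 0.02, noise_sd = 1,
                             phase_pattern = pat, baseline = 2, seed = 5)
  pa <- phase_average(ser, n_boot = 500, seed = 3)
  pp <- pa$per_phase
  expect_true(all(abs(pp$mean - (2 + pat)) < 3.5 * pp$se))
  # overall mean equals the plain mean of the whole-interval truncation
  expect_equal(pa$overall$mean, mean(ser$P), tolerance = 1e-12)
})

test_that("delta_p recovers a known endpoint difference and is 0 for constants", {
  const <- pressure_series(rep(1.0, 100), dt = 0.02, nstlist = 10)
  dp0 <- delta_p(const, n_boot = 200, seed = 1)
  expect_equal(dp0$delta, 0)
  pat <- c(0, rep(0.1, 23), 0.8)   # endpoint difference 0.8
  ser <- gen_pressure_series(25 * 1500, dt = 0.02, noise_sd = 0.8,
                             phase_pattern = pat, seed = 8)
  dp <- delta_p(ser, n_boot = 500, seed = 4)
  expect_lt(abs(dp$delta - 0.8), 3 * dp$se)
})

test_that("phase averaging honours the phase offset for series not starting at a build", {
  pat <- seq(0, 2.4, length.out = 25)
  full <- gen_pressure_series(25 * 400, dt = 0.02, noise_sd = 0,
                              phase_pattern = pat)
  shifted <- pressure_series(full$P[-(1:7)], dt = 0.02, nstlist = 25)
  pa <- phase_average(shifted, phase_offset = 7, n_boot = 50, seed = 1)
  expect_equal(pa$per_phase$mean, pat, tolerance = 1e-12)
})

test_that("multi-component series get per-component phase statistics", {
  nst <- 10L
  base <- gen_pressure_series(nst * 500, dt = 0.02, noise_sd = 0,
                              phase_pattern = seq(0, 0.9, by = 0.1))
  df <- tibble::tibble(P_par = base$P, P_perp = -2 * base$P)
  ser <- pressure_series(df, dt = 0.02, nstlist = nst)
  dp <- delta_p(ser, n_boot = 50, seed = 1)
  expect_setequal(dp$component, c("P_par", "P_perp"))
  expect_equal(dp$delta[dp$component == "P_perp"],
               -2 * dp$delta[dp$component == "P_par"], tolerance = 1e-12)
})

test_that("xvg files round-trip and carry legend metadata", {
  path <- withr::local_tempfile(fileext = ".xvg")
  df <- data.frame(time = seq(0, 0.08, by = 0.02),
                   P = c(1.5, -2.25, 3.125, 0.001, 12345.678),
                   Pxx = exp(seq(-2, 2)))
  write_xvg(df, path, title = "test pressures", ylabel = "P (bar)")
  back <- read_xvg(path)
  expect_equal(back$time, df$time, tolerance = 1e-12)
  expect_equal(back$P, df$P, tolerance = 1e-12)
  expect_equal(back$Pxx, df$Pxx, tolerance = 1e-12)
  expect_equal(attr(back, "title"), "test pressures")
})

test_that("xvg reader maps legends, rejects junk, and reports the bad line", {
  path <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# comment", "@    title \"x\"", "@ s0 legend \"Pres-XX\"",
               "0.0 1.0", "0.2 2.0", "0.4 3.0"), path)
  df <- read_xvg(path)
  expect_named(df, c("time", "Pxx"))
  expect_equal(nrow(df), 3L)

  only_comments <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# a", "@ title \"b\""), only_comments)
  expect_error(read_xvg(only_comments), "no data rows")

  bad <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("0.0 1.0", "0.2 oops"), bad)
  expect_error(read_xvg(bad), "line 2")
})
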