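test_that("semi-isotropic deformation events classify by the normal axis trend", {
  n <- 200
  grow <- box_series(rep(6, n), rep(6, n), seq(6, 6.6, length.out = n))
  shrink <- box_series(rep(6, n), rep(6, n), seq(6, 5.4, length.out = n))
  flat <- box_series(rep(6, n), rep(6, n), rep(6, n))
  expect_equal(classify_semiiso(grow), "elongation")
  expect_equal(classify_semiiso(shrink), "contraction")
  expect_error(classify_semiiso(flat), "tie")
})

test_that("anisotropic events pick the axis with the largest relative growth", {
  n <- 200
  s <- box_series(rep(6, n), rep(6, n), seq(6, 6.3, length.out = n))
  expect_equal(classify_aniso(s), "z")
  s2 <- box_series(seq(6, 6.12, length.out = n), seq(6, 6.06, length.out = n),
                   rep(6, n))
  expect_equal(classify_aniso(s2), "x")
  tie <- box_series(seq(6, 6.1, length.out = n), seq(3, 3.05, length.out = n),
                    seq(9, 9.15, length.out = n))
  expect_warning(ax <- classify_aniso(tie), "tie")
  expect_equal(ax, "x")
})

test_that("classification is invariant under uniform rescaling of the box", {
  n <- 150
  s <- box_series(seq(6, 6.05, length.out = n), rep(6, n),
                  seq(6, 6.2, length.out = n))
  scaled <- box_series(2.7 * s$Lx, 2.7 * s$Ly, 2.7 * s$Lz)
  expect_equal(classify_aniso(s), classify_aniso(scaled))
  expect_equal(classify_semiiso(s), classify_semiiso(scaled))
})

test_that("published isotropy p-values are reproduced under the stated conventions", {
  # two-category replicate counts, continuity-corrected
  expect_lt(abs(chisq_gof(c(2274, 2226), convention = "yates")$p_value - 0.484),
            5e-4)
  # three-category counts referred to df = k
  expect_lt(abs(chisq_gof(c(1486, 1489, 1525),
                      convention = "df_equals_k")$p_value - 0.890), 5e-4)
  expect_lt(abs(chisq_gof(c(1496, 1531, 1473),
                      convention = "df_equals_k")$p_value - 0.768), 5e-4)
  expect_lt(abs(chisq_gof(c(1387, 1536, 1577),
                      convention = "df_equals_k")$p_value - 0.004), 5e-4)
  # heavily biased semi-isotropic counts are significant however tested
  for (conv in c("standard", "yates", "df_equals_k")) {
    expect_lt(chisq_gof(c(1992, 2508), convention = conv)$p_value, 1e-3)
  }
})

test_that("chi-squared machinery: nulls, guards, and monotone sensitivity", {
  even <- chisq_gof(c(100, 100, 100))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  expect_error(chisq_gof(c(10, 20, 30), convention = "yates"), "k = 2")
  expect_error(chisq_gof(c(10.5, 20)), "integers")
  expect_error(chisq_gof(c(10, 20), probs = c(0.6, 0.6)), "sum to 1")
  # p decreases as a single count deviates further (fixed total)
  ps <- vapply(c(0, 10, 20, 40), function(d) {
    chisq_gof(c(500 + d, 500 - d))$p_value
  }, 1.0)
  expect_true(all(diff(ps) < 0))
})

test_that("standard convention matches closed-form survival functions for df 1-3", {
  for (counts in list(c(520, 480), c(360, 310, 330), c(240, 260, 250, 250))) {
    res <- chisq_gof(counts)
    expect_equal(res$p_value, chisq_sf_closed(res$statistic, res$df),
                 tolerance = 1e-10)
  }
})

test_that("replicate series are tabulated and tested end to end", {
  set.seed(4)
  n <- 60
  mk <- function(axis, mag = 0.1) {
    L <- matrix(6, n, 3) + matrix(rnorm(3 * n, sd = 1e-4), n, 3)
    L[, axis] <- L[, axis] + seq(0, mag, length.out = n)
    box_series(L[, 1], L[, 2], L[, 3])
  }
  sers <- c(lapply(1:6, function(i) mk(3)), lapply(1:2, function(i) mk(1)),
            lapply(1:2, function(i) mk(2)))
  res <- isotropy_events(sers, coupling = "anisotropic")
  expect_equal(unname(res$counts), c(2L, 2L, 6L))
  expect_s3_class(res$test, "isotropy_test")
  expect_true(res$test$p_value >= 0 && res$test$p_value <= 1)
})
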