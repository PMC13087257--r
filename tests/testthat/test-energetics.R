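kB <- 0.0019872041

test_that("exponential average obeys its closed forms and Jensen", {
  s <- energy_series(rep(-12.5, 10), temperature = 300)
  expect_equal(exp_avg_free_energy(s), -12.5)
  # alternating two-level series against the analytic expression
  a <- -3; b <- 5; Temp <- 310; kT <- kB * Temp
  s2 <- energy_series(rep(c(a, b), 50), temperature = Temp)
  closed <- -kT * log((exp(-a / kT) + exp(-b / kT)) / 2)
  expect_lt(abs(exp_avg_free_energy(s2) - closed), 1e-10)
  set.seed(1)
  s3 <- energy_series(rnorm(500, -20, 5), temperature = 292)
  expect_lte(exp_avg_free_energy(s3), mean(s3$values))
  # gauge invariance: shifting U shifts Delta G by the same constant
  s4 <- energy_series(s3$values + 1000, temperature = 292)
  expect_lt(abs((exp_avg_free_energy(s4) - 1000) - exp_avg_free_energy(s3)),
            1e-10)
  # overflow-proof for very large magnitudes
  s5 <- energy_series(c(-5e4, -5e4 + 1), temperature = 300)
  expect_true(is.finite(exp_avg_free_energy(s5)))
})

test_that("high-temperature limit approaches the arithmetic mean", {
  set.seed(2)
  u <- rnorm(2000, -10, 1)
  Thot <- 100 * 1 / kB  # kT = 100 x SD(U)
  s <- energy_series(u, temperature = Thot)
  expect_lt(abs(exp_avg_free_energy(s) - mean(u)) / abs(mean(u)), 0.01)
})

test_that("block averaging windows, weights and errs as specified", {
  s <- energy_series(rep(-7, 100), temperature = 300)
  est <- block_free_energy(s)
  expect_equal(est$delta_g, -7)
  expect_equal(est$error, 0)
  expect_identical(est$n_blocks, 5)
  # the first half is ignored when use_last_half is on
  v <- c(rep(-7 + 100, 50), rep(-7, 50))
  est2 <- block_free_energy(energy_series(v, temperature = 300))
  expect_equal(est2$delta_g, -7)
  # white noise: block estimate close to the full-series exponential average
  set.seed(3)
  u <- rnorm(1e5, -30, 2)
  s3 <- energy_series(u, temperature = 292)
  est3 <- block_free_energy(s3, n_blocks = 5, use_last_half = FALSE)
  full <- exp_avg_free_energy(s3)
  se <- est3$error / sqrt(est3$n_blocks)
  expect_lt(abs(est3$delta_g - full), 4 * max(se, 0.02))
  expect_error(block_free_energy(energy_series(rnorm(8), temperature = 300),
                                 n_blocks = 5), "too short")
})

test_that("block error shrinks with series length on white noise", {
  errs <- vapply(c(2000, 32000), function(n) {
    mean(vapply(1:5, function(s) {
      u <- simulate_energy_series(-30, 2, autocorr_time = 0.2, n = n,
                                  seed = s)
      block_free_energy(u)$error
    }, numeric(1)))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("temperature differences combine in quadrature with guards", {
  e1 <- structure(list(delta_g = -10, error = 3, n_blocks = 5,
                       temperature = 292, n_used = 10, state = "S"),
                  class = "free_energy")
  e2 <- structure(list(delta_g = -4, error = 4, n_blocks = 5,
                       temperature = 313, n_used = 10, state = "S"),
                  class = "free_energy")
  dd <- delta_delta_g(e1, e2)
  expect_equal(dd$value, -6)
  expect_equal(dd$error, 5)
  same <- delta_delta_g(e1, e1)
  expect_equal(same$value, 0)
  expect_equal(same$error, 3 * sqrt(2))
  e3 <- e2; e3$state <- "NS"
  expect_error(delta_delta_g(e1, e3), "state")
  # synthetic pair with a known offset is recovered within the block errors
  s1 <- simulate_energy_series(-120, 5, autocorr_time = 20, n = 20000,
                               temperature = 292, seed = 11)
  s2 <- simulate_energy_series(-70, 5, autocorr_time = 20, n = 20000,
                               temperature = 313, seed = 12)
  s1$state <- s2$state <- "S"
  b1 <- block_free_energy(s1); b2 <- block_free_energy(s2)
  dd2 <- delta_delta_g(b1, b2)
  expect_lt(abs(dd2$value - (-50)), 2 * max(dd2$error, 1))
})

test_that("the pressure-volume term converts units correctly", {
  expect_equal(pv_term(1, 1), 0.0602214076)
  expect_lt(abs(pv_term(1, 1545) - 93.0), 0.1)
  expect_equal(pv_term(1, 200), 2 * pv_term(1, 100))
  expect_error(pv_term(-1, 10), "positive")
  expect_equal(kj_to_kcal(kcal_to_kj(3.7)), 3.7)
})

test_that("radial distribution normalises to unity for uniform points", {
  set.seed(4)
  n <- 1e5
  pts <- cbind(runif(n, -10, 10), runif(n, -10, 10))
  ref <- matrix(c(0, 0), 1)
  g <- radial_distribution(pts, ref, r_max = 6, n_bins = 30,
                           box_measure = 400, dimensionality = 2)
  mid <- g$g[g$r > 1 & g$r < 5]
  expect_true(all(abs(mid - 1) < 0.05))
  # exclusion zone forces g = 0 inside it
  d <- sqrt(rowSums(pts^2))
  g2 <- radial_distribution(pts[d > 2, ], ref, r_max = 6, n_bins = 30,
                            box_measure = 400, dimensionality = 2)
  expect_true(all(g2$g[g2$r < 1.9] == 0))
  # density invariance: halving the point count leaves g at unity within
  # Poisson counting noise (a few percent per bin, worst bin larger)
  g3 <- radial_distribution(pts[seq(1, n, 2), ], ref, r_max = 6, n_bins = 30,
                            box_measure = 400, dimensionality = 2)
  d <- abs(g3$g[g3$r > 1 & g3$r < 5] - g$g[g$r > 1 & g$r < 5])
  expect_lt(mean(d), 0.05)
  expect_lt(max(d), 0.25)
  expect_warning(radial_distribution(pts, ref, r_max = 30, n_bins = 10,
                                     box_measure = 400, dimensionality = 2),
                 "box")
})
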