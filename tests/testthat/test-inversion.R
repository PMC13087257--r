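test_that("traces round-trip through text files with unit handling", {
  gt <- single_gauss_truth()
  tr <- simulate_trace(gt, trace_spec(t_max = 3, dt = 0.03, noise_sd = 0))
  f <- withr::local_tempfile(fileext = ".dat")
  write.table(cbind(tr$t, tr$V), f, row.names = FALSE, col.names = FALSE)
  rt <- read_trace(f)
  expect_equal(rt$t, tr$t, tolerance = 1e-12)
  expect_equal(rt$V, tr$V, tolerance = 1e-12)
  # ns-unit file is auto-converted
  fns <- withr::local_tempfile(fileext = ".dat")
  write.table(cbind(tr$t * 1000, tr$V), fns, row.names = FALSE,
              col.names = FALSE)
  expect_equal(max(read_trace(fns)$t), max(tr$t), tolerance = 1e-9)
  # shuffled rows violate monotonicity
  fsh <- withr::local_tempfile(fileext = ".dat")
  idx <- c(2, 1, seq(3, length(tr$t)))
  write.table(cbind(tr$t[idx], tr$V[idx]), fsh, row.names = FALSE,
              col.names = FALSE)
  expect_error(read_trace(fsh), "increasing")
  # malformed rows are reported with their line number
  fbad <- withr::local_tempfile(fileext = ".dat")
  lines <- readLines(f)
  lines[10] <- "0.3 not_a_number"
  writeLines(lines, fbad)
  expect_error(read_trace(fbad), "line 10")
  expect_error(read_trace({
    fshort <- withr::local_tempfile(fileext = ".dat")
    write.table(cbind(1:10, 1:10), fshort, row.names = FALSE,
                col.names = FALSE)
    fshort
  }), "50")
})

test_that("end truncation removes points and barely moves a clean fit", {
  gt <- single_gauss_truth()
  tr <- simulate_trace(gt, trace_spec(t_max = 7.5, dt = 0.015, noise_sd = 0))
  expect_identical(truncate_end(tr, 0), tr)
  n <- length(tr$t)
  tr10 <- truncate_end(tr, 10)
  expect_length(tr10$t, n - 10)
  expect_lt(max(tr10$t), max(tr$t))
  expect_error(truncate_end(tr, n - 10), "n_points")
  ax <- quick_axis()
  m_full <- ddist_moments(deer_fit(tr, ax)$distribution)["mean"]
  m_trunc <- ddist_moments(deer_fit(truncate_end(tr, 20), ax)$distribution)["mean"]
  expect_lt(abs(m_full - m_trunc), 0.05)
})

test_that("single-trace inversion recovers a clean Gaussian ground truth", {
  gt <- make_ground_truth(data.frame(mean = 4, sd = 0.3, weight = 1))
  tr <- simulate_trace(gt, trace_spec(t_max = 6, dt = 0.016, lambda = 0.3,
                                      k = 0.05, noise_sd = 0))
  fit <- fit_single(tr)
  mo <- ddist_moments(fit$distribution)
  expect_lt(abs(mo["mean"] - 4), 0.05)
  expect_lt(abs(mo["sd"] - 0.3), 0.05)
  expect_true(all(fit$distribution$P >= 0))
  expect_lt(abs(ddist_integral(fit$distribution) - 1), 1e-9)
})

test_that("modulation depth is recovered and low depth is flagged", {
  gt <- single_gauss_truth()
  tr <- simulate_trace(gt, trace_spec(t_max = 4, dt = 0.016, lambda = 0.30,
                                      k = 0.05, noise_sd = 0.005, seed = 2))
  fit <- deer_fit(tr, quick_axis())
  expect_gt(fit$pars$lambda, 0.27)
  expect_lt(fit$pars$lambda, 0.33)
  # nearly pure background
  trbg <- simulate_trace(gt, trace_spec(t_max = 4, dt = 0.016, lambda = 0.01,
                                        k = 0.05, noise_sd = 0.003, seed = 3))
  fitbg <- deer_fit(trbg, quick_axis())
  expect_identical(fitbg$pars$lambda < 0.02,
                   "low modulation depth" %in% fitbg$diagnostics$flags)
})

test_that("a set of one reduces the global fit to the single fit", {
  gt <- single_gauss_truth()
  tr <- simulate_trace(gt, trace_spec(t_max = 3, dt = 0.02, noise_sd = 0.005))
  ax <- quick_axis()
  f1 <- fit_single(tr, ax)
  fg <- fit_global(simulate_trace_set(gt, list(
    trace_spec(t_max = 3, dt = 0.02, noise_sd = 0.005))), ax)
  expect_equal(f1$distribution$P, fg$distribution$P, tolerance = 1e-9)
  expect_equal(f1$alpha, fg$alpha)
})

test_that("global fit of four fixture traces resolves both states", {
  ts <- simulate_fixture("exp19C", seed = 1)
  fit <- deer_fit(ts)
  # the two modes of the recovered distribution (quantified as the centres
  # of its two-Gaussian decomposition) sit at the ground-truth means
  tg <- fit_two_gaussians(fit$distribution, 1.0, "sd")
  expect_lt(abs(tg$mu[1] - 3.3), 0.1)
  expect_lt(abs(tg$mu[2] - 5.0), 0.15)
  # residuals of each trace are white at the 1% level
  for (r in fit$residuals) expect_gt(runs_test_p(r), 0.01)
  # per-trace nuisance parameters recovered
  expect_true(all(abs(fit$pars$lambda - 0.3) < 0.05))
  expect_true(all(abs(fit$pars$k - 0.05) < 0.02))
})

test_that("alpha selection returns a full curve and tracks noise", {
  gt <- single_gauss_truth()
  tr <- simulate_trace(gt, trace_spec(t_max = 3, dt = 0.02, noise_sd = 0.005))
  sel <- select_alpha(tr, quick_axis())
  expect_length(sel$values, length(sel$grid))
  expect_true(sel$alpha %in% sel$grid)
  expect_error(select_alpha(tr, quick_axis(), alpha_grid = c(0.1, 1)),
               "grid")
  # noiseless data: the selected alpha keeps reconstruction error tiny
  tr0 <- simulate_trace(gt, trace_spec(t_max = 3, dt = 0.02, noise_sd = 0))
  fit0 <- deer_fit(tr0, quick_axis())
  expect_lt(max(abs(fit0$fitted[[1]] - tr0$V)), 1e-3)
  # a 10x noise increase raises the selected alpha on average
  picks <- vapply(1:10, function(s) {
    lo <- deer_fit(simulate_trace(gt, trace_spec(
      t_max = 3, dt = 0.02, noise_sd = 0.002, seed = s)), quick_axis())$alpha
    hi <- deer_fit(simulate_trace(gt, trace_spec(
      t_max = 3, dt = 0.02, noise_sd = 0.02, seed = s)), quick_axis())$alpha
    c(lo, hi)
  }, numeric(2))
  expect_gt(mean(log(picks[2, ])), mean(log(picks[1, ])))
})

test_that("reconstruction error grows with noise", {
  gt <- single_gauss_truth()
  ax <- quick_axis()
  err <- vapply(c(0.002, 0.005, 0.01, 0.02), function(ns) {
    mean(vapply(1:3, function(s) {
      fit <- deer_fit(simulate_trace(gt, trace_spec(
        t_max = 3, dt = 0.02, noise_sd = ns, seed = s)), ax)
      ddist_l1(fit$distribution, gt)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(err[4], err[1])
  expect_gt(cor(err, c(0.002, 0.005, 0.01, 0.02), method = "spearman"), 0)
})

test_that("reliability ranges follow the cube-root window scaling", {
  r2 <- reliability_ranges(2)
  expect_equal(r2$r_shape, 5.0)
  expect_equal(r2$r_mean_width, 6.0)
  expect_equal(r2$r_mean, 7.0)
  r16 <- reliability_ranges(16)
  expect_equal(r16$r_shape, 10.0)
  for (tm in c(0.5, 2, 7.5, 20)) {
    rr <- reliability_ranges(tm)
    expect_lt(rr$r_shape, rr$r_mean_width)
    expect_lt(rr$r_mean_width, rr$r_mean)
  }
  expect_error(reliability_ranges(0), "positive")
})

test_that("inner solver matches the constrained least-squares oracle", {
  set.seed(42)
  for (rep in 1:5) {
    nr <- 20
    A <- matrix(rnorm(60 * nr), 60, nr)
    xt <- pmax(rnorm(nr), 0)
    b <- drop(A %*% xt + rnorm(60, 0, 0.05))
    L <- deerpop:::.second_diff(nr)
    for (alpha in c(0.01, 1)) {
      Astack <- rbind(A, alpha * L)
      bstack <- c(b, rep(0, nrow(L)))
      oracle <- pracma::lsqnonneg(Astack, bstack)$x
      mine <- deerpop:::fnnls_cpp(crossprod(Astack),
                                  drop(crossprod(Astack, bstack)))$x
      expect_lt(max(abs(mine - oracle)), 1e-6)
    }
  }
})

test_that("leave-one-out fits are stable and degenerate for duplicates", {
  gt <- single_gauss_truth()
  sp <- trace_spec(t_max = 3, dt = 0.02, noise_sd = 0.005, seed = 5)
  tr <- simulate_trace(gt, sp)
  dup <- structure(list(tr, tr, tr), class = "deer_traceset")
  jk <- jackknife_traces(dup, quick_axis())
  expect_length(jk$fits, 3)
  expect_lt(jk$max_l1, 1e-6)
  expect_error(jackknife_traces(structure(list(tr, tr),
                                          class = "deer_traceset"),
                                quick_axis()), "3")
  # four distinct-window fixture traces from one truth: distributions agree
  ts <- simulate_fixture("exp19C", seed = 1)
  jk2 <- jackknife_traces(ts)
  expect_length(jk2$fits, 4)
  expect_lt(jk2$max_l1, 0.15)
})
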