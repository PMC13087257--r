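# shared small fixtures and independent oracles for the test-suite

quick_axis <- function() distance_axis(2, 6, 0.1)

single_gauss_truth <- function(axis = quick_axis(), mean = 4, sd = 0.3)
  make_ground_truth(data.frame(mean = mean, sd = sd, weight = 1), axis)

two_state_truth <- function(axis = distance_axis(), p_S = 0.57)
  make_ground_truth(data.frame(mean = c(3.3, 5.0), sd = c(0.5, 0.3),
                               weight = c(1 - p_S, p_S)), axis)

# brute-force powder-average oracle: plain Riemann sum on a fine u-grid,
# independent of both package evaluation routes
kernel_oracle <- function(t, r, n = 1e5) {
  u <- (seq_len(n) - 0.5) / n
  phi <- 2 * pi * 52.04 / r^3 * t
  vapply(phi, function(p) mean(cos(p * (1 - 3 * u^2))), numeric(1))
}

# Wald-Wolfowitz runs test on residual signs; returns p-value
runs_test_p <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v <- (mu - 1) * (mu - 2) / (n1 + n2 - 1)
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}
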