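test_that("log-sigmoid derivatives: signs, symmetry, finite differences", {
  d0 <- derivative_a_b(1, 0)
  expect_equal(d0$a, -2 * dnorm(0))
  expect_equal(d0$a, -d0$b)
  xs <- seq(-3, 3, 0.5)
  d <- derivative_a_b(1, xs)
  expect_true(all(d$a < 0) && all(d$b > 0))
  # finite-difference oracle for both orders
  h <- 1e-5
  fd_a1 <- (log(pi_tail(1 + h)) - log(pi_tail(1 - h))) / (2 * h)
  fd_b1 <- (log(1 - pi_tail(1 + h)) - log(1 - pi_tail(1 - h))) / (2 * h)
  d1 <- derivative_a_b(1, 1)
  expect_equal(d1$a, fd_a1, tolerance = 1e-6)
  expect_equal(d1$b, fd_b1, tolerance = 1e-6)
  d2 <- derivative_a_b(2, 1)
  fd_a2 <- (derivative_a_b(1, 1 + h)$a - derivative_a_b(1, 1 - h)$a) / (2 * h)
  fd_b2 <- (derivative_a_b(1, 1 + h)$b - derivative_a_b(1, 1 - h)$b) / (2 * h)
  expect_equal(d2$a, fd_a2, tolerance = 1e-6)
  expect_equal(d2$b, fd_b2, tolerance = 1e-6)
  expect_error(derivative_a_b(3, 0), "u must be")
})

test_that("zeta takes the right branch and differentiates the potential", {
  fx <- tiny_net()
  p <- fx$params
  r <- simulate_trial(p, 50, 10, seed = 3)
  omega <- unclass(r)
  rr <- 25
  x <- x_threshold_distance(p, r, NULL, 1, rr - 1)
  d <- derivative_a_b(1, x)
  sig <- integrated_noise_std(p, r, 1, rr - 1)
  want <- if (omega[1, rr - raster_n_min(r) + 1] == 1) d$a else d$b
  expect_equal(zeta(p, r, 1, rr), want / sig, tolerance = 1e-12)
  # finite difference of the potential under a unit stimulus kick at rr - 1
  del <- 1e-5
  S <- matrix(0, 2, ncol(r))
  S[1, (rr - 1) - raster_n_min(r) + 1] <- del
  sf <- stimulus_field(S, n_min = raster_n_min(r), t0 = rr - 1)
  fd <- (potential_phi(p, r, sf, rr) - potential_phi(p, r, NULL, rr)) / del
  expect_equal(-fd, zeta(p, r, 1, rr), tolerance = 1e-4)
})

test_that("zeta_array matches pointwise zeta on a whole ensemble", {
  p <- leaky_params()
  e <- simulate_ensemble(p, 30, 10, NULL, M = 3, master_seed = 6)
  z <- spikeLR:::zeta_array(e, 5:20)
  for (m in 1:3) {
    r <- ensemble_raster(e, m)
    for (t in c(5, 12, 20)) for (k in 1:3)
      expect_equal(z[k, match(t, 5:20), m], zeta(p, r, k, t),
                   tolerance = 1e-10)
  }
})

test_that("kernel entries vanish for neurons independent of the observable", {
  p <- network_params(2, 0, gamma = 0, theta = 1, I0 = 0.6, sigma_B = 0.5)
  e <- simulate_ensemble(p, 2000, 2, NULL, M = 60, master_seed = 8)
  f <- monomial(1, 0)
  kn <- kernel_order1(f, e, D = 3)
  # neuron 2 is disconnected from neuron 1: its column must be noise at 0
  cmp <- spontaneous_correlation(
    f, function(raster, t) vapply(t, function(tt) zeta(p, raster, 2, tt),
                                  numeric(1)), 0, e)
  for (m in 1:4)
    expect_lt(abs(kn$K[2, m]), 4 * cmp$stderr + 1e-3)
  # and the estimator agrees with the generic correlation path entry-wise
  expect_within_3se(kn$K[2, 1], cmp$stderr, cmp$value, "kernel vs corr")
})

test_that("iid closed form: prediction equals the analytic rate derivative", {
  p <- iid_params()
  prob <- iid_rate(p)
  X <- (p$theta - p$I0) / p$sigma_B
  k1 <- exact_kernel(p, 1, monomial(1, 0), depth = 4)
  # K11 = (a1 - b1) p (1 - p) / sigma, other columns vanish (iid)
  d <- derivative_a_b(1, X)
  expect_equal(k1$K[1, 1], (d$a - d$b) * prob * (1 - prob) / p$sigma_B,
               tolerance = 1e-10)
  expect_true(all(abs(k1$K[1, -1]) < 1e-12))
  # impulse stimulus: the predicted jump is dnorm(X)/sigma * S (the exact
  # derivative of the Bernoulli rate with respect to the stimulus)
  amp <- 0.15
  S <- matrix(0, 1, 20); S[1, 8] <- amp
  stim <- stimulus_field(S, n_min = 1, t0 = 8)
  pr <- predict_order1(k1, stim, 1:20)
  expect_equal(pr$value[9], dnorm(X) / p$sigma_B * amp, tolerance = 1e-10)
  expect_true(all(abs(pr$value[-9]) < 1e-12))
  # hc1 coincides with order1 for the iid neuron (zeta exactly degree one)
  kh <- exact_kernel(p, 1, monomial(1, 0), depth = 4, method = "hc1")
  prh <- spikeLR:::predict_from_kernel(kh, stim, 1:20, hc1_prefactor(p)$scale)
  expect_equal(prh, pr$value, tolerance = 1e-12)
})

test_that("predictions are linear in amplitude and causal", {
  fx <- tiny_net()
  p <- fx$params
  k1 <- exact_kernel(p, fx$D, monomial(2, 0), depth = 8)
  t0 <- 6
  s1 <- tiny_net_stimulus(fx, 0.3, t0, 25)
  s2 <- tiny_net_stimulus(fx, 0.6, t0, 25)
  p1 <- predict_order1(k1, s1, 1:25)
  p2 <- predict_order1(k1, s2, 1:25)
  expect_equal(p2$value, 2 * p1$value, tolerance = 1e-12)
  expect_true(all(p1$value[p1$n <= t0] == 0))
  kh <- exact_kernel(p, fx$D, monomial(2, 0), depth = 8, method = "hc1")
  ph <- spikeLR:::predict_from_kernel(kh, s1, 1:25, hc1_prefactor(p)$scale)
  expect_true(all(ph[1:t0] == 0))
})

test_that("the general correlation-series response matches the kernel path", {
  fx <- tiny_net()
  p <- fx$params
  spont <- simulate_ensemble(p, 1500, 10, NULL, M = 1000, master_seed = 77)
  f <- monomial(2, 0, label = "rate2")
  t0 <- 20; Tn <- 60
  stim <- tiny_net_stimulus(fx, 0.5, t0, Tn, burn_in = 10)
  D <- 8
  kn <- kernel_order1(f, spont, D = D)
  pr <- predict_order1(kn, stim, 11:Tn)
  dphi <- lif_delta_phi_order1(spont, stim, times = 3:Tn,
                               horizon = kn$horizon)
  gr <- general_response(f, dphi, spont, times = 11:Tn, D = D)
  # same first-order functional, two estimators on the same ensemble: the
  # kernel path pools anchor times, the general path is per-time, so they
  # agree in rms/shape up to the per-time estimation noise
  scale <- max(abs(pr$value))
  expect_gt(scale, 0.01)
  rms <- sqrt(mean((gr$value - pr$value)^2))
  expect_lt(rms, 0.2 * scale)
  expect_gt(cor(gr$value, pr$value), 0.9)
  # and both are exactly zero where the stimulus cannot reach
  expect_true(all(gr$value[gr$n <= t0] == 0))
})

test_that("validity diagnostics flag saturation and grow with amplitude", {
  fx <- tiny_net()
  p <- fx$params
  t0 <- 10; Tn <- 30
  fracs <- vapply(c(0.5, 2, 8), function(A) {
    stim <- tiny_net_stimulus(fx, A, t0, Tn, burn_in = 5)
    e <- simulate_ensemble(p, Tn, 5, stim, M = 100, master_seed = 19)
    validity_diagnostics(e, stim)$frac_expansion_violated
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
  # no stimulus: no expansion violations at all
  e0 <- simulate_ensemble(p, Tn, 5, NULL, M = 50, master_seed = 20)
  d0 <- validity_diagnostics(e0, NULL)
  expect_equal(d0$frac_expansion_violated, 0)
  expect_gte(d0$frac_saturated, 0)
})
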