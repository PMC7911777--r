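test_that("pi_tail matches quadrature and Gaussian symmetry", {
  expect_equal(pi_tail(0), 0.5)
  xs <- c(-2.3, -0.7, 0.4, 1.1, 3)
  expect_equal(pi_tail(xs) + pi_tail(-xs), rep(1, length(xs)))
  # independent oracle: numeric quadrature of the Gaussian density
  quad <- vapply(c(1.6449, 0.5, -1), function(x)
    integrate(dnorm, x, Inf, rel.tol = 1e-12)$value, numeric(1))
  expect_equal(pi_tail(c(1.6449, 0.5, -1)), quad, tolerance = 1e-9)
  expect_equal(pi_tail(1.6449), 0.05, tolerance = 1e-3)
  expect_true(all(diff(pi_tail(seq(-4, 4, 0.5))) < 0))
  expect_error(pi_tail(NA_real_), "finite")
})

test_that("last_reset_time finds the most recent spike or the sentinel", {
  r <- handmade_raster()              # neuron 1 spikes at 3, 7; n_min = 1
  expect_identical(last_reset_time(r, 1, 9), 7L)
  expect_identical(last_reset_time(r, 1, 5), 3L)
  expect_identical(last_reset_time(r, 1, 7), 7L)   # spike at n itself
  expect_identical(last_reset_time(r, 2, 8), 0L)   # sentinel n_min - 1
  expect_error(last_reset_time(r, 1, 40), "range")
})

test_that("integrated voltage matches the step-recursion oracle", {
  p <- leaky_params()
  set.seed(5)
  omega <- matrix(rbinom(3 * 20, 1, 0.25), 3, 20)
  r <- spike_raster(omega, n_min = 1L)
  S <- matrix(0, 3, 20)
  S[, 12:20] <- matrix(runif(3 * 9, -0.1, 0.1), 3)
  stim <- stimulus_field(S, n_min = 1L, t0 = 12L)
  # oracle: iterate V(n+1) = gamma V(n)(1-w(n)) + inputs(n), zero noise
  V <- rep(0, 3)
  Vtrace <- matrix(NA_real_, 3, 20)
  for (n in 1:19) {
    V <- p$gamma * V * (1 - omega[, n]) + p$W %*% omega[, n] + p$I0 + S[, n]
    Vtrace[, n + 1] <- V
  }
  for (n in c(5, 11, 16, 19)) for (k in 1:3) {
    iv <- integrated_voltage(p, r, stim, k, n)
    expect_equal(iv$v_syn + iv$v_I + iv$v_S, Vtrace[k, n + 1],
                 tolerance = 1e-12)
  }
  # geometric-sum special cases
  p0 <- network_params(1, 0, 0.7, 1, 0.3, 0.2)
  rz <- spike_raster(matrix(0L, 1, 10), n_min = 1L)
  iv <- integrated_voltage(p0, rz, NULL, 1, 6)   # L = 6 steps since start
  expect_equal(iv$v_I, 0.3 * (1 - 0.7^6) / (1 - 0.7))
  r1 <- spike_raster(matrix(c(rep(0L, 5), 1L), 1, 6), n_min = 1L)
  iv1 <- integrated_voltage(p0, r1, NULL, 1, 6)  # spike at n: single term
  expect_equal(iv1$v_I, 0.3)
})

test_that("voltage_decomposition recursion agrees with direct integration", {
  p <- leaky_params()
  set.seed(9)
  r <- simulate_trial(p, 30, 10, seed = 9)
  dec <- voltage_decomposition(p, r, NULL)
  for (n in c(0, 7, 18, 29)) for (k in 1:3) {
    iv <- integrated_voltage(p, r, NULL, k, n)
    j <- n - raster_n_min(r) + 2L                # column of V(n+1)
    expect_equal(dec$v_syn[k, j], iv$v_syn, tolerance = 1e-12)
    expect_equal(dec$v_I[k, j], iv$v_I, tolerance = 1e-12)
    expect_equal(sqrt(dec$s2[k, j]), iv$noise_sd, tolerance = 1e-12)
  }
})

test_that("integrated noise std matches Monte-Carlo variance and limits", {
  p <- network_params(1, 0, 0.6, 1, 0.3, 0.7)
  # spike at t => sigma = sigma_B exactly
  r1 <- spike_raster(matrix(c(0L, 0L, 1L), 1, 3), n_min = 1L)
  expect_equal(integrated_noise_std(p, r1, 1, 3), 0.7)
  # gamma = 0 => sigma_B for any history
  p0 <- iid_params()
  r0 <- spike_raster(matrix(0L, 1, 8), n_min = 1L)
  expect_equal(integrated_noise_std(p0, r0, 1, 8), p0$sigma_B)
  # Monte-Carlo oracle: 10 steps since reset, gamma = 0.6
  rz <- spike_raster(matrix(c(1L, rep(0L, 9)), 1, 10), n_min = 1L)
  set.seed(1)
  n_draws <- 1e6
  acc <- numeric(n_draws)
  for (j in 0:9) acc <- acc + 0.6^j * rnorm(n_draws)  # gamma^(t-l) weights
  mc_sd <- 0.7 * sd(acc)
  se <- mc_sd / sqrt(2 * n_draws)
  got <- integrated_noise_std(p, rz, 1, 10)
  expect_lt(abs(got - mc_sd), 3 * se)
  # monotone growth towards sigma_B / sqrt(1 - gamma^2)
  long <- spike_raster(matrix(0L, 1, 60), n_min = 1L)
  sds <- vapply(1:60, function(t) integrated_noise_std(p, long, 1, t),
                numeric(1))
  expect_true(all(diff(sds) >= 0))
  expect_true(all(diff(sds[1:20]) > 0))   # strictly, until float saturation
  expect_equal(sds[60], 0.7 / sqrt(1 - 0.36), tolerance = 1e-9)
})

test_that("threshold distance decomposes linearly in the stimulus", {
  p <- leaky_params()
  r <- simulate_trial(p, 20, 5, seed = 2)
  S <- matrix(0, 3, 25); S[, 15:25] <- 0.3
  stim1 <- stimulus_field(S, n_min = -4L, t0 = 10L)
  stim2 <- stimulus_field(2 * S, n_min = -4L, t0 = 10L)
  d0 <- x_threshold_distance(p, r, NULL, 2, 18, decompose = TRUE)
  expect_equal(d0$delta_x, 0)
  d1 <- x_threshold_distance(p, r, stim1, 2, 18, decompose = TRUE)
  d2 <- x_threshold_distance(p, r, stim2, 2, 18, decompose = TRUE)
  expect_equal(d1$x_sp, d0$x_sp)
  expect_equal(d2$delta_x, 2 * d1$delta_x, tolerance = 1e-12)
})

test_that("transition probabilities normalize, factorize and stay in (0,1)", {
  p <- leaky_params()
  r <- simulate_trial(p, 15, 5, seed = 3)
  pats <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  probs <- apply(pats, 1, function(q)
    transition_probability(p, r, NULL, as.numeric(q), 10))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_true(all(probs > 0 & probs < 1))
  # factorization over neurons
  pk <- vapply(1:3, function(k)
    pi_tail(x_threshold_distance(p, r, NULL, k, 9)), numeric(1))
  expect_equal(transition_probability(p, r, NULL, c(1, 0, 1), 10),
               pk[1] * (1 - pk[2]) * pk[3], tolerance = 1e-12)
})

test_that("potential is the log transition probability and chains over blocks", {
  p <- leaky_params()
  r <- simulate_trial(p, 15, 5, seed = 4)
  omega <- unclass(r)
  for (n in c(6, 11)) {
    pat <- omega[, n - raster_n_min(r) + 1L]
    expect_equal(exp(potential_phi(p, r, NULL, n)),
                 transition_probability(p, r, NULL, pat, n),
                 tolerance = 1e-12)
  }
  # block probability: exp(sum phi) equals the product of one-step terms
  block_lp <- sum(vapply(8:12, function(n) potential_phi(p, r, NULL, n),
                         numeric(1)))
  prod_p <- prod(vapply(8:12, function(n) {
    pat <- omega[, n - raster_n_min(r) + 1L]
    transition_probability(p, r, NULL, pat, n)
  }, numeric(1)))
  expect_equal(exp(block_lp), prod_p, tolerance = 1e-12)
})

test_that("history changes far in the past barely move the transition probability", {
  p <- leaky_params()
  r <- simulate_trial(p, 40, 0, seed = 6)
  pat <- c(1, 0, 0)
  base <- transition_probability(p, r, NULL, pat, 40)
  diffs <- vapply(c(2, 6, 12, 20), function(m) {
    omega2 <- unclass(r)
    omega2[, seq_len(40 - m)] <- 1L - omega2[, seq_len(40 - m)]
    r2 <- spike_raster(omega2, raster_n_min(r))
    abs(transition_probability(p, r2, NULL, pat, 40) - base)
  }, numeric(1))
  # m-variation decays at least like gamma^m (generous constant)
  expect_true(all(diffs <= 20 * p$gamma^c(2, 6, 12, 20) + 1e-12))
  expect_lt(diffs[4], diffs[1] + 1e-12)
})
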