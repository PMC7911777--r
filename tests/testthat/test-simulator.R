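test_that("simulation is deterministic under a fixed seed", {
  p <- leaky_params()
  r1 <- simulate_trial(p, 40, 10, seed = 123)
  r2 <- simulate_trial(p, 40, 10, seed = 123)
  expect_identical(unclass(r1), unclass(r2))
  e1 <- simulate_ensemble(p, 20, 5, NULL, M = 4, master_seed = 7)
  e2 <- simulate_ensemble(p, 20, 5, NULL, M = 4, master_seed = 7)
  expect_identical(e1$omega, e2$omega)
  expect_identical(e1$seeds, 7:10)
  # M = 1 wraps simulate_trial
  tr <- simulate_trial(p, 20, 5, seed = 7)
  expect_true(all(e1$omega[, , 1] == unclass(tr)))
})

test_that("deterministic sub-threshold dynamics never spike; at threshold they cycle", {
  # fixed point I0/(1-gamma) below theta, negligible noise: silent network
  p_sub <- network_params(2, 0, gamma = 0.5, theta = 1, I0 = 0.4,
                          sigma_B = 1e-9)
  r <- simulate_trial(p_sub, 200, 0, seed = 1)
  expect_equal(sum(r), 0)
  # I0 pushes V over theta every third step: periodic inter-spike interval
  p_per <- network_params(1, 0, gamma = 0.5, theta = 1, I0 = 0.6,
                          sigma_B = 1e-9)
  r2 <- simulate_trial(p_per, 60, 0, seed = 1)
  isi <- diff(which(unclass(r2)[1, ] == 1))
  expect_true(length(isi) > 10)
  expect_true(all(isi == isi[1]))
})

test_that("iid single neuron matches the Bernoulli closed form", {
  p <- iid_params()
  prob <- iid_rate(p)
  r <- simulate_trial(p, 1e5, 1, seed = 42)
  emp <- mean(unclass(r)[1, -1])   # drop the deterministic first step
  expect_lt(abs(emp - prob), 3 * sqrt(prob * (1 - prob) / 1e5))
})

test_that("ensemble one-step transition frequencies match the model law", {
  fx <- tiny_net()
  p <- fx$params
  e <- simulate_ensemble(p, 2000, 10, NULL, M = 50, master_seed = 3)
  # condition on the previous pattern (gamma = 0: memory one step)
  omega <- e$omega
  cols <- 12:2010                      # post-burn-in columns
  prev1 <- omega[1, cols - 1L, ]; prev2 <- omega[2, cols - 1L, ]
  cur1 <- omega[1, cols, ]
  for (q in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    sel <- prev1 == q[1] & prev2 == q[2]
    n_sel <- sum(sel)
    v <- (p$theta - (p$W %*% q + p$I0)) / p$sigma_B
    p_true <- pi_tail(v[1])
    emp <- mean(cur1[sel])
    expect_lt(abs(emp - p_true),
              3 * sqrt(p_true * (1 - p_true) / n_sel))
  }
})

test_that("stationarity: disjoint spontaneous windows agree within CLT error", {
  p <- leaky_params()
  e <- simulate_ensemble(p, 400, 20, NULL, M = 60, master_seed = 11)
  f <- monomial(2, 0)
  # trial-level comparison: means over disjoint windows, SE across trials
  a1 <- colMeans(eval_observable(f, e, 1:200))
  a2 <- colMeans(eval_observable(f, e, 201:400))
  d <- a1 - a2
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 1e-12)
})

test_that("firing-rate estimates and horizons behave", {
  p <- iid_params()
  e <- simulate_ensemble(p, 4000, 1, NULL, M = 25, master_seed = 5)
  est <- estimate_firing_rates(e)
  prob <- iid_rate(p)
  expect_lt(abs(est$nu - prob), 3 * sqrt(prob * (1 - prob) / (25 * 4000)))
  expect_identical(est$horizon, as.integer(min(max(1, round(1 / est$nu)), 100)))
  # silent ensemble: horizon capped with a warning
  p_sil <- network_params(1, 0, 0.5, 1, 0.2, 1e-9)
  e_sil <- simulate_ensemble(p_sil, 50, 0, NULL, M = 2, master_seed = 1)
  expect_warning(est_sil <- estimate_firing_rates(e_sil, horizon_cap = 40),
                 "never spiked")
  expect_identical(est_sil$horizon, 40L)
})

test_that("memory-truncated sampling reproduces the truncated chain law", {
  # gamma > 0: simulate with memory = D and compare to the exact
  # depth-D oracle (same law by construction, independent code paths)
  p <- network_params(2, rbind(c(0, 0.6), c(-0.4, 0)), gamma = 0.5,
                      theta = 1, I0 = 0.5, sigma_B = 0.6)
  D <- 2L
  ch <- build_block_chain(p, D)
  p_inv <- invariant_distribution(ch)
  e <- simulate_ensemble(p, 4000, 20, NULL, M = 50, master_seed = 21,
                         memory = D)
  n_samp <- 50 * 4000
  for (k in 1:2) {
    nu_ex <- exact_expectation(ch, p_inv, monomial(k, 0))
    nu_emp <- mean(e$omega[k, ensemble_cols(e, 1:4000), ])
    expect_lt(abs(nu_emp - nu_ex), 3 * sqrt(nu_ex * (1 - nu_ex) / n_samp))
  }
  c_ex <- exact_correlation(ch, p_inv, monomial(1, 0), monomial(2, 0), 1)
  sc <- spontaneous_correlation(monomial(1, 0), monomial(2, 0), 1, e)
  expect_within_3se(sc$value, sc$stderr, c_ex, "lag-1 cross-correlation")
})

test_that("simulated log-likelihood matches the potential (iid entropy rate)", {
  p <- iid_params()
  prob <- iid_rate(p)
  r <- simulate_trial(p, 3000, 2, seed = 8)
  lp <- vapply(101:3000, function(n) potential_phi(p, r, NULL, n), numeric(1))
  truth <- prob * log(prob) + (1 - prob) * log(1 - prob)
  se <- sd(lp) / sqrt(length(lp))
  expect_within_3se(mean(lp), se, truth, "mean log-likelihood per step")
})
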