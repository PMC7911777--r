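# Shared fixtures, built in code.

# two-neuron oracle-exact network (gamma = 0 => chain memory 1, the depth-2
# block chain is exact and the threshold simulator samples the same law)
tiny_net <- function() make_fixture("tiny-net")

# single neuron, gamma = 0, no weights: i.i.d. Bernoulli(pi((theta-I0)/sigma))
iid_params <- function(theta = 1, I0 = 0.6, sigma_B = 0.5) {
  network_params(N = 1, W = 0, gamma = 0, theta = theta, I0 = I0,
                 sigma_B = sigma_B)
}

iid_rate <- function(params) {
  pi_tail((params$theta - params$I0) / params$sigma_B)
}

# small leaky coupled network for generic property tests
leaky_params <- function() {
  network_params(N = 3, W = rbind(c(0, 0.4, -0.2),
                                  c(0.3, 0, 0.1),
                                  c(-0.5, 0.2, 0)),
                 gamma = 0.5, theta = 1, I0 = 0.4, sigma_B = 0.6)
}

# deterministic raster with a known spike layout (times = columns)
handmade_raster <- function() {
  omega <- matrix(0L, 2, 12)
  omega[1, c(3, 7)] <- 1L
  omega[2, 10] <- 1L
  spike_raster(omega, n_min = 1L)
}

expect_within_3se <- function(est, se, truth, label = "estimate") {
  expect_lt(abs(est - truth), 3 * se + 1e-12,
            label = sprintf("%s (|%.5g - %.5g| vs 3se=%.3g)",
                            label, est, truth, 3 * se))
}
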