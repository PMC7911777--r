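# --- exact computations on small networks under a memory-D truncation ------
#
# State space: all 2^(N*D) spike blocks of depth D.  State index u encodes
# bit (i-1) + N*d as "neuron i spiked d steps before the block's last time"
# (age d = 0 is the newest pattern, stored in the low N bits).  A transition
# u -> u' is legal iff u' = (u mod 2^(N(D-1))) * 2^N + p for some new
# pattern p; its probability is the conditionally-independent Bernoulli
# product with spike probabilities Pi(X_k) where X_k is computed from the
# block with the voltage integration capped at the block start (a neuron
# with no spike inside the block is treated as reset at the block's first
# step).  The truncation error of this finite-memory approximation is
# governed by gamma^D (and vanishes for gamma = 0).

# threshold distances, noise scales and spike probabilities Pi(X_k) out of
# every state; S_hist is N x D (stimulus at the block's times,
# oldest..newest) or NULL
state_fields <- function(params, D, S_hist = NULL) {
  N <- params$N; g <- params$gamma
  nstate <- 2L^(N * D)
  u <- 0:(nstate - 1L)
  v <- s2 <- matrix(0, nstate, N)
  for (j in seq_len(D)) {                      # oldest (age D-1) to newest
    age <- D - j
    pat <- bitwAnd(bitwShiftR(u, N * age), 2L^N - 1L)
    om <- matrix(0L, nstate, N)
    for (i in seq_len(N)) om[, i] <- bitwAnd(bitwShiftR(pat, i - 1L), 1L)
    keep <- 1 - om
    syn <- om %*% t(params$W)
    for (k in seq_len(N)) {
      drive <- syn[, k] + params$I0 +
        if (is.null(S_hist)) 0 else S_hist[k, j]
      v[, k] <- g * v[, k] * keep[, k] + drive
      s2[, k] <- g^2 * s2[, k] * keep[, k] + params$sigma_B^2
    }
  }
  x <- (params$theta - v) / sqrt(s2)
  list(x = x, s = sqrt(s2), p = pi_tail(x))    # each nstate x N
}

#' Block transition chain of a small network
#'
#' Builds the exact transition matrix of the depth-`D` Markov approximation
#' of the model on the space of `2^(N*D)` spike blocks.  Rows sum to one;
#' an entry is non-zero exactly for legal block-overlap transitions, and
#' every legal entry is strictly positive (the Bernoulli probabilities lie
#' in (0,1) for finite parameters).
#'
#' @param params a [network_params()].
#' @param D memory depth of the chain (>= 1).
#' @param stimulus_hist `NULL` (spontaneous), or an `N x D` matrix of
#'   stimulus values at the block's time steps (oldest to newest) entering
#'   the voltage integration.
#' @param max_bits capacity guard: requires `N * D <= max_bits` (dense
#'   `2^(N*D)` linear algebra; the oracle targets test-sized networks).
#' @return Object of class `block_chain`: list with the dense transition
#'   matrix `M`, `params`, `D`, `n_states`, and the per-state spike
#'   probabilities `p_spike`.
#' @export
build_block_chain <- function(params, D, stimulus_hist = NULL,
                              max_bits = 12L) {
  N <- params$N
  if (N * D > max_bits)
    stop(sprintf("state space 2^%d exceeds capacity (max_bits = %d)",
                 N * D, max_bits))
  if (!is.null(stimulus_hist))
    stopifnot(nrow(stimulus_hist) == N, ncol(stimulus_hist) == D)
  nstate <- 2L^(N * D)
  fields <- state_fields(params, D, stimulus_hist)
  p_spike <- fields$p
  M <- matrix(0, nstate, nstate)
  u <- 0:(nstate - 1L)
  base <- bitwAnd(u, 2L^(N * (D - 1L)) - 1L) * 2L^N
  for (p in 0:(2L^N - 1L)) {
    prob <- rep(1, nstate)
    for (k in seq_len(N)) {
      bit <- bitwAnd(bitwShiftR(p, k - 1L), 1L)
      prob <- prob * if (bit == 1L) p_spike[, k] else 1 - p_spike[, k]
    }
    M[cbind(u + 1L, base + p + 1L)] <- prob
  }
  structure(list(M = M, params = params, D = as.integer(D),
                 n_states = nstate, p_spike = p_spike, fields = fields),
            class = "block_chain")
}

#' @export
print.block_chain <- function(x, ...) {
  cat(sprintf("<block_chain> N=%d D=%d: %d states\n",
              x$params$N, x$D, x$n_states))
  invisible(x)
}

#' Invariant distribution of a block chain
#'
#' Left fixed point of the transition matrix, computed by power iteration
#' to an L1 tolerance.
#'
#' @param chain a [build_block_chain()] result.
#' @param tol L1 convergence tolerance (default 1e-12).
#' @param max_iter iteration cap.
#' @return Probability vector over block states (positive, sums to 1).
#' @export
invariant_distribution <- function(chain, tol = 1e-12, max_iter = 1e6) {
  p <- rep(1 / chain$n_states, chain$n_states)
  for (it in seq_len(max_iter)) {
    pn <- as.numeric(p %*% chain$M)
    pn <- pn / sum(pn)
    if (sum(abs(pn - p)) < tol) return(pn)
    p <- pn
  }
  stop(sprintf("power iteration did not converge (residual %.3g)",
               sum(abs(as.numeric(p %*% chain$M) - p))))
}

# values of a monomial (lags < D) on every block state
state_observable_values <- function(f, N, D) {
  u <- 0:(2L^(N * D) - 1L)
  if (inherits(f, "timed_observable")) {
    out <- numeric(length(u))
    for (i in seq_along(f$monomials))
      out <- out + f$coefficients[i] *
        state_observable_values(f$monomials[[i]], N, D)
    return(out)
  }
  stopifnot(inherits(f, "monomial"))
  if (length(f$lags) && max(f$lags) >= D)
    stop("observable range exceeds block depth D")
  out <- rep(1, length(u))
  for (e in seq_along(f$neurons)) {
    bit <- (f$neurons[e] - 1L) + N * f$lags[e]
    out <- out * bitwAnd(bitwShiftR(u, bit), 1L)
  }
  out
}

#' Exact expectation and lagged correlation under the block chain
#'
#' `exact_expectation()` evaluates \eqn{E[f]} under the invariant measure;
#' `exact_correlation()` evaluates the centered lagged correlation
#' \eqn{E[f(t+m)g(t)] - E[f]E[g]} by propagating the `g`-weighted
#' distribution `m` steps through the chain (blocks overlap, so window
#' overlaps between `f` and `g` are handled exactly).
#'
#' @param chain a [build_block_chain()] result.
#' @param p_inv its [invariant_distribution()].
#' @param f,g monomial (or timed) observables with range `<= D`.
#' @param lag non-negative integer `m`.
#' @return Scalar.
#' @export
exact_expectation <- function(chain, p_inv, f) {
  sum(p_inv * state_observable_values(f, chain$params$N, chain$D))
}

#' @rdname exact_expectation
#' @export
exact_correlation <- function(chain, p_inv, f, g, lag) {
  stopifnot(lag >= 0)
  fv <- state_observable_values(f, chain$params$N, chain$D)
  gv <- state_observable_values(g, chain$params$N, chain$D)
  if (lag == 0)
    return(sum(p_inv * fv * gv) - sum(p_inv * fv) * sum(p_inv * gv))
  q <- p_inv * gv
  for (i in seq_len(lag)) q <- as.numeric(q %*% chain$M)
  sum(q * fv) - sum(p_inv * fv) * sum(p_inv * gv)
}

#' Spectral gap of a block chain
#'
#' `1 - |lambda_2|`, with `lambda_2` the second-largest eigenvalue modulus
#' of the transition matrix; exact spontaneous correlations decay like
#' \eqn{|\lambda_2|^m}, which is what motivates truncating response sums at
#' a finite depth.
#'
#' @param chain a [build_block_chain()] result.
#' @return Scalar in (0, 1].
#' @export
spectral_gap <- function(chain) {
  ev <- sort(Mod(eigen(chain$M, only.values = TRUE)$values),
             decreasing = TRUE)
  1 - ev[2]
}

#' Exact non-stationary propagation under a stimulus
#'
#' Starts from the spontaneous invariant distribution and applies the
#' time-dependent transition matrices (rebuilt each step with the stimulus
#' history folded into the threshold distances), reading off the exact
#' \eqn{E[f(n)]} and \eqn{\delta f_{exact}(n) = E[f(n)] - E^{(sp)}[f]}.
#' This is the ground-truth trace against which stochastic estimates and
#' first-order predictions are compared on small networks.
#'
#' @param params a [network_params()].
#' @param D memory depth.
#' @param stimulus a [stimulus_field()].
#' @param f monomial (or timed) observable with range `<= D`.
#' @param times evaluation times (default `1 ..` end of stimulus grid).
#' @param max_bits capacity guard as in [build_block_chain()].
#' @return A [response_trace()] with method `"exact"`.
#' @export
propagate_with_stimulus <- function(params, D, stimulus, f, times = NULL,
                                    max_bits = 12L) {
  if (is.null(times))
    times <- 1:(attr(stimulus, "n_min") + ncol(stimulus) - 1L)
  stopifnot(all(diff(times) == 1L))
  sp_chain <- build_block_chain(params, D, NULL, max_bits)
  p_inv <- invariant_distribution(sp_chain)
  f_sp <- exact_expectation(sp_chain, p_inv, f)
  fv <- state_observable_values(f, params$N, D)
  q <- p_inv
  t0 <- attr(stimulus, "t0")
  vals <- numeric(length(times))
  # warm from the first time whose D-window can touch the stimulus
  start <- max(min(times), t0)
  for (n in min(times):max(times)) {
    if (n >= start) {
      S_hist <- stimulus_values(stimulus, (n - D):(n - 1L))
      ch <- if (all(S_hist == 0)) sp_chain else
        build_block_chain(params, D, S_hist, max_bits)
      q <- as.numeric(q %*% ch$M)
    }
    i <- match(n, times)
    if (!is.na(i)) vals[i] <- sum(q * fv) - f_sp
  }
  response_trace(times, vals, stderr = NA_real_, method = "exact",
                 observable = observable_label(f))
}

#' Exact response kernels from the block chain
#'
#' Computes the kernel entries
#' \eqn{K^{(1)}_{k,m} = C^{(sp)}[f(m,\cdot), \zeta_k(0,\cdot)]} (or, with
#' `method = "hc1"`, \eqn{C^{(sp)}[f(m,\cdot), \omega_k(0,\cdot)]}) exactly:
#' the susceptibility lives on (state, next-pattern) pairs, and the
#' `f`-correlation at column `m` is obtained by propagating the weighted
#' distribution `m - 1` steps.  Used to validate the ensemble estimators
#' and to drive [predict_order1()] without sampling noise.
#'
#' @param params a [network_params()].
#' @param D memory depth of the chain.
#' @param f monomial (or timed) observable with range `<= D`.
#' @param depth kernel truncation depth (columns `m = 1..depth+1`).
#' @param method `"order1"` or `"hc1"`.
#' @param horizon_cap clip for the mean-field horizon.
#' @param max_bits capacity guard.
#' @return A `response_kernel` with exact entries and exact rates.
#' @export
exact_kernel <- function(params, D, f, depth, method = c("order1", "hc1"),
                         horizon_cap = 10L * depth, max_bits = 12L) {
  method <- match.arg(method)
  chain <- build_block_chain(params, D, NULL, max_bits)
  p_inv <- invariant_distribution(chain)
  N <- params$N
  nstate <- chain$n_states
  fv <- state_observable_values(f, N, D)
  Ef <- sum(p_inv * fv)
  u <- 0:(nstate - 1L)
  base <- bitwAnd(u, 2L^(N * (D - 1L)) - 1L) * 2L^N
  # susceptibility on (state, new pattern): zeta or the bare spike variable
  d1 <- derivative_a_b(1, chain$fields$x)
  q0 <- matrix(0, nstate, N)                     # weighted successor mass
  Ez <- numeric(N)
  for (p in 0:(2L^N - 1L)) {
    prob <- rep(1, nstate)
    for (k in seq_len(N)) {
      bit <- bitwAnd(bitwShiftR(p, k - 1L), 1L)
      prob <- prob * if (bit == 1L) chain$p_spike[, k] else 1 - chain$p_spike[, k]
    }
    w <- p_inv * prob
    tgt <- base + p + 1L
    for (k in seq_len(N)) {
      bit <- bitwAnd(bitwShiftR(p, k - 1L), 1L)
      zk <- if (method == "order1") {
        (if (bit == 1L) d1$a[, k] else d1$b[, k]) / chain$fields$s[, k]
      } else rep(bit, nstate)
      contrib <- w * zk
      # many states share a successor: aggregate before accumulating
      agg <- rowsum(contrib, tgt)
      q0[as.integer(rownames(agg)), k] <-
        q0[as.integer(rownames(agg)), k] + agg[, 1L]
      Ez[k] <- Ez[k] + sum(contrib)
    }
  }
  K <- matrix(0, N, depth + 1L)
  q <- q0
  for (m in seq_len(depth + 1L)) {
    for (k in seq_len(N)) K[k, m] <- sum(q[, k] * fv) - Ef * Ez[k]
    q <- crossprod(chain$M, q)                   # t(M) %*% q per column
  }
  nu <- vapply(seq_len(N), function(k)
    exact_expectation(chain, p_inv, monomial(k, 0L)), numeric(1))
  horizon <- pmin(pmax(1L, as.integer(round(1 / pmax(nu, 1e-12)))),
                  as.integer(horizon_cap))
  new_response_kernel(K, method, observable_label(f), nu, horizon,
                      as.integer(depth), params)
}
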