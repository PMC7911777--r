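#' Simulate one trial of the network
#'
#' Iterates the sub-threshold recursion with Gaussian noise and
#' threshold/reset: \eqn{\omega_k(n) = 1} iff \eqn{V_k(n) \ge \theta}, then
#' \deqn{V_k(n+1) = \gamma V_k(n)(1-\omega_k(n)) + \sum_j W_{kj}\omega_j(n)
#'       + I_0 + S_k(n) + \sigma_B \xi_k(n),}
#' starting from \eqn{V = 0} at the history start `1 - burn_in`.  The same
#' seed yields a bit-identical raster.
#'
#' With a finite `memory`, spikes are instead drawn from the exact
#' conditional law \eqn{Bernoulli(\Pi(X_k))} with voltage and noise
#' integration capped at `memory` steps since the last reset -- this samples
#' precisely the depth-`memory` Markov truncation of the model used by
#' [build_block_chain()].
#'
#' @param params a [network_params()].
#' @param T_steps number of post-burn-in steps (times `1..T_steps`).
#' @param burn_in number of discarded initial steps (times `1-burn_in..0`);
#'   default `10 * max(tau_gamma, 1)` rounded up.
#' @param stimulus `NULL` or a [stimulus_field()]; must be zero during
#'   burn-in.
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @param keep_voltage also return the voltage trace (threshold mode only).
#' @param memory `Inf` (default) for the full unbounded-memory dynamics, or
#'   a positive integer truncation depth.
#' @return A [spike_raster()] covering times `1-burn_in .. T_steps`; with
#'   `keep_voltage = TRUE`, attribute `"V"` holds the voltage matrix.
#' @export
simulate_trial <- function(params, T_steps, burn_in = default_burn_in(params),
                           stimulus = NULL, seed = NULL,
                           keep_voltage = FALSE, memory = Inf) {
  stopifnot(T_steps >= 1, burn_in >= 0)
  n_min <- 1L - as.integer(burn_in)
  L <- as.integer(burn_in + T_steps)
  S <- if (is.null(stimulus)) matrix(0, params$N, L) else {
    if (attr(stimulus, "t0") < 1L) stop("stimulus onset must be >= 1")
    stimulus_values(stimulus, n_min:T_steps)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.finite(memory)) {
    stopifnot(memory >= 1)
    omega <- sim_lif_truncated(params$N, L, params$gamma, params$theta,
                               params$I0, params$sigma_B, params$W, S,
                               as.integer(memory))
    return(spike_raster(omega, n_min))
  }
  res <- sim_lif_threshold(params$N, L, params$gamma, params$theta,
                           params$I0, params$sigma_B, params$W, S,
                           keep_voltage)
  out <- spike_raster(res$omega, n_min)
  if (keep_voltage) attr(out, "V") <- res$V
  out
}

# burn-in long enough for the leak memory to fade (>= 10 tau_gamma)
default_burn_in <- function(params, D = 1L) {
  as.integer(ceiling(10 * max(params$tau_gamma, D, 1)))
}

#' Simulate a seeded trial ensemble
#'
#' Runs `M` independent trials whose seeds are derived deterministically
#' from `master_seed` (sequential: `master_seed + m - 1` for trial `m`), so
#' that two calls with the same master seed return identical ensembles.
#'
#' @inheritParams simulate_trial
#' @param M number of trials (>= 1).
#' @param master_seed integer; per-trial seeds are `master_seed + 0:(M-1)`.
#' @return A `trial_ensemble`: list with the `N x L x M` binary array
#'   `omega`, `params`, `stimulus`, `seeds`, `burn_in`, `T_steps`, `n_min`,
#'   `M`.
#' @export
simulate_ensemble <- function(params, T_steps,
                              burn_in = default_burn_in(params),
                              stimulus = NULL, M, master_seed,
                              memory = Inf) {
  stopifnot(M >= 1)
  seeds <- as.integer(master_seed) + seq_len(M) - 1L
  L <- as.integer(burn_in + T_steps)
  omega <- array(0L, dim = c(params$N, L, M))
  for (m in seq_len(M)) {
    tr <- tryCatch(
      simulate_trial(params, T_steps, burn_in, stimulus, seed = seeds[m],
                     memory = memory),
      error = function(e) stop(sprintf("trial %d: %s", m, conditionMessage(e)),
                               call. = FALSE))
    omega[, , m] <- unclass(tr)
  }
  structure(list(omega = omega, params = params, stimulus = stimulus,
                 seeds = seeds, burn_in = as.integer(burn_in),
                 T_steps = as.integer(T_steps), n_min = 1L - as.integer(burn_in),
                 M = as.integer(M)),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble> M=%d trials, %d neurons, times %d..%d (%s)\n",
              x$M, x$params$N, x$n_min, x$T_steps,
              if (is.null(x$stimulus)) "spontaneous" else "stimulus-driven"))
  invisible(x)
}

#' Extract one trial of an ensemble as a spike raster
#' @param ensemble a `trial_ensemble`.
#' @param m trial index.
#' @export
ensemble_raster <- function(ensemble, m) {
  omega <- matrix(ensemble$omega[, , m], nrow = dim(ensemble$omega)[1])
  spike_raster(omega, ensemble$n_min)
}

# column indices of an ensemble for a vector of times
ensemble_cols <- function(ensemble, times) {
  j <- times - ensemble$n_min + 1L
  if (any(j < 1L) || any(j > dim(ensemble$omega)[2]))
    stop("time index out of ensemble range")
  j
}

#' Empirical firing rates and mean-field horizons
#'
#' Per-neuron spontaneous rate \eqn{\nu_k}: fraction of (trial, time) bins
#' with a spike, over the post-burn-in window, plus the mean-field horizon
#' \eqn{h_k = \mathrm{round}(1/\nu_k)} (the mean inter-spike interval)
#' clipped to `[1, horizon_cap]`.  A silent neuron gets the cap, with a
#' warning.
#'
#' @param ensemble a spontaneous `trial_ensemble`.
#' @param horizon_cap upper clip for the horizon.
#' @return List with `nu` (rates) and `horizon` (integer vector).
#' @export
estimate_firing_rates <- function(ensemble, horizon_cap = 100L) {
  if (!is.null(ensemble$stimulus))
    warning("firing rates estimated on a stimulus-driven ensemble")
  cols <- ensemble_cols(ensemble, seq_len(ensemble$T_steps))
  nu <- apply(ensemble$omega[, cols, , drop = FALSE], 1, mean)
  h <- integer(length(nu))
  for (k in seq_along(nu)) {
    if (nu[k] <= 0) {
      warning(sprintf("neuron %d never spiked; horizon set to cap", k))
      h[k] <- as.integer(horizon_cap)
    } else {
      h[k] <- min(max(1L, as.integer(round(1 / nu[k]))), as.integer(horizon_cap))
    }
  }
  list(nu = nu, horizon = h)
}
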