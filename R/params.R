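#' Network parameters for the discrete-time LIF model
#'
#' Bundles the constants of the sub-threshold dynamics
#' \deqn{V_k(n+1) = \gamma V_k(n)(1-\omega_k(n)) + \sum_j W_{kj}\omega_j(n)
#'       + I_0 + S_k(n) + \sigma_B \xi_k(n),}
#' where a neuron spikes (\eqn{\omega_k(n)=1}) whenever \eqn{V_k(n) \ge \theta}
#' and its voltage is then reset to 0.  Derived time constants are attached:
#' the integration time \eqn{\tau = 1/(1-\gamma)} and the memory decay time
#' \eqn{\tau_\gamma = -1/\log\gamma} (for \eqn{\gamma > 0}).
#'
#' @param N neuron count (integer >= 1).
#' @param W N x N synaptic weight matrix; `W[k, j]` is the weight from
#'   presynaptic neuron `j` onto postsynaptic neuron `k`.  Scalar 0 is
#'   recycled to a zero matrix.
#' @param gamma leak rate in `[0, 1)`.
#' @param theta firing threshold (voltage units).
#' @param I0 constant input per step (voltage units).
#' @param sigma_B noise amplitude, strictly positive.
#' @return An object of class `network_params`.
#' @examples
#' p <- network_params(N = 2, W = matrix(0, 2, 2), gamma = 0.6,
#'                     theta = 1, I0 = 0.3, sigma_B = 0.2)
#' p$tau_gamma  # ~ 1.96
#' @export
network_params <- function(N, W = 0, gamma, theta, I0, sigma_B) {
  N <- as.integer(N)
  stopifnot(length(N) == 1L, N >= 1L)
  if (is.null(dim(W))) {
    stopifnot(length(W) == 1L, W == 0)
    W <- matrix(0, N, N)
  }
  W <- as.matrix(W)
  if (!all(dim(W) == c(N, N))) stop("W must be an N x N matrix")
  if (!all(is.finite(W))) stop("W must be finite")
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma < 1)
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  stopifnot(is.numeric(I0), length(I0) == 1L, is.finite(I0))
  stopifnot(is.numeric(sigma_B), length(sigma_B) == 1L, sigma_B > 0)
  structure(
    list(N = N, W = W, gamma = gamma, theta = theta, I0 = I0,
         sigma_B = sigma_B,
         tau = 1 / (1 - gamma),
         tau_gamma = if (gamma > 0) -1 / log(gamma) else 0),
    class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "<network_params> N=%d gamma=%g theta=%g I0=%g sigma_B=%g (tau=%.3g, tau_gamma=%.3g)\n",
    x$N, x$gamma, x$theta, x$I0, x$sigma_B, x$tau, x$tau_gamma))
  nz <- sum(x$W != 0)
  cat(sprintf("  W: %d x %d, %d non-zero entries\n", x$N, x$N, nz))
  invisible(x)
}

#' One-dimensional lattice connectivity
#'
#' Builds the banded weight matrix of a chain of `N` neurons with null
#' boundary conditions: each neuron excites its nearest neighbours with
#' weight `+w_plus` and inhibits its second neighbours with weight
#' `-w_minus`.  Both arguments are magnitudes; the inhibitory sign is applied
#' internally.  Entries that would reference sites outside `1..N` are dropped.
#'
#' @param N number of lattice sites.
#' @param w_plus excitatory nearest-neighbour magnitude (>= 0).
#' @param w_minus inhibitory second-neighbour magnitude (>= 0).
#' @return An `N x N` symmetric matrix with zero diagonal and bandwidth 2.
#' @export
lattice_weights <- function(N, w_plus, w_minus) {
  N <- as.integer(N)
  stopifnot(N >= 1L, w_plus >= 0, w_minus >= 0)
  W <- matrix(0, N, N)
  for (k in seq_len(N)) {
    for (d in c(-1L, 1L)) {
      j <- k + d
      if (j >= 1L && j <= N) W[j, k] <- W[j, k] + w_plus
    }
    for (d in c(-2L, 2L)) {
      j <- k + d
      if (j >= 1L && j <= N) W[j, k] <- W[j, k] - w_minus
    }
  }
  W
}

#' Calibrate the constant input for a target baseline rate
#'
#' Solves \eqn{\Pi\big((\theta - I_0/(1-\gamma)) / \sigma_\infty\big) =
#' \nu_{target}} for \eqn{I_0}, with \eqn{\sigma_\infty =
#' \sigma_B/\sqrt{1-\gamma^2}} the stationary integrated-noise scale.  This is
#' a single-neuron mean-field calibration (synaptic input ignored); in a
#' coupled network the realized rate shifts with the net synaptic drive.
#'
#' @param target_rate desired spontaneous spike probability per step, in (0,1).
#' @param gamma,theta,sigma_B model constants as in [network_params()].
#' @return The calibrated `I0` value.
#' @export
calibrate_baseline_input <- function(target_rate, gamma, theta, sigma_B) {
  stopifnot(target_rate > 0, target_rate < 1)
  sigma_inf <- sigma_B / sqrt(1 - gamma^2)
  # Pi(x) = target  <=>  x = qnorm(target, lower.tail = FALSE)
  x <- stats::qnorm(target_rate, lower.tail = FALSE)
  (theta - x * sigma_inf) * (1 - gamma)
}
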