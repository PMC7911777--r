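#' Gaussian upper-tail probability
#'
#' \eqn{\Pi(x) = \frac{1}{\sqrt{2\pi}} \int_x^\infty e^{-u^2/2}\,du}, the
#' model's threshold-crossing nonlinearity: the probability that a neuron
#' whose noise-free voltage sits \eqn{x} integrated-noise standard deviations
#' below threshold fires at the next step.  Strictly decreasing, `pi_tail(0)
#' = 0.5`.
#'
#' @param x numeric vector, finite.
#' @return Probabilities in (0, 1).
#' @export
pi_tail <- function(x) {
  if (!all(is.finite(x))) stop("x must be finite")
  pnorm(x, lower.tail = FALSE)
}

# log Pi and log(1 - Pi) with floors, used for the potential
log_pi_tail <- function(x) {
  pmax(pnorm(x, lower.tail = FALSE, log.p = TRUE), log(1e-300))
}
log_one_minus_pi_tail <- function(x) {
  pmax(pnorm(x, lower.tail = TRUE, log.p = TRUE), log(1e-300))
}

#' Derivatives of the log sigmoid branches
#'
#' Returns the `u`-th derivatives of \eqn{\log \Pi(x)} and
#' \eqn{\log(1-\Pi(x))}, written `a(u)` and `b(u)`.  Closed forms in terms of
#' the Gaussian hazard \eqn{h(x) = \varphi(x)/\Pi(x)} and Mills ratio
#' \eqn{m(x) = \varphi(x)/(1-\Pi(x))}:
#' \deqn{a^{(1)} = -h, \quad a^{(2)} = xh - h^2, \quad
#'       b^{(1)} = m,  \quad b^{(2)} = -m(x + m).}
#' `a(1) < 0 < b(1)` everywhere since \eqn{\Pi} is decreasing.
#'
#' @param u derivative order, 1 or 2.
#' @param x numeric vector, finite.
#' @return List with components `a` and `b`.
#' @export
derivative_a_b <- function(u, x) {
  if (!all(is.finite(x))) stop("x must be finite")
  if (!u %in% c(1, 2)) stop("u must be 1 or 2")
  ldn <- dnorm(x, log = TRUE)
  h <- exp(ldn - pnorm(x, lower.tail = FALSE, log.p = TRUE))
  m <- exp(ldn - pnorm(x, lower.tail = TRUE, log.p = TRUE))
  if (u == 1) list(a = -h, b = m) else list(a = x * h - h^2, b = -m * (x + m))
}

#' Integrated voltage components
#'
#' Evaluates the integrated form of the sub-threshold dynamics: starting from
#' the last reset \eqn{\tau_k(n,\omega)} (or the history start if neuron `k`
#' never spiked), the conditional mean of \eqn{V_k(n+1)} decomposes into
#' \deqn{V^{syn}_k = \sum_j W_{kj} \sum_{l=\tau}^{n} \gamma^{n-l}\omega_j(l),
#'   \quad V^{I}_k = I_0 \frac{1-\gamma^{n+1-\tau}}{1-\gamma}, \quad
#'   V^{S}_k = \sum_{l=\tau}^{n} \gamma^{n-l} S_k(l),}
#' while the integrated noise has mean 0 and standard deviation
#' [integrated_noise_std()].  This is the direct summation; the simulator and
#' the correlation machinery use the equivalent step recursion
#' (see [voltage_decomposition()]), and the two are cross-checked in the
#' test-suite.
#'
#' @param params a [network_params()].
#' @param raster a [spike_raster()] defined at least on `[tau, n]`.
#' @param stimulus `NULL` or a stimulus matrix aligned with the raster
#'   columns (see [moving_gaussian_stimulus()]).
#' @param k neuron index.
#' @param n last history time; the returned values describe \eqn{V_k(n+1)}.
#' @return List with `v_syn`, `v_I`, `v_S`, `noise_mean` (0) and `noise_sd`.
#' @export
integrated_voltage <- function(params, raster, stimulus = NULL, k, n) {
  n_min <- raster_n_min(raster)
  tau <- max(last_reset_time(raster, k, n), n_min)
  ll <- tau:n
  g <- params$gamma ^ (n - ll)
  cols <- raster_col(raster, ll)
  omega_win <- unclass(raster)[, cols, drop = FALSE]
  v_syn <- sum(params$W[k, ] * (omega_win %*% g))
  v_I <- params$I0 * sum(g)
  v_S <- if (is.null(stimulus)) 0 else {
    sum(stimulus_values(stimulus, ll)[k, ] * g)
  }
  list(v_syn = v_syn, v_I = v_I, v_S = v_S, noise_mean = 0,
       noise_sd = integrated_noise_std(params, raster, k, n))
}

#' Integrated noise standard deviation
#'
#' Standard deviation of the Gaussian noise accumulated in the voltage since
#' the last reset:
#' \deqn{\sigma_k(t,\omega) = \sigma_B
#'   \sqrt{\frac{1-\gamma^{2(t+1-\tau_k(t,\omega))}}{1-\gamma^2}},}
#' where \eqn{\tau_k(t,\omega)} is the last reset at or before `t` (the
#' history start counts as a reset).  Equals \eqn{\sigma_B} right after a
#' spike and grows monotonically towards \eqn{\sigma_B/\sqrt{1-\gamma^2}}.
#' The \eqn{\sigma_B} factor is included: this is the full variance of the
#' integrated noise term of the voltage.
#'
#' @inheritParams integrated_voltage
#' @param t time of the conditioning history; the value is the noise scale
#'   of \eqn{V_k(t+1)}.
#' @return Positive scalar.
#' @export
integrated_noise_std <- function(params, raster, k, t) {
  n_min <- raster_n_min(raster)
  tau <- max(last_reset_time(raster, k, t), n_min)
  steps <- t - tau + 1L
  if (params$gamma == 0) return(params$sigma_B)
  params$sigma_B * sqrt((1 - params$gamma^(2 * steps)) / (1 - params$gamma^2))
}

#' Normalized distance to threshold
#'
#' \eqn{X_k(t,\omega) = (\theta - \bar V_k(t,\omega)) / \sigma_k(t,\omega)},
#' where \eqn{\bar V_k} is the noise-free conditional mean of the voltage at
#' `t + 1` (synaptic + constant + stimulus components) and \eqn{\sigma_k} the
#' integrated-noise scale.  The spike probability of neuron `k` at time
#' `t + 1` is exactly \eqn{\Pi(X_k(t,\omega))}.  Decomposes as
#' \eqn{X_k = X^{sp}_k + \delta X_k} with
#' \eqn{\delta X_k = -V^{S}_k/\sigma_k} linear in the stimulus.
#'
#' @inheritParams integrated_noise_std
#' @return Scalar `X` value; with `decompose = TRUE`, a list with `x`,
#'   `x_sp` and `delta_x`.
#' @param decompose return the spontaneous/stimulus split.
#' @export
x_threshold_distance <- function(params, raster, stimulus = NULL, k, t,
                                 decompose = FALSE) {
  v <- integrated_voltage(params, raster, stimulus, k, t)
  s <- v$noise_sd
  x_sp <- (params$theta - (v$v_syn + v$v_I)) / s
  dx <- -v$v_S / s
  if (decompose) list(x = x_sp + dx, x_sp = x_sp, delta_x = dx) else x_sp + dx
}

#' One-step transition probability
#'
#' Probability of observing the spike `pattern` at time `n` given the raster
#' history up to `n - 1`.  The model is conditionally independent across
#' neurons:
#' \deqn{P[\omega(n) \mid \omega^{n-1}] = \prod_k
#'  \big[\omega_k(n)\Pi(X_k) + (1-\omega_k(n))(1-\Pi(X_k))\big],}
#' with \eqn{X_k = X_k(n-1, \omega)} from [x_threshold_distance()].
#'
#' @inheritParams integrated_voltage
#' @param pattern 0/1 vector of length `N`, the candidate spike pattern.
#' @param n the time of the pattern; history must cover `n - 1`.
#' @return Probability in (0, 1).
#' @export
transition_probability <- function(params, raster, stimulus = NULL, pattern, n) {
  stopifnot(length(pattern) == params$N, all(pattern %in% c(0, 1)))
  p <- vapply(seq_len(params$N), function(k) {
    pk <- pi_tail(x_threshold_distance(params, raster, stimulus, k, n - 1L))
    if (pattern[k] == 1) pk else 1 - pk
  }, numeric(1))
  prod(p)
}

#' Normalized Gibbs potential
#'
#' \eqn{\phi(n,\omega) = \log P[\omega(n) \mid \omega^{n-1}] = \sum_k
#' \phi_k(n,\omega)} with
#' \eqn{\phi_k = \omega_k(n)\log\Pi(X_k) + (1-\omega_k(n))\log(1-\Pi(X_k))},
#' evaluated in log space (with a floor at `1e-300` on the probabilities) on
#' the raster's own pattern at time `n`.  Summing \eqn{\phi(r,\omega)} over
#' a block \eqn{r = m, \dots, n} gives the log conditional probability of
#' the block.
#'
#' @inheritParams transition_probability
#' @return Scalar log-probability (negative).
#' @export
potential_phi <- function(params, raster, stimulus = NULL, n) {
  pat <- unclass(raster)[, raster_col(raster, n)]
  phi_k <- vapply(seq_len(params$N), function(k) {
    x <- x_threshold_distance(params, raster, stimulus, k, n - 1L)
    if (pat[k] == 1) log_pi_tail(x) else log_one_minus_pi_tail(x)
  }, numeric(1))
  sum(phi_k)
}

#' Recursive voltage decomposition over a full raster
#'
#' Computes, for every neuron and time, the conditional-mean voltage
#' components and the integrated-noise variance by the step recursion
#' \deqn{c_k(t) = \gamma\, c_k(t-1) (1-\omega_k(t-1)) + \mathrm{input}_k(t-1),
#'  \qquad s^2_k(t) = \gamma^2 s^2_k(t-1)(1-\omega_k(t-1)) + \sigma_B^2,}
#' with zero initial conditions at the history start.  Column `t` of each
#' field refers to the voltage \eqn{V_k(t)} (decided by the history up to
#' `t - 1`); the first column is the deterministic start (`s2 = 0`), so
#' threshold distances are defined from the second column on.
#'
#' @inheritParams integrated_voltage
#' @return List of `N x L` matrices `v_syn`, `v_I`, `v_S`, `s2`, plus the
#'   raster time axis `times`.
#' @export
voltage_decomposition <- function(params, raster, stimulus = NULL) {
  N <- params$N
  L <- ncol(raster)
  omega <- unclass(raster)
  S <- if (is.null(stimulus)) NULL else stimulus_matrix(stimulus, raster)
  v_syn <- v_I <- v_S <- s2 <- matrix(0, N, L)
  g <- params$gamma
  for (t in 2:L) {
    keep <- 1 - omega[, t - 1L]
    syn_in <- as.numeric(params$W %*% omega[, t - 1L])
    v_syn[, t] <- g * v_syn[, t - 1L] * keep + syn_in
    v_I[, t] <- g * v_I[, t - 1L] * keep + params$I0
    if (!is.null(S)) v_S[, t] <- g * v_S[, t - 1L] * keep + S[, t - 1L]
    s2[, t] <- g^2 * s2[, t - 1L] * keep + params$sigma_B^2
  }
  list(v_syn = v_syn, v_I = v_I, v_S = v_S, s2 = s2,
       times = raster_n_min(raster) + seq_len(L) - 1L)
}
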